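# Codecs for the system cargo formats.  The TSV dialect is deliberately
# minimal and is itself part of the format contract: no header row, no
# quoting, no escaping, fields split on literal tabs, LF line endings on
# write (CRLF tolerated on read).  Values are preserved verbatim -- the
# library never reformats a stored value, so no precision is added or lost.

payload_text <- function(payload) {
  if (is.raw(payload)) payload <- rawToChar(payload)
  qdb_assert(is.character(payload) && length(payload) == 1L,
             "qdb_type_error", "payload must be raw or a single string")
  payload
}

# split into lines; accepts CRLF; a trailing newline does not produce an
# empty final row
tsv_lines <- function(text) {
  if (!nzchar(text)) return(character())
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (endsWith(text, "\n")) lines else lines  # strsplit already drops nothing
}

# strsplit drops a trailing empty field ("1\t" -> "1"), so guard with a
# sentinel to keep empty trailing cells observable
tsv_fields <- function(line) {
  fields <- strsplit(paste0(line, "\x01"), "\t", fixed = TRUE)[[1L]]
  n <- length(fields)
  fields[n] <- substr(fields[n], 1L, nchar(fields[n]) - 1L)
  fields
}

#' Classify a parameter value token
#'
#' A token is "normal" iff it parses as a number in the simplified US
#' system: dot decimal separator, optional sign and exponent, and no
#' grouping separators (so `"1,204"` is abnormal).  Every other non-empty
#' token -- `"N/A"` or any custom error code -- is "abnormal".  The raw text
#' is always preserved verbatim.
#'
#' @param raw character vector of raw value tokens.
#' @return a data frame with columns `raw`, `kind` (`"normal"`/`"abnormal"`)
#'   and `numeric` (`NA` for abnormal tokens).
#' @examples
#' qdb_classify_value(c("3.2e-5", "N/A", "1,204"))
#' @export
qdb_classify_value <- function(raw) {
  qdb_assert(is.character(raw), "qdb_type_error", "raw must be character")
  normal <- grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$", raw)
  data.frame(raw = raw,
             kind = ifelse(normal, "normal", "abnormal"),
             numeric = ifelse(normal, suppressWarnings(as.numeric(raw)), NA_real_),
             stringsAsFactors = FALSE)
}

# canonical text form for a computed value; %.17g round-trips doubles
# exactly through as.numeric()
qdb_format_number <- function(x) sprintf("%.17g", x)

#' Parameter value tables
#'
#' `qdb_values()` builds a parameter table in memory; `qdb_parse_values()`
#' decodes a `values` cargo payload; `qdb_format_values()` serialises one.
#' The first column holds compound identifiers, the second holds the
#' activity/property/descriptor values; additional columns are preserved
#' byte-exact but carry no defined meaning.  At most one row per compound.
#'
#' @param ids character vector of compound identifiers.
#' @param values character vector of raw value tokens (use
#'   [qdb_classify_value()] to inspect them).
#' @param extras optional list of character vectors, extra columns per row.
#' @param payload raw vector or text of a `values` cargo.
#' @param strict if `FALSE`, duplicate compound rows are tolerated (used by
#'   the validator, which must be able to inspect broken archives).
#' @param x a `qdb_values` table.
#' @return `qdb_values()`/`qdb_parse_values()` a `qdb_values` object;
#'   `qdb_format_values()` a single string in the TSV dialect.
#' @export
qdb_values <- function(ids, values, extras = NULL) {
  ids <- as.character(ids)
  values <- as.character(values)
  qdb_assert(length(ids) == length(values), "qdb_type_error",
             "ids and values must have the same length")
  qdb_assert(!anyDuplicated(ids), "qdb_duplicate_compound_row",
             "at most one row per compound identifier")
  if (is.null(extras)) extras <- rep(list(character()), length(ids))
  structure(list(id = ids, value = values, extras = extras),
            class = "qdb_values")
}

#' @rdname qdb_values
#' @export
qdb_parse_values <- function(payload, strict = TRUE) {
  lines <- tsv_lines(payload_text(payload))
  lines <- sub("\r$", "", lines)
  rows <- lapply(seq_along(lines), function(i) {
    fields <- tsv_fields(lines[[i]])
    if (length(fields) < 2L) {
      qdb_stop("qdb_malformed_row",
               sprintf("row %d has %d column(s), expected at least 2", i, length(fields)),
               row = i)
    }
    fields
  })
  ids <- vapply(rows, `[[`, character(1L), 1L)
  if (strict && anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    qdb_stop("qdb_duplicate_compound_row",
             sprintf("duplicate row for compound '%s'", dup), id = dup)
  }
  structure(list(id = ids,
                 value = vapply(rows, `[[`, character(1L), 2L),
                 extras = lapply(rows, function(f) f[-(1:2)])),
            class = "qdb_values")
}

#' @rdname qdb_values
#' @export
qdb_format_values <- function(x) {
  stopifnot(inherits(x, "qdb_values") || inherits(x, "qdb_references"))
  if (inherits(x, "qdb_references")) {
    rows <- mapply(function(i, k) paste(c(i, k), collapse = "\t"),
                   x$id, x$key, USE.NAMES = FALSE)
  } else {
    rows <- mapply(function(i, v, e) paste(c(i, v, e), collapse = "\t"),
                   x$id, x$value, x$extras, USE.NAMES = FALSE)
  }
  if (!length(rows)) "" else paste0(paste(rows, collapse = "\n"), "\n")
}

#' @export
length.qdb_values <- function(x) length(x$id)

#' @export
as.data.frame.qdb_values <- function(x, ...) {
  cbind(data.frame(id = x$id, stringsAsFactors = FALSE),
        qdb_classify_value(x$value))
}

#' @export
print.qdb_values <- function(x, ...) {
  cat(sprintf("<qdb parameter table: %d row(s)>\n", length(x)))
  print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

# ---- references -----------------------------------------------------------

#' Parameter reference tables
#'
#' Bibliography references for individual parameter values: the first
#' column holds compound identifiers, the second holds BibTeX data entry
#' keys, which must resolve against the sibling `bibtex` cargo.  Values and
#' references are stored in two separate cargos (dense one-key-one-value
#' mappings are easier to process than a sparse master table).
#'
#' @inheritParams qdb_values
#' @param keys character vector of BibTeX entry keys.
#' @param refs a `qdb_references` table.
#' @param bibtex raw vector or text of the sibling BibTeX cargo.
#' @return `qdb_references()`/`qdb_parse_references()` a `qdb_references`
#'   object; `qdb_resolve_references()` a data frame of findings (zero rows
#'   iff fully resolvable) with columns `row`, `id`, `key`, `message`.
#' @export
qdb_references <- function(ids, keys) {
  ids <- as.character(ids)
  keys <- as.character(keys)
  qdb_assert(length(ids) == length(keys), "qdb_type_error",
             "ids and keys must have the same length")
  qdb_assert(!anyDuplicated(ids), "qdb_duplicate_compound_row",
             "at most one row per compound identifier")
  structure(list(id = ids, key = keys), class = "qdb_references")
}

#' @rdname qdb_references
#' @export
qdb_parse_references <- function(payload, strict = TRUE) {
  tab <- qdb_parse_values(payload, strict = strict)
  structure(list(id = tab$id, key = tab$value), class = "qdb_references")
}

#' @export
length.qdb_references <- function(x) length(x$id)

#' @rdname qdb_references
#' @export
qdb_resolve_references <- function(refs, bibtex) {
  stopifnot(inherits(refs, "qdb_references"))
  db <- qdb_parse_bibtex(bibtex)
  dup_keys <- unique(db$key[duplicated(db$key)])
  findings <- list()
  for (i in seq_along(refs$id)) {
    key <- refs$key[[i]]
    if (!key %in% db$key) {
      findings[[length(findings) + 1L]] <-
        data.frame(row = i, id = refs$id[[i]], key = key,
                   message = sprintf("row %d: key '%s' not found in BibTeX cargo", i, key),
                   stringsAsFactors = FALSE)
    } else if (key %in% dup_keys) {
      findings[[length(findings) + 1L]] <-
        data.frame(row = i, id = refs$id[[i]], key = key,
                   message = sprintf("row %d: key '%s' is ambiguous (duplicated in BibTeX cargo)", i, key),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(findings)) {
    data.frame(row = integer(), id = character(), key = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
}

# ---- bibtex ---------------------------------------------------------------

#' Parse a BibTeX database
#'
#' A deliberately shallow parser: only entry types and keys are interpreted
#' (that is all the reference-resolution contract needs); entry bodies are
#' preserved as raw text.  `@comment`, `@preamble` and `@string` directives
#' are skipped.
#'
#' @param payload raw vector or text of a BibTeX cargo.
#' @return a data frame with columns `type`, `key` and `body`.
#' @export
qdb_parse_bibtex <- function(payload) {
  text <- payload_text(payload)
  entries <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    at <- regexpr("@", substr(text, pos, n), fixed = TRUE)
    if (at < 0L) break
    pos <- pos + at - 1L
    m <- regexpr("^@\\s*([A-Za-z]+)\\s*([{(])", substr(text, pos, n), perl = TRUE)
    if (m < 0L) {
      qdb_stop("qdb_bibtex_parse_error",
               sprintf("malformed BibTeX entry at offset %d", pos), offset = pos)
    }
    head_len <- attr(m, "match.length")
    head <- substr(text, pos, pos + head_len - 1L)
    type <- tolower(gsub("^@\\s*|\\s*[{(]$", "", head))
    open <- substr(head, head_len, head_len)
    close <- if (open == "{") "}" else ")"
    # scan to the balanced closing delimiter
    depth <- 1L
    i <- pos + head_len
    while (i <= n && depth > 0L) {
      ch <- substr(text, i, i)
      if (ch == open) depth <- depth + 1L
      else if (ch == close) depth <- depth - 1L
      i <- i + 1L
    }
    if (depth != 0L) {
      qdb_stop("qdb_bibtex_parse_error",
               sprintf("unterminated BibTeX entry '%s' at offset %d", type, pos),
               offset = pos)
    }
    body <- substr(text, pos + head_len, i - 2L)
    if (!type %in% c("comment", "preamble", "string")) {
      km <- regexpr("^\\s*([^,\\s{}()]+)\\s*,", body, perl = TRUE)
      if (km < 0L) {
        qdb_stop("qdb_bibtex_parse_error",
                 sprintf("BibTeX entry '%s' at offset %d has no key", type, pos),
                 offset = pos)
      }
      key <- gsub("^\\s*|\\s*,$", "", substr(body, km, km + attr(km, "match.length") - 1L))
      entries[[length(entries) + 1L]] <-
        data.frame(type = type, key = key, body = body, stringsAsFactors = FALSE)
    }
    pos <- i
  }
  if (!length(entries)) {
    data.frame(type = character(), key = character(), body = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, entries)
  }
}

# ---- structure cargos -----------------------------------------------------

#' Cargo identifier for a chemical structure representation
#'
#' The identifier of a compound structure cargo is derived from the Chemical
#' MIME type of its content by stripping the prefix `chemical/x-`.  SMILES
#' is special: the default flavour `chemical/x-daylight-smiles` keeps its
#' full identifier, while any other (or unknown) SMILES flavour uses the
#' shorthand identifier `"smiles"`.
#'
#' @param chemical_mime a Chemical MIME type, e.g. `"chemical/x-cml"`.
#' @return a cargo identifier.
#' @examples
#' qdb_structure_cargo_id("chemical/x-cml")
#' qdb_structure_cargo_id("chemical/x-opensmiles")
#' @export
qdb_structure_cargo_id <- function(chemical_mime) {
  qdb_assert(is.character(chemical_mime) && length(chemical_mime) == 1L &&
               startsWith(chemical_mime, "chemical/x-"),
             "qdb_not_chemical_mime",
             sprintf("'%s' is not a Chemical MIME type", chemical_mime))
  id <- substring(chemical_mime, nchar("chemical/x-") + 1L)
  qdb_assert(nzchar(id) && qdb_valid_id(id), "qdb_not_chemical_mime",
             sprintf("'%s' does not yield a usable cargo identifier", chemical_mime))
  if (endsWith(id, "smiles") && id != "daylight-smiles") id <- "smiles"
  id
}

# ---- BODO -----------------------------------------------------------------

#' BODO descriptor-ontology records
#'
#' A descriptor's `bodo` cargo is a small YAML document with two named
#' fields: `ontologyReference` (the Blue Obelisk Descriptor Ontology
#' identifier) and `implementations` (a free-form list of known equivalent
#' implementations with their parameterisation, preserved on round trip).
#'
#' @param payload raw vector or YAML text.
#' @param record a list with elements `ontologyReference` and
#'   `implementations`.
#' @return `qdb_parse_bodo()` a `qdb_bodo` list; `qdb_format_bodo()` YAML
#'   text.
#' @export
qdb_parse_bodo <- function(payload) {
  text <- payload_text(payload)
  doc <- tryCatch(yaml::yaml.load(text),
                  error = function(e) qdb_stop("qdb_yaml_parse_error",
                                               paste("invalid YAML:", conditionMessage(e))))
  qdb_assert(is.list(doc), "qdb_yaml_parse_error", "BODO cargo must be a YAML mapping")
  ref <- doc[["ontologyReference"]]
  qdb_assert(!is.null(ref) && nzchar(as.character(ref)[1L]), "qdb_missing_field",
             "BODO cargo lacks the 'ontologyReference' field")
  structure(list(ontologyReference = as.character(ref)[1L],
                 implementations = doc[["implementations"]] %||% list()),
            class = "qdb_bodo")
}

#' @rdname qdb_parse_bodo
#' @export
qdb_format_bodo <- function(record) {
  qdb_assert(!is.null(record$ontologyReference), "qdb_missing_field",
             "BODO record lacks the 'ontologyReference' field")
  yaml::as.yaml(list(ontologyReference = record$ontologyReference,
                     implementations = record$implementations %||% list()))
}

# ---- UCUM -----------------------------------------------------------------

#' Read a UCUM unit cargo
#'
#' UCUM unit strings are contract strings: stored verbatim (trimmed), with
#' only a shallow syntax check (non-empty printable US-ASCII).  No unit
#' algebra or conversion is performed.
#'
#' @param payload raw vector or text.
#' @return the trimmed unit string.
#' @export
qdb_parse_ucum <- function(payload) {
  unit <- trimws(payload_text(payload))
  qdb_assert(nzchar(unit), "qdb_empty_unit", "empty UCUM unit")
  qdb_assert(!grepl("[^\x20-\x7e]", unit), "qdb_empty_unit",
             "UCUM unit must be printable US-ASCII")
  unit
}

# ---- extension identifiers ------------------------------------------------

#' Is a cargo identifier a qualified extension identifier?
#'
#' System cargos use simple one-word identifiers; extension cargos must use
#' qualified identifiers carrying a reversed-domain namespace prefix of at
#' least two labels before the final simple name (e.g. `"org.dmg.pmml"`).
#'
#' @param cargo_id a cargo identifier.
#' @param system_ids character vector of system cargo identifiers for the
#'   container type (see [qdb_system_cargos()]).
#' @return `TRUE` iff `cargo_id` is a well-formed extension identifier.
#' @export
qdb_is_extension_id <- function(cargo_id, system_ids = character()) {
  qdb_check_id(cargo_id, "cargo identifier")
  if (cargo_id %in% system_ids) return(FALSE)
  labels <- strsplit(cargo_id, ".", fixed = TRUE)[[1L]]
  length(labels) >= 3L && all(nzchar(labels))
}
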