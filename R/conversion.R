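# Conversion of tabular raw data into archives.  Every table row becomes a
# Compound; columns map onto compound attributes, structure cargos or
# parameter values/references cargos.  An optional linear regression
# equation additionally creates a Model (PMML cargo) plus the training
# Prediction, turning a spreadsheet export into a fully developed archive.

#' Column mappings for table conversion
#'
#' Three kinds of mappings are supported: compound attributes (`id`,
#' `name`, `cas`, `inchi`), compound structure cargos (the cell becomes the
#' payload of a structure cargo such as `smiles`), and parameter columns
#' (the cell becomes a row of a property's or descriptor's `values` or
#' `references` cargo).
#'
#' @param column column selector: a 1-based integer index or a header name.
#' @param kind compound attribute kind: `"id"`, `"name"`, `"cas"` or
#'   `"inchi"`.
#' @param format structure cargo identifier (e.g. `"smiles"`, `"cml"`); see
#'   [qdb_structure_cargo_id()] for the Chemical MIME mapping.
#' @param parameter_id identifier of the property or descriptor container
#'   to create.
#' @param role `"property"` or `"descriptor"`.
#' @return a `qdb_mapping` object.
#' @name qdb-mappings
NULL

new_mapping <- function(column, role, ...) {
  qdb_assert((is.numeric(column) && length(column) == 1L && column >= 1L) ||
               (is.character(column) && length(column) == 1L && nzchar(column)),
             "qdb_mapping_error", "column must be a positive index or a header name")
  structure(list(column = column, role = role, ...), class = "qdb_mapping")
}

#' @rdname qdb-mappings
#' @export
qdb_map_attribute <- function(column, kind = c("id", "name", "cas", "inchi")) {
  new_mapping(column, "attribute", kind = match.arg(kind))
}

#' @rdname qdb-mappings
#' @export
qdb_map_structure <- function(column, format = "smiles") {
  new_mapping(column, "structure", format = qdb_check_id(format, "structure cargo identifier"))
}

#' @rdname qdb-mappings
#' @export
qdb_map_values <- function(column, parameter_id, role = c("property", "descriptor")) {
  new_mapping(column, "values", parameter_id = qdb_check_id(parameter_id),
              parameter_role = match.arg(role))
}

#' @rdname qdb-mappings
#' @export
qdb_map_references <- function(column, parameter_id, role = c("property", "descriptor")) {
  new_mapping(column, "references", parameter_id = qdb_check_id(parameter_id),
              parameter_role = match.arg(role))
}

# resolve a mapping's column selector against the table
resolve_column <- function(mapping, table, headers) {
  col <- mapping$column
  if (is.character(col)) {
    i <- match(col, headers)
    qdb_assert(!is.na(i), "qdb_mapping_error",
               sprintf("no column named '%s' in the table header", col))
    return(i)
  }
  qdb_assert(col <= ncol(table), "qdb_mapping_error",
             sprintf("column index %d exceeds the table width (%d)", col, ncol(table)))
  as.integer(col)
}

#' Convert a table of raw data into an archive
#'
#' Associates every table row with a new Compound (identifier from the `id`
#' mapping if present, else sequential `"1"`, `"2"`, ...).  Attribute
#' columns fill CAS/InChI/name; structure columns become structure cargos;
#' parameter columns become Property/Descriptor containers carrying
#' `values` (or `references`) cargos over all rows.  Empty cells in a
#' values column are recorded as the abnormal value `"N/A"`, never silently
#' dropped, so the number of compounds always equals the number of data
#' rows.
#'
#' @param table a data frame or character matrix of text cells (as read
#'   from a tab- or comma-separated spreadsheet export).
#' @param mappings list of [qdb-mappings] objects.
#' @param header `TRUE`, `FALSE` or `"auto"`: is the first row a header?
#'   Under `"auto"` the first row is taken as a header iff some mapped
#'   values-column cell in it is non-numeric while at least one later cell
#'   in that column is numeric.
#' @param name,description archive descriptor attributes.
#' @return a `qdb_archive`.
#' @export
qdb_convert_table <- function(table, mappings, header = "auto",
                              name = NULL, description = NULL) {
  table <- as.matrix(table)
  storage.mode(table) <- "character"
  table[is.na(table)] <- ""
  qdb_assert(is.list(mappings) && length(mappings) > 0L &&
               all(vapply(mappings, inherits, logical(1L), "qdb_mapping")),
             "qdb_mapping_error", "mappings must be a non-empty list of qdb_mapping objects")
  n_id <- sum(vapply(mappings, function(m)
    m$role == "attribute" && m$kind == "id", logical(1L)))
  qdb_assert(n_id <= 1L, "qdb_mapping_error", "at most one id attribute mapping")

  headers <- colnames(table) %||% rep("", ncol(table))
  cols <- vapply(mappings, resolve_column, integer(1L), table, headers)

  # header auto-detection over mapped values columns
  if (identical(header, "auto")) {
    header <- FALSE
    if (nrow(table) >= 2L) {
      for (k in seq_along(mappings)) {
        if (mappings[[k]]$role != "values") next
        col <- table[, cols[[k]]]
        first_numeric <- qdb_classify_value(col[1L])$kind == "normal"
        later_numeric <- any(qdb_classify_value(col[-1L])$kind == "normal")
        if (!first_numeric && later_numeric) { header <- TRUE; break }
      }
    }
  }
  if (isTRUE(header)) {
    if (all(!nzchar(headers))) headers <- table[1L, ]
    table <- table[-1L, , drop = FALSE]
  }

  n <- nrow(table)
  id_k <- which(vapply(mappings, function(m)
    m$role == "attribute" && m$kind == "id", logical(1L)))
  ids <- if (length(id_k)) table[, cols[[id_k]]] else as.character(seq_len(n))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    qdb_stop("qdb_duplicate_compound_row",
             sprintf("duplicate compound row '%s'", dup), id = dup)
  }

  archive <- qdb_archive(name, description)

  attr_of <- function(kind) {
    k <- which(vapply(mappings, function(m)
      m$role == "attribute" && m$kind == kind, logical(1L)))
    if (length(k)) table[, cols[[k[1L]]]] else rep(NA_character_, n)
  }
  names_col <- attr_of("name"); cas_col <- attr_of("cas"); inchi_col <- attr_of("inchi")
  cell_or_null <- function(x) if (is.na(x) || !nzchar(x)) NULL else x

  structure_ks <- which(vapply(mappings, function(m) m$role == "structure", logical(1L)))
  for (i in seq_len(n)) {
    compound <- qdb_compound(ids[[i]],
                             name = cell_or_null(names_col[[i]]),
                             cas = cell_or_null(cas_col[[i]]),
                             inchi = cell_or_null(inchi_col[[i]]))
    for (k in structure_ks) {
      cell <- table[i, cols[[k]]]
      if (nzchar(cell)) {
        compound <- qdb_set_cargo(compound, mappings[[k]]$format, cell)
      }
    }
    archive <- qdb_add(archive, compound)
  }

  # one Property/Descriptor per distinct parameter id; values first, then
  # references attach to the already-created container
  for (k in seq_along(mappings)) {
    m <- mappings[[k]]
    if (!m$role %in% c("values", "references")) next
    registry <- if (m$parameter_role == "property") "properties" else "descriptors"
    if (!qdb_has(archive[[registry]], m$parameter_id)) {
      container <- if (m$parameter_role == "property") {
        qdb_property(m$parameter_id)
      } else {
        qdb_descriptor(m$parameter_id)
      }
      archive <- qdb_add(archive, container)
    }
    idx <- match(m$parameter_id, qdb_ids(archive[[registry]]))
    container <- archive[[registry]]$members[[idx]]
    cells <- table[, cols[[k]]]
    if (m$role == "values") {
      cells[!nzchar(cells)] <- "N/A"
      payload <- qdb_format_values(qdb_values(ids, cells))
      container <- qdb_set_cargo(container, "values", payload)
    } else {
      keep <- nzchar(cells)
      payload <- qdb_format_values(qdb_references(ids[keep], cells[keep]))
      container <- qdb_set_cargo(container, "references", payload)
    }
    archive[[registry]]$members[[idx]] <- container
  }
  archive
}

#' Linear regression specifications
#'
#' `qdb_regression()` builds a specification directly;
#' `qdb_parse_equation()` parses the CLI equation grammar
#' `"property_id = intercept + c1*descriptor_id1 + c2*descriptor_id2 + ..."`
#' with `*` multiplication and signed decimal coefficients (a bare
#' `descriptor_id` term means coefficient 1).
#'
#' @param property_id identifier of the modelled property.
#' @param terms named numeric vector: coefficients named by descriptor
#'   identifier.
#' @param intercept numeric scalar.
#' @param equation an equation string.
#' @return a `qdb_regression` specification.
#' @examples
#' qdb_parse_equation("p1 = 1.2 + 0.5*logp - 0.1*mw")
#' @export
qdb_regression <- function(property_id, terms = numeric(), intercept = 0) {
  qdb_check_id(property_id, "property id")
  qdb_assert(is.numeric(terms) && (length(terms) == 0L || !is.null(names(terms))),
             "qdb_type_error", "terms must be a named numeric vector")
  for (d in names(terms)) qdb_check_id(d, "descriptor id")
  structure(list(property_id = property_id,
                 terms = terms,
                 intercept = as.numeric(intercept)),
            class = "qdb_regression")
}

#' @rdname qdb_regression
#' @export
qdb_parse_equation <- function(equation) {
  qdb_assert(is.character(equation) && length(equation) == 1L,
             "qdb_type_error", "equation must be a single string")
  sides <- strsplit(equation, "=", fixed = TRUE)[[1L]]
  qdb_assert(length(sides) == 2L, "qdb_mapping_error",
             "equation must have the form 'property_id = intercept + c1*descriptor_id1 + ...'")
  property_id <- trimws(sides[[1L]])
  qdb_check_id(property_id, "property id")
  rhs <- gsub("\\s+", "", sides[[2L]])
  # split into signed terms; exponent signs ("2.5e-1") are not term
  # boundaries, so shield them before splitting and restore afterwards
  shielded <- gsub("([0-9.][eE])-", "\\1\x01", gsub("([0-9.][eE])\\+", "\\1\x02", rhs))
  pieces <- regmatches(shielded, gregexpr("[+-]?[^+-]+", shielded))[[1L]]
  pieces <- gsub("\x01", "-", gsub("\x02", "+", pieces))
  qdb_assert(length(pieces) >= 1L, "qdb_mapping_error", "empty equation right-hand side")
  intercept <- 0
  seen_intercept <- FALSE
  terms <- numeric()
  num_re <- "^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
  for (piece in pieces) {
    if (grepl(num_re, piece)) {
      qdb_assert(!seen_intercept, "qdb_mapping_error",
                 "more than one intercept term in equation")
      intercept <- as.numeric(piece)
      seen_intercept <- TRUE
    } else if (grepl("*", piece, fixed = TRUE)) {
      halves <- strsplit(piece, "*", fixed = TRUE)[[1L]]
      qdb_assert(length(halves) == 2L && grepl(num_re, halves[[1L]]),
                 "qdb_mapping_error",
                 sprintf("malformed term '%s' (expected coefficient*descriptor_id)", piece))
      terms[[qdb_check_id(halves[[2L]], "descriptor id")]] <- as.numeric(halves[[1L]])
    } else {
      sign <- if (startsWith(piece, "-")) -1 else 1
      bare <- sub("^[+-]", "", piece)
      terms[[qdb_check_id(bare, "descriptor id")]] <- sign
    }
  }
  qdb_regression(property_id, terms, intercept)
}

# next unused identifier "m1", "m2", ... in a registry
next_free_id <- function(registry, stem) {
  i <- 1L
  while (qdb_has(registry, paste0(stem, i))) i <- i + 1L
  paste0(stem, i)
}

#' Attach a regression model and its training prediction
#'
#' Adds one Model carrying the PMML cargo built from the specification, and
#' one Prediction of type `"training"` whose `values` cargo holds the
#' evaluation of the model over every compound in the archive (abnormal or
#' missing descriptor inputs yield `"N/A"`).
#'
#' @param archive a `qdb_archive` whose property and descriptor registries
#'   resolve every identifier in `spec`.
#' @param spec a [qdb_regression] specification (or an equation string).
#' @param model_id,prediction_id identifiers for the new containers
#'   (defaults: next free `"m<k>"` and `"<model_id>-training"`).
#' @param application software name/version recorded on the prediction.
#' @return the grown archive.
#' @export
qdb_attach_regression <- function(archive, spec, model_id = NULL,
                                  prediction_id = NULL,
                                  application = NULL) {
  stopifnot(inherits(archive, "qdb_archive"))
  if (is.character(spec)) spec <- qdb_parse_equation(spec)
  stopifnot(inherits(spec, "qdb_regression"))
  qdb_assert(qdb_has(archive$properties, spec$property_id), "qdb_unresolved_identifier",
             sprintf("property '%s' does not resolve in the property registry",
                     spec$property_id))
  for (d in names(spec$terms)) {
    qdb_assert(qdb_has(archive$descriptors, d), "qdb_unresolved_identifier",
               sprintf("term '%s' does not resolve in the descriptor registry (independent variables must be descriptors)", d))
  }
  model_id <- model_id %||% next_free_id(archive$models, "m")
  prediction_id <- prediction_id %||% paste0(model_id, "-training")

  term_refs <- vapply(names(spec$terms) %||% character(),
                      function(d) qdb_prefixed_id("descriptor", d), character(1L))
  pmml <- qdb_pmml(qdb_prefixed_id("property", spec$property_id),
                   unname(term_refs), unname(spec$terms), spec$intercept)
  model <- qdb_model(model_id, property_id = spec$property_id,
                     name = sprintf("Linear regression model for '%s'", spec$property_id))
  model <- qdb_set_cargo(model, "pmml", qdb_write_pmml(pmml))
  archive <- qdb_add(archive, model)

  prediction <- qdb_prediction(prediction_id, model_id = model_id,
                               type = "training", application = application,
                               name = sprintf("Training run of '%s'", model_id))
  training <- qdb_predict(archive, model_id)
  prediction <- qdb_set_cargo(prediction, "values", qdb_format_values(training))
  qdb_add(archive, prediction)
}
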