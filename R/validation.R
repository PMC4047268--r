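# Archive-wide integrity checking.  Validation is read-only and never
# throws for content problems: every defect becomes a Finding row naming
# the rule that produced it, so imperfect archives remain fully
# inspectable.  External cross-validation services (name parsing,
# structure resolution) are out of scope; only the offline-checkable parts
# of the curation workflow are implemented.

#' CAS registry number checksum
#'
#' A CAS RN has the shape `N{2,7}-NN-N`; the final digit is a check digit.
#' Counting the other digits right-to-left with positions 1, 2, ..., the
#' weighted digit sum modulo 10 must equal the check digit.
#'
#' @param casrn character vector of CAS registry numbers.
#' @return logical vector: does the check digit verify?  A value that does
#'   not even match the digit-group shape raises a `qdb_malformed_cas`
#'   error.
#' @examples
#' qdb_cas_check("50-00-0")   # formaldehyde
#' @export
qdb_cas_check <- function(casrn) {
  qdb_assert(is.character(casrn), "qdb_type_error", "casrn must be character")
  shape_ok <- grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", casrn)
  if (any(!shape_ok)) {
    qdb_stop("qdb_malformed_cas",
             sprintf("malformed CAS registry number: %s",
                     paste(sQuote(casrn[!shape_ok]), collapse = ", ")))
  }
  vapply(casrn, function(x) {
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1L]])
    n <- length(digits)
    check <- digits[n]
    base <- rev(digits[-n])            # right-to-left, positions 1..(n-1)
    sum(base * seq_along(base)) %% 10L == check
  }, logical(1L), USE.NAMES = FALSE)
}

#' Standard InChI predicate
#'
#' The Compound InChI attribute must hold a standard InChI, which starts
#' with the prefix `InChI=1S`; non-standard InChI strings (prefix
#' `InChI=1`) belong in structure cargos instead.
#'
#' @param inchi character vector.
#' @return logical vector.
#' @export
qdb_is_standard_inchi <- function(inchi) {
  if (length(inchi) == 0L) return(logical())
  !is.na(inchi) & startsWith(inchi, "InChI=1S")
}

finding <- function(severity, rule, path, message) {
  data.frame(severity = severity, rule = rule, path = path, message = message,
             stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(severity = character(), rule = character(), path = character(),
             message = character(), stringsAsFactors = FALSE)
}

# iterate (type, container) pairs over all registries
each_container <- function(archive, fn) {
  out <- list()
  for (type in .qdb_concrete) {
    for (member in qdb_registry_of(archive, type)$members) {
      out[[length(out) + 1L]] <- fn(type, member)
    }
  }
  out
}

container_path <- function(type, member) paste(qdb_subdir(type), member$id, sep = "/")

# parameter-table cargos of a container, parsed leniently; NULL if absent
lenient_table <- function(member, cargo_id, parse) {
  if (!qdb_has_cargo(member, cargo_id)) return(NULL)
  tryCatch(parse(qdb_get_cargo(member, cargo_id), strict = FALSE),
           qdb_error = function(e) NULL)
}

# ---- individual rules -----------------------------------------------------

# r1: cargos attribute <-> attached payload set equality
rule_r1 <- function(archive) {
  rows <- each_container(archive, function(type, member) {
    declared <- member$cargos
    attached <- names(member$payloads)
    missing <- setdiff(declared, attached)
    undeclared <- setdiff(attached, declared)
    rbind(
      if (length(missing))
        finding("error", "r1", container_path(type, member),
                sprintf("cargo(s) declared but not attached: %s",
                        paste(missing, collapse = ", "))),
      if (length(undeclared))
        finding("error", "r1", container_path(type, member),
                sprintf("cargo payload(s) attached but not declared: %s",
                        paste(undeclared, collapse = ", "))))
  })
  do.call(rbind, c(rows, list(no_findings())))
}

# r2: strong-relationship resolution
rule_r2 <- function(archive) {
  rows <- list()
  for (m in archive$models$members) {
    if (!qdb_has(archive$properties, m$property_id)) {
      rows[[length(rows) + 1L]] <-
        finding("error", "r2", container_path("model", m),
                sprintf("propertyId '%s' does not resolve in the property registry",
                        m$property_id))
    }
  }
  for (p in archive$predictions$members) {
    if (!qdb_has(archive$models, p$model_id)) {
      rows[[length(rows) + 1L]] <-
        finding("error", "r2", container_path("prediction", p),
                sprintf("modelId '%s' does not resolve in the model registry",
                        p$model_id))
    }
  }
  do.call(rbind, c(rows, list(no_findings())))
}

# r3: values/references row ids resolve to compounds
rule_r3 <- function(archive) {
  compound_ids <- qdb_ids(archive$compounds)
  rows <- each_container(archive, function(type, member) {
    if (!inherits(member, "qdb_parameter")) return(NULL)
    out <- list()
    for (cargo_id in c("values", "references")) {
      tab <- lenient_table(member, cargo_id,
                           if (cargo_id == "values") qdb_parse_values else qdb_parse_references)
      if (is.null(tab)) next
      dangling <- setdiff(unique(tab$id), compound_ids)
      if (length(dangling)) {
        out[[length(out) + 1L]] <-
          finding("error", "r3",
                  paste(container_path(type, member), cargo_id, sep = "/"),
                  sprintf("row id(s) do not resolve to compounds: %s",
                          paste(dangling, collapse = ", ")))
      }
    }
    do.call(rbind, c(out, list(no_findings())))
  })
  do.call(rbind, c(rows, list(no_findings())))
}

# r4: references resolve into the sibling BibTeX cargo
rule_r4 <- function(archive) {
  rows <- each_container(archive, function(type, member) {
    if (!inherits(member, "qdb_parameter")) return(NULL)
    refs <- lenient_table(member, "references", qdb_parse_references)
    if (is.null(refs) || !length(refs)) return(NULL)
    path <- paste(container_path(type, member), "references", sep = "/")
    if (!qdb_has_cargo(member, "bibtex")) {
      return(finding("error", "r4", path,
                     "references cargo present but no sibling bibtex cargo"))
    }
    hits <- tryCatch(qdb_resolve_references(refs, qdb_get_cargo(member, "bibtex")),
                     qdb_error = function(e)
                       data.frame(message = paste("bibtex cargo unparseable:",
                                                  conditionMessage(e))))
    if (!nrow(hits)) return(NULL)
    do.call(rbind, lapply(hits$message, function(msg) finding("error", "r4", path, msg)))
  })
  do.call(rbind, c(rows, list(no_findings())))
}

# r5: identifier charset + case-insensitive collisions
rule_r5 <- function(archive) {
  rows <- list()
  for (type in .qdb_concrete) {
    registry <- qdb_registry_of(archive, type)
    ids <- qdb_ids(registry)
    bad <- ids[!qdb_valid_id(ids)]
    for (id in bad) {
      rows[[length(rows) + 1L]] <-
        finding("error", "r5", paste(qdb_subdir(type), id, sep = "/"),
                "identifier violates the identifier character set")
    }
    lowered <- tolower(ids)
    clash <- ids[lowered %in% lowered[duplicated(lowered)]]
    if (length(clash)) {
      rows[[length(rows) + 1L]] <-
        finding("warning", "r5", qdb_subdir(type),
                sprintf("case-insensitive identifier collision: %s (paths would clash on case-insensitive file systems)",
                        paste(clash, collapse = ", ")))
    }
    for (member in registry$members) {
      bad_cargo <- member$cargos[!qdb_valid_id(member$cargos)]
      for (cg in bad_cargo) {
        rows[[length(rows) + 1L]] <-
          finding("error", "r5", container_path(type, member),
                  sprintf("cargo identifier '%s' violates the identifier character set", cg))
      }
    }
  }
  do.call(rbind, c(rows, list(no_findings())))
}

# r6: CAS checksum + standard InChI prefix
rule_r6 <- function(archive) {
  rows <- lapply(archive$compounds$members, function(member) {
    path <- container_path("compound", member)
    out <- list()
    if (!is.null(member$cas)) {
      ok <- tryCatch(qdb_cas_check(member$cas), qdb_error = function(e) NA)
      if (is.na(ok)) {
        out[[length(out) + 1L]] <-
          finding("error", "r6", path,
                  sprintf("CAS '%s' does not match the N{2,7}-NN-N digit-group shape", member$cas))
      } else if (!ok) {
        out[[length(out) + 1L]] <-
          finding("error", "r6", path,
                  sprintf("CAS '%s' fails the check digit", member$cas))
      }
    }
    if (!is.null(member$inchi) && !qdb_is_standard_inchi(member$inchi)) {
      out[[length(out) + 1L]] <-
        finding("error", "r6", path,
                "InChI attribute is not a standard InChI (prefix 'InChI=1S'); attach non-standard codes as structure cargos")
    }
    do.call(rbind, c(out, list(no_findings())))
  })
  do.call(rbind, c(rows, list(no_findings())))
}

# r7: Prediction.type enumeration
rule_r7 <- function(archive) {
  rows <- lapply(archive$predictions$members, function(member) {
    if (is.null(member$type) || !member$type %in% .qdb_prediction_types) {
      finding("error", "r7", container_path("prediction", member),
              sprintf("type '%s' is not one of %s",
                      member$type %||% "<missing>",
                      paste(.qdb_prediction_types, collapse = "/")))
    }
  })
  do.call(rbind, c(rows, list(no_findings())))
}

# r8: extension cargo identifiers must be qualified
rule_r8 <- function(archive) {
  rows <- each_container(archive, function(type, member) {
    system_ids <- qdb_system_cargos(type)
    out <- list()
    for (cg in member$cargos) {
      if (!qdb_valid_id(cg)) next                   # r5's business
      if (cg %in% system_ids) next
      # any simple identifier on a Compound is taken to be a structure
      # cargo (its identifier is variable by design)
      if (type == "compound" && !grepl(".", cg, fixed = TRUE)) next
      if (!qdb_is_extension_id(cg, system_ids)) {
        out[[length(out) + 1L]] <-
          finding("error", "r8", container_path(type, member),
                  sprintf("cargo '%s' is neither a system cargo nor a qualified extension identifier", cg))
      }
    }
    do.call(rbind, c(out, list(no_findings())))
  })
  do.call(rbind, c(rows, list(no_findings())))
}

# r9: PMML variable identifiers resolve with the correct registry prefix
rule_r9 <- function(archive) {
  rows <- lapply(archive$models$members, function(member) {
    if (!qdb_has_cargo(member, "pmml")) return(NULL)
    path <- paste(container_path("model", member), "pmml", sep = "/")
    model <- tryCatch(qdb_read_pmml(qdb_get_cargo(member, "pmml")),
                      qdb_error = function(e) e)
    if (inherits(model, "condition")) {
      return(finding("error", "r9", path,
                     paste("unreadable PMML cargo:", conditionMessage(model))))
    }
    out <- list()
    target <- qdb_parse_prefixed_id(model$target_ref)
    if (!qdb_has(archive$properties, target$id)) {
      out[[length(out) + 1L]] <-
        finding("error", "r9", path,
                sprintf("target '%s' does not resolve in the property registry",
                        model$target_ref))
    } else if (!identical(target$id, member$property_id)) {
      out[[length(out) + 1L]] <-
        finding("error", "r9", path,
                sprintf("target '%s' disagrees with the model's propertyId '%s'",
                        model$target_ref, member$property_id))
    }
    for (ref in model$term_refs) {
      term <- qdb_parse_prefixed_id(ref)
      if (!qdb_has(archive$descriptors, term$id)) {
        out[[length(out) + 1L]] <-
          finding("error", "r9", path,
                  sprintf("term '%s' does not resolve in the descriptor registry", ref))
      }
    }
    do.call(rbind, c(out, list(no_findings())))
  })
  do.call(rbind, c(rows, list(no_findings())))
}

# r10: duplicate rows in parameter tables
rule_r10 <- function(archive) {
  rows <- each_container(archive, function(type, member) {
    if (!inherits(member, "qdb_parameter")) return(NULL)
    out <- list()
    for (cargo_id in c("values", "references")) {
      tab <- lenient_table(member, cargo_id,
                           if (cargo_id == "values") qdb_parse_values else qdb_parse_references)
      if (is.null(tab)) next
      dup <- unique(tab$id[duplicated(tab$id)])
      if (length(dup)) {
        out[[length(out) + 1L]] <-
          finding("error", "r10",
                  paste(container_path(type, member), cargo_id, sep = "/"),
                  sprintf("duplicate row(s) for compound id(s): %s",
                          paste(dup, collapse = ", ")))
      }
    }
    do.call(rbind, c(out, list(no_findings())))
  })
  do.call(rbind, c(rows, list(no_findings())))
}

.qdb_rules <- list(r1 = rule_r1, r2 = rule_r2, r3 = rule_r3, r4 = rule_r4,
                   r5 = rule_r5, r6 = rule_r6, r7 = rule_r7, r8 = rule_r8,
                   r9 = rule_r9, r10 = rule_r10)

#' Validate an archive
#'
#' Runs every integrity rule and returns the findings (zero rows iff the
#' archive is fully valid).  Rules: `r1` cargos attribute vs attached
#' payloads; `r2` strong-relationship resolution; `r3` parameter-table row
#' ids resolve to compounds; `r4` reference keys resolve into the sibling
#' BibTeX cargo; `r5` identifier charset (error) and case-insensitive
#' collisions (warning); `r6` CAS checksum and standard-InChI prefix; `r7`
#' prediction type enumeration; `r8` unqualified extension cargo
#' identifiers; `r9` PMML variable identifiers resolve with the correct
#' registry prefix; `r10` duplicate parameter-table rows.
#'
#' @param archive a `qdb_archive`.
#' @param rules subset of rule identifiers to run (default: all).
#' @return a data frame of findings with columns `severity`
#'   (`"error"`/`"warning"`), `rule`, `path`, `message`.
#' @export
qdb_validate <- function(archive, rules = names(.qdb_rules)) {
  stopifnot(inherits(archive, "qdb_archive"))
  rules <- match.arg(rules, names(.qdb_rules), several.ok = TRUE)
  out <- lapply(.qdb_rules[rules], function(rule) rule(archive))
  out <- do.call(rbind, c(unname(out), list(no_findings())))
  rownames(out) <- NULL
  class(out) <- c("qdb_findings", "data.frame")
  out
}

#' @export
print.qdb_findings <- function(x, ...) {
  if (!nrow(x)) {
    cat("No findings: the archive is valid.\n")
  } else {
    cat(sprintf("%d finding(s): %d error(s), %d warning(s)\n",
                nrow(x), sum(x$severity == "error"), sum(x$severity == "warning")))
    print.data.frame(x)
  }
  invisible(x)
}
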