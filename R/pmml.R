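# Linear-regression PMML subset.  The writer pins one dialect (PMML 4.2);
# the reader accepts any document whose regression vocabulary matches and
# rejects every other model type loudly.  Variable names are "prefixed
# identifiers" -- the abstract archive path of the container
# ("properties/<id>", "descriptors/<id>") -- which removes any risk of
# identifier collision between the property and descriptor registries.

.pmml_xmlns <- "http://www.dmg.org/PMML-4_2"

#' Prefixed container identifiers
#'
#' Disambiguate container identifiers across registries by concatenating
#' the container type's subdirectory name with a forward slash:
#' `("property", "p1")` becomes `"properties/p1"`, identical to the
#' container's abstract path inside an archive.
#'
#' @param type a concrete container type.
#' @param id a container identifier.
#' @param prefixed a prefixed identifier, e.g. `"descriptors/logp"`.
#' @return `qdb_prefixed_id()` the prefixed identifier;
#'   `qdb_parse_prefixed_id()` a list with elements `type` and `id`.
#' @export
qdb_prefixed_id <- function(type, id) {
  type <- qdb_norm_type(type)
  qdb_check_id(id)
  paste(qdb_subdir(type), id, sep = "/")
}

#' @rdname qdb_prefixed_id
#' @export
qdb_parse_prefixed_id <- function(prefixed) {
  qdb_assert(is.character(prefixed) && length(prefixed) == 1L,
             "qdb_type_error", "prefixed identifier must be a single string")
  parts <- strsplit(prefixed, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !parts[1L] %in% unname(.qdb_subdirs) ||
      !qdb_valid_id(parts[2L])) {
    qdb_stop("qdb_invalid_identifier",
             sprintf("'%s' is not a prefixed container identifier", prefixed))
  }
  list(type = names(.qdb_subdirs)[match(parts[1L], .qdb_subdirs)], id = parts[2L])
}

#' Linear regression models for the PMML cargo
#'
#' A single-target linear model: `target = intercept + sum(coefficients *
#' terms)`.  The target must be a property; every term must be a descriptor
#' (independent variables must originate from the descriptor registry,
#' never the property registry).
#'
#' @param target_ref prefixed identifier of the modelled property
#'   (`"properties/<id>"`).
#' @param term_refs character vector of prefixed descriptor identifiers.
#' @param coefficients numeric vector, one coefficient per term.
#' @param intercept numeric scalar.
#' @return a `qdb_pmml` object.
#' @examples
#' m <- qdb_pmml("properties/p1", "descriptors/logp", 0.5, 1.2)
#' @export
qdb_pmml <- function(target_ref, term_refs = character(), coefficients = numeric(),
                     intercept = 0) {
  target <- qdb_parse_prefixed_id(target_ref)
  qdb_assert(target$type == "property", "qdb_invalid_identifier",
             "the PMML target must be a 'properties/<id>' reference")
  for (ref in term_refs) {
    term <- qdb_parse_prefixed_id(ref)
    qdb_assert(term$type == "descriptor", "qdb_invalid_identifier",
               sprintf("independent variables must originate from the descriptor registry, not '%s'", ref))
  }
  qdb_assert(length(coefficients) == length(term_refs), "qdb_type_error",
             "one coefficient per term is required")
  qdb_assert(is.numeric(intercept) && length(intercept) == 1L && is.finite(intercept),
             "qdb_type_error", "intercept must be a finite number")
  structure(list(target_ref = target_ref,
                 term_refs = as.character(term_refs),
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept)),
            class = "qdb_pmml")
}

#' @export
print.qdb_pmml <- function(x, ...) {
  rhs <- c(qdb_format_number(x$intercept),
           sprintf("%s*%s", qdb_format_number(x$coefficients), x$term_refs))
  cat(sprintf("<qdb pmml regression> %s = %s\n", x$target_ref,
              paste(rhs, collapse = " + ")))
  invisible(x)
}

#' Serialise and parse PMML regression cargos
#'
#' `qdb_write_pmml()` emits a PMML 4.2 document whose `DataDictionary`
#' lists the target and terms under their prefixed identifiers and whose
#' `RegressionModel` carries the intercept and per-term coefficients.
#' `qdb_read_pmml()` accepts any PMML version with matching regression
#' vocabulary; any other model element (a neural network, a tree, ...) is
#' rejected with an `UnsupportedModelType`-style error naming the element.
#' Coefficients survive the round trip to full double precision.
#'
#' @param model a `qdb_pmml` model.
#' @param payload raw vector or XML text.
#' @return `qdb_write_pmml()` a single XML string; `qdb_read_pmml()` a
#'   `qdb_pmml` model.
#' @export
qdb_write_pmml <- function(model) {
  stopifnot(inherits(model, "qdb_pmml"))
  doc <- xml2::xml_new_root("PMML", version = "4.2", xmlns = .pmml_xmlns)
  header <- xml2::xml_add_child(doc, "Header",
                                description = "QDB linear regression model")
  xml2::xml_add_child(header, "Application", name = "qsardb",
                      version = as.character(utils::packageVersion("qsardb")))
  fields <- c(model$target_ref, model$term_refs)
  dict <- xml2::xml_add_child(doc, "DataDictionary",
                              numberOfFields = as.character(length(fields)))
  for (f in fields) {
    xml2::xml_add_child(dict, "DataField", name = f, optype = "continuous",
                        dataType = "double")
  }
  reg <- xml2::xml_add_child(doc, "RegressionModel",
                             functionName = "regression",
                             modelName = model$target_ref)
  schema <- xml2::xml_add_child(reg, "MiningSchema")
  xml2::xml_add_child(schema, "MiningField", name = model$target_ref,
                      usageType = "target")
  for (f in model$term_refs) {
    xml2::xml_add_child(schema, "MiningField", name = f, usageType = "active")
  }
  tab <- xml2::xml_add_child(reg, "RegressionTable",
                             intercept = qdb_format_number(model$intercept))
  for (i in seq_along(model$term_refs)) {
    xml2::xml_add_child(tab, "NumericPredictor",
                        name = model$term_refs[[i]],
                        coefficient = qdb_format_number(model$coefficients[[i]]))
  }
  as.character(doc)
}

#' @rdname qdb_write_pmml
#' @export
qdb_read_pmml <- function(payload) {
  text <- payload_text(payload)
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) qdb_stop("qdb_malformed_pmml",
                                               paste("not well-formed XML:", conditionMessage(e))))
  qdb_assert(xml2::xml_name(doc) == "PMML", "qdb_malformed_pmml",
             sprintf("root element is <%s>, expected <PMML>", xml2::xml_name(doc)))
  xml2::xml_ns_strip(doc)
  kids <- xml2::xml_children(doc)
  names <- xml2::xml_name(kids)
  skeleton <- c("Header", "DataDictionary", "MiningBuildTask",
                "TransformationDictionary", "Extension")
  model_nodes <- kids[!names %in% skeleton]
  model_names <- xml2::xml_name(model_nodes)
  qdb_assert(length(model_nodes) >= 1L, "qdb_malformed_pmml",
             "document contains no model element")
  bad <- setdiff(model_names, "RegressionModel")
  if (length(bad)) {
    qdb_stop("qdb_unsupported_model_type",
             sprintf("unsupported PMML model type <%s>; only <RegressionModel> is consumed",
                     bad[[1L]]),
             element = bad[[1L]])
  }
  qdb_assert(length(model_nodes) == 1L, "qdb_malformed_pmml",
             "expected exactly one <RegressionModel> element")
  reg <- model_nodes[[1L]]
  fn <- xml2::xml_attr(reg, "functionName")
  qdb_assert(identical(fn, "regression"), "qdb_unsupported_model_type",
             sprintf("functionName '%s' is not supported", fn %||% "<missing>"))

  # every DataField name must carry a recognised registry prefix
  for (df in xml2::xml_find_all(doc, "./DataDictionary/DataField")) {
    nm <- xml2::xml_attr(df, "name")
    ok <- tryCatch({qdb_parse_prefixed_id(nm); TRUE},
                   qdb_error = function(e) FALSE)
    qdb_assert(ok, "qdb_malformed_pmml",
               sprintf("DataField name '%s' lacks a recognised registry prefix", nm %||% "<missing>"))
  }

  target_nodes <- xml2::xml_find_all(reg,
    "./MiningSchema/MiningField[@usageType='target' or @usageType='predicted']")
  qdb_assert(length(target_nodes) == 1L, "qdb_malformed_pmml",
             "expected exactly one target MiningField")
  target_ref <- xml2::xml_attr(target_nodes[[1L]], "name")

  tab <- xml2::xml_find_all(reg, "./RegressionTable")
  qdb_assert(length(tab) == 1L, "qdb_malformed_pmml",
             "expected exactly one <RegressionTable>")
  intercept <- suppressWarnings(as.numeric(xml2::xml_attr(tab[[1L]], "intercept")))
  qdb_assert(length(intercept) == 1L && !is.na(intercept), "qdb_malformed_pmml",
             "RegressionTable lacks a numeric intercept")
  preds <- xml2::xml_find_all(tab[[1L]], "./NumericPredictor")
  term_refs <- xml2::xml_attr(preds, "name")
  coefficients <- suppressWarnings(as.numeric(xml2::xml_attr(preds, "coefficient")))
  qdb_assert(!anyNA(coefficients), "qdb_malformed_pmml",
             "non-numeric coefficient in RegressionTable")
  qdb_pmml(target_ref, term_refs, coefficients, intercept)
}

#' Evaluate a regression model over descriptor values
#'
#' Computes `intercept + sum(coefficient * term)` for every compound whose
#' term values are all normal; a compound with any missing or abnormal term
#' value degrades to the abnormal value `"N/A"` (error codes are significant
#' and must not be silently dropped).
#'
#' @param model a `qdb_pmml` model.
#' @param descriptor_values a named list: compound id -> named character (or
#'   list) of raw value tokens keyed by prefixed term identifier.
#' @return a [qdb_values] table, one row per compound in input order.
#' @examples
#' m <- qdb_pmml("properties/p1", "descriptors/x", 0.5, 1.2)
#' qdb_evaluate(m, list("1" = c("descriptors/x" = "2.0"),
#'                      "2" = c("descriptors/x" = "N/A")))
#' @export
qdb_evaluate <- function(model, descriptor_values) {
  stopifnot(inherits(model, "qdb_pmml"))
  ids <- names(descriptor_values) %||% character()
  out <- vapply(seq_along(descriptor_values), function(i) {
    row <- descriptor_values[[i]]
    raw <- vapply(model$term_refs, function(ref) {
      v <- if (is.list(row)) row[[ref]] else unname(row[ref])
      if (is.null(v) || is.na(v)) NA_character_ else as.character(v)
    }, character(1L))
    if (anyNA(raw)) return("N/A")
    tok <- qdb_classify_value(raw)
    if (any(tok$kind != "normal")) return("N/A")
    qdb_format_number(model$intercept + sum(model$coefficients * tok$numeric))
  }, character(1L))
  qdb_values(ids, out)
}

#' Evaluate a model stored in an archive
#'
#' Gathers the values cargos of the model's descriptors, evaluates the PMML
#' regression over every compound in the compound registry and returns the
#' resulting parameter table.  Compounds missing from a descriptor table
#' (or with abnormal descriptor values) yield `"N/A"`.
#'
#' @param archive a `qdb_archive`.
#' @param model_id identifier of a model carrying a `pmml` cargo.
#' @return a [qdb_values] table over all compounds, in registry order.
#' @export
qdb_predict <- function(archive, model_id) {
  stopifnot(inherits(archive, "qdb_archive"))
  model_c <- qdb_get(archive$models, model_id)
  qdb_assert(qdb_has_cargo(model_c, "pmml"), "qdb_not_found",
             sprintf("model '%s' has no 'pmml' cargo", model_id))
  model <- qdb_read_pmml(qdb_get_cargo(model_c, "pmml"))
  tables <- lapply(model$term_refs, function(ref) {
    d <- qdb_parse_prefixed_id(ref)
    if (!qdb_has(archive$descriptors, d$id)) {
      qdb_stop("qdb_broken_chain",
               sprintf("PMML term '%s' does not resolve in the descriptor registry", ref))
    }
    dc <- qdb_get(archive$descriptors, d$id)
    if (!qdb_has_cargo(dc, "values")) return(NULL)
    qdb_parse_values(qdb_get_cargo(dc, "values"))
  })
  names(tables) <- model$term_refs
  ids <- qdb_ids(archive$compounds)
  rows <- lapply(ids, function(id) {
    vapply(model$term_refs, function(ref) {
      tab <- tables[[ref]]
      if (is.null(tab)) return(NA_character_)
      j <- match(id, tab$id)
      if (is.na(j)) NA_character_ else tab$value[[j]]
    }, character(1L))
  })
  names(rows) <- ids
  qdb_evaluate(model, rows)
}
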