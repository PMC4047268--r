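# The QDB type hierarchy.  This table is the single source of truth for
# schema introspection (qdb_schema), registry subdirectory names, element
# vocabulary of the XML dialect and the system-cargo sets used by the
# validator.  "structure" is a pseudo-identifier: the actual identifier of a
# Compound structure cargo is variable (derived from its Chemical MIME type).
.qdb_types <- list(
  container  = list(abstract = TRUE,  parent = NA_character_,
                    attributes = c("Id", "Name", "Description", "Labels", "Cargos"),
                    cargos = "bibtex"),
  parameter  = list(abstract = TRUE,  parent = "container",
                    attributes = character(),
                    cargos = c("ucum", "values", "references")),
  compound   = list(abstract = FALSE, parent = "container",
                    attributes = c("Cas", "Inchi"),
                    cargos = "structure"),
  property   = list(abstract = FALSE, parent = "parameter",
                    attributes = c("Endpoint", "Species"),
                    cargos = character()),
  descriptor = list(abstract = FALSE, parent = "parameter",
                    attributes = "Application",
                    cargos = "bodo"),
  model      = list(abstract = FALSE, parent = "container",
                    attributes = "PropertyId",
                    cargos = "pmml"),
  prediction = list(abstract = FALSE, parent = "parameter",
                    attributes = c("ModelId", "Application", "Type"),
                    cargos = character())
)

.qdb_concrete <- c("compound", "property", "descriptor", "model", "prediction")

.qdb_prediction_types <- c("training", "validation", "testing")

qdb_norm_type <- function(type) {
  type <- tolower(as.character(type)[1L])
  # accept the plural (subdirectory) form as well
  hit <- match(type, paste0(.qdb_concrete, "s"))
  if (!is.na(hit)) type <- .qdb_concrete[hit]
  if (type == "properties") type <- "property"
  qdb_assert(type %in% .qdb_concrete, "qdb_not_found",
             sprintf("unknown container type '%s'", type))
  type
}

# chain of ancestors, root first, excluding `type` itself
qdb_ancestors <- function(type) {
  out <- character()
  p <- .qdb_types[[type]]$parent
  while (!is.na(p)) {
    out <- c(p, out)
    p <- .qdb_types[[p]]$parent
  }
  out
}

#' System cargo identifiers of a container type
#'
#' Returns the system cargo identifiers that a container type carries, own
#' plus inherited.  The Compound structure cargo has a variable identifier
#' (derived from a Chemical MIME type) and is excluded here; see
#' [qdb_structure_cargo_id()].
#'
#' @param type a concrete container type (`"compound"`, `"property"`,
#'   `"descriptor"`, `"model"`, `"prediction"`).
#' @return character vector of cargo identifiers.
#' @export
qdb_system_cargos <- function(type) {
  type <- qdb_norm_type(type)
  ids <- unlist(lapply(c(qdb_ancestors(type), type),
                       function(t) .qdb_types[[t]]$cargos), use.names = FALSE)
  setdiff(ids, "structure")
}

#' Validate a container or cargo identifier
#'
#' Identifiers name containers and cargos and appear verbatim in archive
#' paths, so they must be safe path components: non-empty, no whitespace, no
#' path separators, and only ASCII letters, digits, dot, hyphen and
#' underscore.
#'
#' @param token character vector of candidate identifiers.
#' @return logical vector, `TRUE` where the token is a valid identifier.
#' @examples
#' qdb_valid_id(c("cmp_0", "cmp 0", "a/b"))
#' @export
qdb_valid_id <- function(token) {
  if (length(token) == 0L) return(logical())
  !is.na(token) & grepl("^[A-Za-z0-9._-]+$", token)
}

qdb_check_id <- function(id, what = "identifier") {
  qdb_assert(is.character(id) && length(id) == 1L && qdb_valid_id(id),
             "qdb_invalid_identifier",
             sprintf("invalid %s: %s", what,
                     if (is.character(id) && length(id) == 1L) sQuote(id) else "<non-string>"))
  id
}

# ---- containers -----------------------------------------------------------

new_qdb_container <- function(type, id, name, description, labels, extra) {
  qdb_check_id(id, sprintf("%s identifier", type))
  labels <- as.character(labels %||% character())
  qdb_assert(all(qdb_valid_id(labels)), "qdb_invalid_identifier",
             "labels must use the identifier character set")
  qdb_assert(!anyDuplicated(labels), "qdb_duplicate_identifier",
             sprintf("duplicate labels on container '%s'", id))
  cls <- c(paste0("qdb_", type),
           if (.qdb_types[[type]]$parent == "parameter") "qdb_parameter",
           "qdb_container")
  structure(
    c(list(id = id,
           name = qdb_chr1(name, "name"),
           description = qdb_chr1(description, "description"),
           labels = labels,
           cargos = character(),       # declared cargo identifiers, in order
           payloads = structure(list(), names = character())),  # raw payloads
      extra),
    class = cls, type = type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Container constructors
#'
#' Build the five concrete QDB container types.  All containers carry an
#' identifier, optional name/description, an ordered list of labels (plain
#' tokens used to form subsets) and cargo attachments (see
#' [qdb_set_cargo()]).  A description may embed simple markup when wrapped in
#' `<html>`...`</html>`; it is stored verbatim.
#'
#' @param id container identifier; must satisfy [qdb_valid_id()].
#' @param name short free-text description.
#' @param description longer free-text description.
#' @param labels character vector of label tokens (identifier charset,
#'   unique within the container).
#' @param cas CAS registry number (`NNNNNNN-NN-N` shape); see
#'   [qdb_cas_check()].
#' @param inchi standard InChI string (prefix `InChI=1S`).
#' @param endpoint experimental test classification of a property.
#' @param species binomial species name, optionally followed by the common
#'   name in parentheses, e.g. `"Homo sapiens (Human)"`.
#' @param application name and version of the software implementing the
#'   descriptor algorithm or the statistical technique.
#' @param property_id identifier of the modelled property (strong
#'   relationship; must resolve when added to an archive).
#' @param model_id identifier of the executed model (strong relationship).
#' @param type prediction type: `"training"`, `"validation"` or `"testing"`.
#' @return a container object (`qdb_compound`, `qdb_property`, ...), all of
#'   which inherit from class `qdb_container`.
#' @name qdb-containers
NULL

#' @rdname qdb-containers
#' @export
qdb_compound <- function(id, name = NULL, description = NULL, labels = character(),
                         cas = NULL, inchi = NULL) {
  new_qdb_container("compound", id, name, description, labels,
                    list(cas = qdb_chr1(cas, "cas"),
                         inchi = qdb_chr1(inchi, "inchi")))
}

#' @rdname qdb-containers
#' @export
qdb_property <- function(id, name = NULL, description = NULL, labels = character(),
                         endpoint = NULL, species = NULL) {
  new_qdb_container("property", id, name, description, labels,
                    list(endpoint = qdb_chr1(endpoint, "endpoint"),
                         species = qdb_chr1(species, "species")))
}

#' @rdname qdb-containers
#' @export
qdb_descriptor <- function(id, name = NULL, description = NULL, labels = character(),
                           application = NULL) {
  new_qdb_container("descriptor", id, name, description, labels,
                    list(application = qdb_chr1(application, "application")))
}

#' @rdname qdb-containers
#' @export
qdb_model <- function(id, property_id, name = NULL, description = NULL,
                      labels = character()) {
  new_qdb_container("model", id, name, description, labels,
                    list(property_id = qdb_check_id(property_id, "property id")))
}

#' @rdname qdb-containers
#' @export
qdb_prediction <- function(id, model_id, type, name = NULL, description = NULL,
                           labels = character(), application = NULL) {
  qdb_assert(is.character(type) && length(type) == 1L &&
               type %in% .qdb_prediction_types,
             "qdb_type_error",
             sprintf("prediction type must be one of %s",
                     paste(sQuote(.qdb_prediction_types), collapse = ", ")))
  new_qdb_container("prediction", id, name, description, labels,
                    list(model_id = qdb_check_id(model_id, "model id"),
                         application = qdb_chr1(application, "application"),
                         type = type))
}

qdb_container_type <- function(x) attr(x, "type")

# ---- cargo attachments ----------------------------------------------------

as_payload <- function(payload) {
  if (is.character(payload)) payload <- charToRaw(paste(payload, collapse = "\n"))
  qdb_assert(is.raw(payload), "qdb_type_error",
             "a cargo payload must be a raw vector or a character string")
  payload
}

#' Attach, read or remove cargo payloads
#'
#' A cargo is a named document attachment on a container.  The container
#' keeps both the declared cargo identifier list (the `Cargos` attribute,
#' serialised into the registry XML) and the payload bytes; the API keeps the
#' two in sync, and [qdb_validate()] rule `r1` reports archives where they
#' have drifted apart.
#'
#' @param container a `qdb_container`.
#' @param cargo_id cargo identifier (system identifiers are single words;
#'   extension identifiers must be qualified, e.g. `"org.dmg.pmml"`).
#' @param payload raw vector, or character (encoded as UTF-8 text).
#' @return `qdb_set_cargo()` and `qdb_delete_cargo()` return the modified
#'   container; `qdb_get_cargo()` returns a raw vector (or character when
#'   `as = "character"`); `qdb_has_cargo()` returns a logical.
#' @export
qdb_set_cargo <- function(container, cargo_id, payload) {
  stopifnot(inherits(container, "qdb_container"))
  qdb_check_id(cargo_id, "cargo identifier")
  if (!cargo_id %in% container$cargos) {
    container$cargos <- c(container$cargos, cargo_id)
  }
  container$payloads[[cargo_id]] <- as_payload(payload)
  # keep payload order aligned with the declared order
  container$payloads <- container$payloads[container$cargos]
  container
}

#' @rdname qdb_set_cargo
#' @param as return type for `qdb_get_cargo()`: `"raw"` or `"character"`.
#' @export
qdb_get_cargo <- function(container, cargo_id, as = c("raw", "character")) {
  stopifnot(inherits(container, "qdb_container"))
  as <- match.arg(as)
  payload <- container$payloads[[cargo_id]]
  qdb_assert(!is.null(payload), "qdb_not_found",
             sprintf("container '%s' has no cargo '%s'", container$id, cargo_id))
  if (as == "character") rawToChar(payload) else payload
}

#' @rdname qdb_set_cargo
#' @export
qdb_has_cargo <- function(container, cargo_id) {
  inherits(container, "qdb_container") && cargo_id %in% names(container$payloads)
}

#' @rdname qdb_set_cargo
#' @export
qdb_delete_cargo <- function(container, cargo_id) {
  stopifnot(inherits(container, "qdb_container"))
  container$cargos <- setdiff(container$cargos, cargo_id)
  container$payloads[[cargo_id]] <- NULL
  container
}

# ---- registries -----------------------------------------------------------

#' Container registries
#'
#' A registry is an ordered list of containers of one type whose identifiers
#' are unique (exact match).  Ordering is preserved across save/load.
#'
#' @param type a concrete container type.
#' @param registry a `qdb_registry`.
#' @param container a container of the registry's type.
#' @param id a container identifier.
#' @return `qdb_registry()` a new empty registry; `qdb_add()` the grown
#'   registry/archive; `qdb_ids()` the member identifiers in order;
#'   `qdb_get()` a member or an error.
#' @export
qdb_registry <- function(type) {
  type <- qdb_norm_type(type)
  structure(list(type = type, members = list()), class = "qdb_registry")
}

#' @rdname qdb_registry
#' @export
qdb_ids <- function(registry) {
  stopifnot(inherits(registry, "qdb_registry"))
  vapply(registry$members, `[[`, character(1L), "id")
}

#' @rdname qdb_registry
#' @export
qdb_get <- function(registry, id) {
  stopifnot(inherits(registry, "qdb_registry"))
  i <- match(id, qdb_ids(registry))
  qdb_assert(!is.na(i), "qdb_not_found",
             sprintf("no %s with identifier '%s'", registry$type, id))
  registry$members[[i]]
}

qdb_has <- function(registry, id) id %in% qdb_ids(registry)

#' @rdname qdb_registry
#' @param x a registry or an archive (for an archive the target registry is
#'   chosen from the container's type).
#' @export
qdb_add <- function(x, container) UseMethod("qdb_add")

#' @export
qdb_add.qdb_registry <- function(x, container) {
  qdb_assert(inherits(x, "qdb_registry") && inherits(container, "qdb_container"),
             "qdb_type_error", "qdb_add() expects a registry and a container")
  qdb_assert(identical(qdb_container_type(container), x$type), "qdb_type_error",
             sprintf("cannot add a %s to the %s registry",
                     qdb_container_type(container), x$type))
  qdb_check_id(container$id, sprintf("%s identifier", x$type))
  qdb_assert(!qdb_has(x, container$id), "qdb_duplicate_identifier",
             sprintf("duplicate %s identifier '%s'", x$type, container$id))
  x$members <- c(x$members, list(container))
  x
}

#' @export
length.qdb_registry <- function(x) length(x$members)

#' @export
print.qdb_registry <- function(x, ...) {
  cat(sprintf("<qdb %s registry: %d member(s)>\n", x$type, length(x)))
  if (length(x)) cat(" ", paste(qdb_ids(x), collapse = ", "), "\n")
  invisible(x)
}

# ---- archive --------------------------------------------------------------

.qdb_registry_field <- c(compound = "compounds", property = "properties",
                         descriptor = "descriptors", model = "models",
                         prediction = "predictions")

#' Create an in-memory QDB archive
#'
#' The archive is the root object: a name, a description (both "by humans
#' for humans") and one registry per concrete container type.  Registries
#' may be empty but are always present in memory; empty registries are
#' simply omitted from storage.
#'
#' @param name short free-text description, ideally one sentence (for
#'   published work, the article title).
#' @param description longer free-text description.
#' @return a `qdb_archive`.
#' @examples
#' a <- qdb_archive("Toy data set")
#' a <- qdb_add(a, qdb_compound("1", cas = "50-00-0"))
#' a <- qdb_add(a, qdb_property("p1", endpoint = "Acute toxicity"))
#' qdb_ids(a$compounds)
#' @export
qdb_archive <- function(name = NULL, description = NULL) {
  a <- c(list(name = qdb_chr1(name, "name"),
              description = qdb_chr1(description, "description")),
         lapply(stats::setNames(.qdb_concrete, .qdb_registry_field), qdb_registry),
         list(extras = structure(list(), names = character())))
  structure(a, class = "qdb_archive")
}

qdb_registry_of <- function(archive, type) {
  archive[[.qdb_registry_field[[qdb_norm_type(type)]]]]
}

#' @export
qdb_add.qdb_archive <- function(x, container) {
  qdb_assert(inherits(container, "qdb_container"), "qdb_type_error",
             "qdb_add() expects a container")
  type <- qdb_container_type(container)
  field <- .qdb_registry_field[[type]]
  x[[field]] <- qdb_add(x[[field]], container)
  x
}

#' Remove a container, enforcing strong relationships
#'
#' Strong relationships (Property <- Model <- Prediction) are declared
#' through container attributes and enforced for consistency: a container on
#' the left-hand side of a strong relationship cannot be removed while a
#' right-hand side still references it.  Weak relationships (compound
#' identifiers inside parameter-table cargos) never block removal; the
#' dangling rows are reported by [qdb_validate()] instead.
#'
#' @param archive a `qdb_archive`.
#' @param type container type of the victim.
#' @param id identifier of the victim.
#' @return the archive without the container.
#' @export
qdb_remove <- function(archive, type, id) {
  stopifnot(inherits(archive, "qdb_archive"))
  type <- qdb_norm_type(type)
  reg <- qdb_registry_of(archive, type)
  qdb_assert(qdb_has(reg, id), "qdb_not_found",
             sprintf("no %s with identifier '%s'", type, id))
  dependents <- switch(type,
    property = qdb_ids(archive$models)[
      vapply(archive$models$members, function(m) identical(m$property_id, id), logical(1L))],
    model = qdb_ids(archive$predictions)[
      vapply(archive$predictions$members, function(p) identical(p$model_id, id), logical(1L))],
    character())
  if (length(dependents)) {
    qdb_stop("qdb_relationship_violation",
             sprintf("cannot remove %s '%s': referenced by %s", type, id,
                     paste(sQuote(dependents), collapse = ", ")),
             dependents = dependents)
  }
  field <- .qdb_registry_field[[type]]
  keep <- qdb_ids(reg) != id
  archive[[field]]$members <- reg$members[keep]
  archive
}

#' Resolve the strong-relationship chain of a prediction
#'
#' A Prediction deliberately has no property identifier of its own: one must
#' first jump from Prediction to Model and then from Model to Property.
#'
#' @param archive a `qdb_archive`.
#' @param prediction_id identifier of a prediction.
#' @return a list with elements `prediction`, `model` and `property`.
#' @export
qdb_resolve_prediction <- function(archive, prediction_id) {
  stopifnot(inherits(archive, "qdb_archive"))
  qdb_assert(qdb_has(archive$predictions, prediction_id), "qdb_not_found",
             sprintf("no prediction with identifier '%s'", prediction_id))
  prediction <- qdb_get(archive$predictions, prediction_id)
  if (!qdb_has(archive$models, prediction$model_id)) {
    qdb_stop("qdb_broken_chain",
             sprintf("prediction '%s' references missing model '%s'",
                     prediction_id, prediction$model_id))
  }
  model <- qdb_get(archive$models, prediction$model_id)
  if (!qdb_has(archive$properties, model$property_id)) {
    qdb_stop("qdb_broken_chain",
             sprintf("model '%s' references missing property '%s'",
                     model$id, model$property_id))
  }
  list(prediction = prediction, model = model,
       property = qdb_get(archive$properties, model$property_id))
}

#' Introspect the container type hierarchy
#'
#' Reports, for every type in the implemented hierarchy, its own and
#' inherited attributes and system cargos.  Counts are derived from the type
#' table that also drives serialisation, so they always reflect the code.
#'
#' @return a named list, one entry per type, each with `abstract`, `parent`,
#'   `own_attributes`, `inherited_attributes`, `own_cargos`,
#'   `inherited_cargos`; plus an attribute `concrete` naming the concrete
#'   types.
#' @export
qdb_schema <- function() {
  out <- lapply(names(.qdb_types), function(type) {
    anc <- qdb_ancestors(type)
    def <- .qdb_types[[type]]
    list(abstract = def$abstract,
         parent = def$parent,
         own_attributes = def$attributes,
         inherited_attributes = unlist(lapply(anc, function(t) .qdb_types[[t]]$attributes),
                                       use.names = FALSE) %||% character(),
         own_cargos = def$cargos,
         inherited_cargos = unlist(lapply(anc, function(t) .qdb_types[[t]]$cargos),
                                   use.names = FALSE) %||% character())
  })
  names(out) <- names(.qdb_types)
  attr(out, "concrete") <- .qdb_concrete
  out
}

#' @export
print.qdb_archive <- function(x, ...) {
  cat("<qdb archive>", if (!is.null(x$name)) sQuote(x$name), "\n")
  for (field in .qdb_registry_field) {
    cat(sprintf("  %-12s %d\n", field, length(x[[field]])))
  }
  if (length(x$extras)) {
    cat("  extras      ", paste(names(x$extras), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.qdb_container <- function(x, ...) {
  cat(sprintf("<qdb %s '%s'>", qdb_container_type(x), x$id))
  if (!is.null(x$name)) cat(" ", x$name)
  cat("\n")
  if (length(x$labels)) cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  if (length(x$cargos)) cat("  cargos:", paste(x$cargos, collapse = ", "), "\n")
  invisible(x)
}
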