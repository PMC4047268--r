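# Storage backends.  The QDB format is storage independent: both backends
# produce identical relative paths with '/' separators; a ZIP archive is
# just the directory tree's entries.  The registry XML dialect written here
# uses lowercase attribute names nested under a per-type element, in a
# versioned namespace; the acceptance surface is round-trip fidelity plus
# the path conventions, which the format fixes exactly.

.qdb_xmlns <- "urn:qsardb:schema:1.0"

.qdb_subdirs <- c(compound = "compounds", property = "properties",
                  descriptor = "descriptors", model = "models",
                  prediction = "predictions")

# fixed mtime stamped onto staged files so ZIP output is reproducible
# byte-for-byte given the same content
.qdb_zip_epoch <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")

#' QDB archive path conventions
#'
#' Pure path arithmetic, identical across backends and platforms.  The
#' archive descriptor lives at `archive.xml`; each container type owns a
#' subdirectory named by the plural of the lowercase type name; the registry
#' file is `<subdir>/<subdir>.xml`; a cargo lives at
#' `<subdir>/<containerId>/<cargoId>`.
#'
#' @param type a concrete container type.
#' @param container_id,cargo_id identifiers (must satisfy
#'   [qdb_valid_id()]).
#' @return a relative path with `/` separators.
#' @examples
#' qdb_subdir("compound")
#' qdb_registry_path("compound")
#' qdb_cargo_path("compound", "1", "smiles")
#' @export
qdb_subdir <- function(type) {
  unname(.qdb_subdirs[[qdb_norm_type(type)]])
}

#' @rdname qdb_subdir
#' @export
qdb_registry_path <- function(type) {
  subdir <- qdb_subdir(type)
  paste0(subdir, "/", subdir, ".xml")
}

#' @rdname qdb_subdir
#' @export
qdb_cargo_path <- function(type, container_id, cargo_id) {
  paste(qdb_subdir(type), qdb_check_id(container_id, "container identifier"),
        qdb_check_id(cargo_id, "cargo identifier"), sep = "/")
}

# ---- XML dialect ----------------------------------------------------------

# element name for an attribute: lowercase of the schema attribute name
attr_element <- function(attribute) tolower(attribute)

# list field name on the container object for a schema attribute
attr_field <- function(attribute) {
  c(Id = "id", Name = "name", Description = "description",
    Cas = "cas", Inchi = "inchi", Endpoint = "endpoint", Species = "species",
    Application = "application", PropertyId = "property_id",
    ModelId = "model_id", Type = "type")[[attribute]]
}

container_attributes <- function(type) {
  anc <- qdb_ancestors(type)
  unlist(lapply(c(anc, type), function(t) .qdb_types[[t]]$attributes),
         use.names = FALSE)
}

write_archive_xml <- function(archive) {
  doc <- xml2::xml_new_root("archive", xmlns = .qdb_xmlns)
  xml2::xml_add_child(doc, "name", archive$name %||% "")
  xml2::xml_add_child(doc, "description", archive$description %||% "")
  as.character(doc)
}

read_archive_xml <- function(text, path = "archive.xml") {
  doc <- tryCatch(xml2::read_xml(text), error = function(e) {
    qdb_stop("qdb_parse_error",
             sprintf("%s: not well-formed XML (%s)", path, conditionMessage(e)),
             path = path)
  })
  xml2::xml_ns_strip(doc)
  qdb_assert(xml2::xml_name(doc) == "archive", "qdb_parse_error",
             sprintf("%s: root element is <%s>, expected <archive>", path,
                     xml2::xml_name(doc)))
  list(name = qdb_chr1(xml_text_or_null(doc, "name"), "name"),
       description = qdb_chr1(xml_text_or_null(doc, "description"), "description"))
}

xml_text_or_null <- function(node, element) {
  hit <- xml2::xml_find_first(node, paste0("./", element))
  if (inherits(hit, "xml_missing")) NULL else xml2::xml_text(hit)
}

write_registry_xml <- function(registry) {
  subdir <- qdb_subdir(registry$type)
  doc <- xml2::xml_new_root(subdir, xmlns = .qdb_xmlns)
  for (member in registry$members) {
    node <- xml2::xml_add_child(doc, registry$type)
    for (attribute in container_attributes(registry$type)) {
      if (attribute == "Labels") {
        if (length(member$labels)) {
          labels <- xml2::xml_add_child(node, "labels")
          for (l in member$labels) xml2::xml_add_child(labels, "label", l)
        }
      } else if (attribute == "Cargos") {
        if (length(member$cargos)) {
          cargos <- xml2::xml_add_child(node, "cargos")
          for (cg in member$cargos) xml2::xml_add_child(cargos, "cargo", cg)
        }
      } else {
        field <- attr_field(attribute)
        if (!is.null(member[[field]])) {
          xml2::xml_add_child(node, attr_element(attribute), member[[field]])
        }
      }
    }
  }
  as.character(doc)
}

read_registry_xml <- function(text, type, path = qdb_registry_path(type)) {
  doc <- tryCatch(xml2::read_xml(text), error = function(e) {
    qdb_stop("qdb_parse_error",
             sprintf("%s: not well-formed XML (%s)", path, conditionMessage(e)),
             path = path)
  })
  xml2::xml_ns_strip(doc)
  qdb_assert(xml2::xml_name(doc) == qdb_subdir(type), "qdb_parse_error",
             sprintf("%s: root element is <%s>, expected <%s>", path,
                     xml2::xml_name(doc), qdb_subdir(type)))
  registry <- qdb_registry(type)
  for (node in xml2::xml_find_all(doc, paste0("./", type))) {
    id <- xml_text_or_null(node, "id")
    qdb_assert(!is.null(id), "qdb_parse_error",
               sprintf("%s: container without <id>", path))
    labels <- xml2::xml_text(xml2::xml_find_all(node, "./labels/label"))
    cargos <- xml2::xml_text(xml2::xml_find_all(node, "./cargos/cargo"))
    container <- switch(type,
      compound = qdb_compound(id,
        name = xml_text_or_null(node, "name"),
        description = xml_text_or_null(node, "description"),
        labels = labels,
        cas = xml_text_or_null(node, "cas"),
        inchi = xml_text_or_null(node, "inchi")),
      property = qdb_property(id,
        name = xml_text_or_null(node, "name"),
        description = xml_text_or_null(node, "description"),
        labels = labels,
        endpoint = xml_text_or_null(node, "endpoint"),
        species = xml_text_or_null(node, "species")),
      descriptor = qdb_descriptor(id,
        name = xml_text_or_null(node, "name"),
        description = xml_text_or_null(node, "description"),
        labels = labels,
        application = xml_text_or_null(node, "application")),
      model = qdb_model(id,
        property_id = xml_text_or_null(node, "propertyid") %||% "",
        name = xml_text_or_null(node, "name"),
        description = xml_text_or_null(node, "description"),
        labels = labels),
      prediction = {
        # construct with a placeholder type, then restore the stored value
        # verbatim: an out-of-enum type must not block loading (the
        # validator reports it as rule r7)
        p <- qdb_prediction(id,
          model_id = xml_text_or_null(node, "modelid") %||% "",
          type = "training",
          name = xml_text_or_null(node, "name"),
          description = xml_text_or_null(node, "description"),
          labels = labels,
          application = xml_text_or_null(node, "application"))
        p$type <- xml_text_or_null(node, "type")
        p
      })
    container$cargos <- cargos
    registry <- qdb_add(registry, container)
  }
  registry
}

# ---- integrity checks before save ----------------------------------------

check_saveable <- function(archive) {
  stopifnot(inherits(archive, "qdb_archive"))
  for (m in archive$models$members) {
    qdb_assert(qdb_has(archive$properties, m$property_id), "qdb_integrity_error",
               sprintf("model '%s' references missing property '%s'", m$id, m$property_id))
  }
  for (p in archive$predictions$members) {
    qdb_assert(qdb_has(archive$models, p$model_id), "qdb_integrity_error",
               sprintf("prediction '%s' references missing model '%s'", p$id, p$model_id))
  }
  for (type in .qdb_concrete) {
    for (c in qdb_registry_of(archive, type)$members) {
      if (!setequal(c$cargos, names(c$payloads))) {
        qdb_stop("qdb_integrity_error",
                 sprintf("%s '%s': cargos attribute (%s) disagrees with attached payloads (%s)",
                         type, c$id,
                         paste(c$cargos, collapse = ","),
                         paste(names(c$payloads), collapse = ",")))
      }
    }
  }
  invisible(TRUE)
}

# ordered relative paths + content writer; shared by both backends
archive_entries <- function(archive) {
  entries <- list(list(path = "archive.xml",
                       bytes = charToRaw(write_archive_xml(archive))))
  for (type in .qdb_concrete) {
    registry <- qdb_registry_of(archive, type)
    if (!length(registry)) next
    entries[[length(entries) + 1L]] <-
      list(path = qdb_registry_path(type),
           bytes = charToRaw(write_registry_xml(registry)))
  }
  cargo_entries <- list()
  for (type in .qdb_concrete) {
    registry <- qdb_registry_of(archive, type)
    for (member in registry$members) {
      for (cargo_id in names(member$payloads)) {
        cargo_entries[[length(cargo_entries) + 1L]] <-
          list(path = qdb_cargo_path(type, member$id, cargo_id),
               bytes = member$payloads[[cargo_id]])
      }
    }
  }
  if (length(cargo_entries)) {
    ord <- order(vapply(cargo_entries, `[[`, character(1L), "path"), method = "radix")
    entries <- c(entries, cargo_entries[ord])
  }
  if (length(archive$extras)) {
    for (path in sort(names(archive$extras), method = "radix")) {
      entries[[length(entries) + 1L]] <-
        list(path = path, bytes = archive$extras[[path]])
    }
  }
  entries
}

#' Save an archive to a directory or ZIP file
#'
#' The backend is chosen from the target path: a path ending in `.zip`
#' (recommended: the two-level extension `.qdb.zip`) selects the ZIP
#' backend, anything else a directory tree.  Only non-empty registries are
#' written, so a raw data set lists two or three root subdirectories while a
#' fully developed archive lists all five.  Existing content at the target
#' is replaced atomically (staged in a temporary sibling, then swapped).
#' ZIP output is reproducible byte-for-byte for identical content: entries
#' are ordered (`archive.xml`, registries, cargos sorted by path, extras)
#' and carry a fixed timestamp.
#'
#' @param archive a `qdb_archive` whose strong relationships resolve and
#'   whose cargo declarations match the attached payloads.
#' @param path target directory or `*.zip` file.
#' @return `path`, invisibly.
#' @export
qdb_save <- function(archive, path) {
  check_saveable(archive)
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    qdb_save_zip(archive, path)
  } else {
    qdb_save_dir(archive, path)
  }
  invisible(path)
}

stage_archive <- function(archive, staging) {
  entries <- archive_entries(archive)
  for (entry in entries) {
    target <- file.path(staging, entry$path)
    dir.create(dirname(target), recursive = TRUE, showWarnings = FALSE)
    writeBin(entry$bytes, target)
  }
  vapply(entries, `[[`, character(1L), "path")
}

qdb_save_dir <- function(archive, path) {
  parent <- dirname(normalizePath(path, mustWork = FALSE))
  qdb_assert(dir.exists(parent), "qdb_storage_error",
             sprintf("parent directory '%s' does not exist", parent))
  staging <- tempfile(".qdb-staging-", tmpdir = parent)
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  stage_archive(archive, staging)
  if (file.exists(path)) unlink(path, recursive = TRUE)
  qdb_assert(file.rename(staging, path), "qdb_storage_error",
             sprintf("could not move staged archive into place at '%s'", path))
  invisible(path)
}

qdb_save_zip <- function(archive, path) {
  staging <- tempfile("qdb-zip-staging-")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  paths <- stage_archive(archive, staging)
  Sys.setFileTime(file.path(staging, paths), .qdb_zip_epoch)
  tmp_zip <- tempfile("qdb-", fileext = ".zip")
  zip::zip(tmp_zip, files = paths, root = staging, mode = "mirror",
           include_directories = FALSE)
  if (file.exists(path)) unlink(path)
  if (!suppressWarnings(file.rename(tmp_zip, path))) {
    qdb_assert(file.copy(tmp_zip, path, overwrite = TRUE), "qdb_storage_error",
               sprintf("could not write ZIP archive '%s'", path))
    unlink(tmp_zip)
  }
  invisible(path)
}

#' Load an archive from a directory or ZIP file
#'
#' The inverse of [qdb_save()]: `load(save(A))` is structurally equal to
#' `A`, including registry ordering and cargo bytes.  Unrecognised files at
#' the archive root or inside registry subdirectories (e.g. `license.txt`)
#' are preserved verbatim as unofficial extensions and written back on
#' save.  Cargo payloads found on disk are attached even when they are not
#' declared in the container's cargos attribute (and vice versa), so that
#' imperfect archives remain inspectable; [qdb_validate()] reports the
#' drift.
#'
#' @param path a directory containing `archive.xml`, or a `*.zip` file.
#' @return a `qdb_archive`.
#' @export
qdb_load <- function(path) {
  qdb_assert(file.exists(path), "qdb_storage_error",
             sprintf("'%s' does not exist", path))
  if (!dir.exists(path)) {
    staging <- tempfile("qdb-unzip-")
    dir.create(staging)
    on.exit(unlink(staging, recursive = TRUE), add = TRUE)
    zip::unzip(path, exdir = staging)
    return(qdb_load_dir(staging))
  }
  qdb_load_dir(path)
}

read_file <- function(path) readBin(path, what = "raw", n = file.size(path))

qdb_load_dir <- function(root) {
  descriptor <- file.path(root, "archive.xml")
  qdb_assert(file.exists(descriptor), "qdb_missing_descriptor",
             sprintf("'%s' does not contain an archive descriptor (archive.xml)", root))
  meta <- read_archive_xml(rawToChar(read_file(descriptor)))
  archive <- qdb_archive(meta$name, meta$description)

  claimed <- "archive.xml"
  for (type in .qdb_concrete) {
    subdir <- qdb_subdir(type)
    reg_path <- qdb_registry_path(type)
    reg_file <- file.path(root, reg_path)
    if (!file.exists(reg_file)) next
    claimed <- c(claimed, reg_path)
    registry <- read_registry_xml(rawToChar(read_file(reg_file)), type, reg_path)
    # attach every payload found in the container's cargo directory
    for (i in seq_along(registry$members)) {
      member <- registry$members[[i]]
      cargo_dir <- file.path(root, subdir, member$id)
      found <- if (dir.exists(cargo_dir)) {
        sort(list.files(cargo_dir, all.files = FALSE), method = "radix")
      } else character()
      # keep declared order for declared cargos, append undeclared ones
      found <- c(intersect(member$cargos, found), setdiff(found, member$cargos))
      for (cargo_id in found) {
        member$payloads[[cargo_id]] <- read_file(file.path(cargo_dir, cargo_id))
        claimed <- c(claimed, paste(subdir, member$id, cargo_id, sep = "/"))
      }
      registry$members[[i]] <- member
    }
    archive[[.qdb_registry_field[[type]]]] <- registry
  }

  # everything else is an unofficial extension, preserved verbatim
  all_files <- list.files(root, recursive = TRUE, all.files = FALSE)
  extras <- setdiff(all_files, claimed)
  for (path in sort(extras, method = "radix")) {
    archive$extras[[path]] <- read_file(file.path(root, path))
  }
  archive
}

#' Pack a directory archive into a ZIP file, or unpack one
#'
#' Thin round-trip helpers over [qdb_load()] and [qdb_save()].
#'
#' @param dir archive directory.
#' @param zipfile target/source `*.qdb.zip` file.
#' @return the target path, invisibly.
#' @export
qdb_pack <- function(dir, zipfile) {
  qdb_save_zip(qdb_load(dir), zipfile)
  invisible(zipfile)
}

#' @rdname qdb_pack
#' @export
qdb_unpack <- function(zipfile, dir) {
  qdb_save_dir(qdb_load(zipfile), dir)
  invisible(dir)
}
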