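toy_table <- function() {
  rbind(c("50-00-0", "C=O",      "5.24"),
        c("74-82-8", "C",        ""),
        c("64-17-5", "CCO",      "3.1"))
}

test_that("a (cas, smiles, property) table becomes a raw archive", {
  archive <- qdb_convert_table(toy_table(), list(
    qdb_map_attribute(1, "cas"),
    qdb_map_structure(2, "smiles"),
    qdb_map_values(3, "pLC50", "property")))
  expect_length(archive$compounds, 3L)
  expect_length(archive$properties, 1L)
  expect_identical(qdb_ids(archive$compounds), c("1", "2", "3"))
  expect_identical(qdb_get(archive$compounds, "1")$cas, "50-00-0")
  for (id in c("1", "2", "3")) {
    expect_true(qdb_has_cargo(qdb_get(archive$compounds, id), "smiles"))
  }
  # empty cell recorded as abnormal "N/A", never skipped
  values <- qdb_parse_values(qdb_get_cargo(qdb_get(archive$properties, "pLC50"), "values"))
  expect_identical(values$value, c("5.24", "N/A", "3.1"))
  # raw archives list two root subdirectories
  d <- withr::local_tempdir()
  qdb_save(archive, file.path(d, "raw"))
  expect_setequal(list.files(file.path(d, "raw")),
                  c("archive.xml", "compounds", "properties"))
})

test_that("id mappings, headers and duplicates behave per contract", {
  tab <- rbind(c("id", "pLC50"),
               c("cmp1", "1.0"),
               c("cmp2", "2.0"))
  archive <- qdb_convert_table(tab, list(
    qdb_map_attribute(1, "id"),
    qdb_map_values(2, "p", "property")))  # header auto-detected
  expect_identical(qdb_ids(archive$compounds), c("cmp1", "cmp2"))

  dup <- rbind(c("cmp1", "1.0"), c("cmp1", "2.0"))
  expect_qdb_error(
    qdb_convert_table(dup, list(qdb_map_attribute(1, "id"),
                                qdb_map_values(2, "p", "property")),
                      header = FALSE),
    "qdb_duplicate_compound_row")

  expect_qdb_error(
    qdb_convert_table(dup, list(qdb_map_values(5, "p", "property"))),
    "qdb_mapping_error")
})

test_that("conversion is deterministic and conserves rows", {
  maps <- list(qdb_map_attribute(1, "cas"),
               qdb_map_structure(2, "smiles"),
               qdb_map_values(3, "pLC50", "property"))
  d <- withr::local_tempdir()
  qdb_save(qdb_convert_table(toy_table(), maps), file.path(d, "a"))
  qdb_save(qdb_convert_table(toy_table(), maps), file.path(d, "b"))
  files <- list.files(file.path(d, "a"), recursive = TRUE)
  expect_setequal(files, list.files(file.path(d, "b"), recursive = TRUE))
  for (f in files) {
    expect_identical(readBin(file.path(d, "a", f), "raw", file.size(file.path(d, "a", f))),
                     readBin(file.path(d, "b", f), "raw", file.size(file.path(d, "b", f))))
  }

  set.seed(33)
  for (n in c(1L, 5L, 17L)) {
    tab <- cbind(sprintf("c%d", seq_len(n)), qdb_format_number(runif(n)))
    a <- qdb_convert_table(tab, list(qdb_map_attribute(1, "id"),
                                     qdb_map_values(2, "y", "property")),
                           header = FALSE)
    expect_length(a$compounds, n)  # row-count conservation
  }
})

test_that("the equation grammar parses signed coefficients", {
  spec <- qdb_parse_equation("p1 = 1.2 + 0.5*logp - 0.1*mw")
  expect_identical(spec$property_id, "p1")
  expect_equal(spec$intercept, 1.2)
  expect_equal(spec$terms, c(logp = 0.5, mw = -0.1))

  bare <- qdb_parse_equation("y = -2.5e-1 + logp")
  expect_equal(bare$intercept, -0.25)
  expect_equal(bare$terms, c(logp = 1))

  expect_qdb_error(qdb_parse_equation("no equals sign"), "qdb_mapping_error")
  expect_qdb_error(qdb_parse_equation("p = 1 + 2"), "qdb_mapping_error")
  expect_qdb_error(qdb_parse_equation("p = logp*0.5*x"), "qdb_mapping_error")
})

test_that("attach_regression builds the model and training prediction", {
  archive <- qdb_convert_table(rbind(c("1", "C", "2.0", "1.0"),
                                     c("2", "CC", "3.0", "2.0"),
                                     c("3", "CCO", "4.5", "3.0")),
                               list(qdb_map_attribute(1, "id"),
                                    qdb_map_structure(2, "smiles"),
                                    qdb_map_values(3, "p1", "property"),
                                    qdb_map_values(4, "logp", "descriptor")),
                               header = FALSE)
  grown <- qdb_attach_regression(archive, "p1 = 1.2 + 0.5*logp")
  expect_length(grown$models, 1L)
  expect_length(grown$predictions, 1L)
  prediction <- grown$predictions$members[[1L]]
  expect_identical(prediction$type, "training")
  values <- qdb_parse_values(qdb_get_cargo(prediction, "values"))
  expect_identical(values$id, c("1", "2", "3"))
  # per-compound evaluation oracle: intercept + coefficient * x
  expect_equal(as.numeric(values$value), 1.2 + 0.5 * c(1, 2, 3), tolerance = 1e-12)
  # a well-formed conversion validates cleanly
  findings <- qdb_validate(grown)
  expect_identical(nrow(findings[findings$severity == "error", ]), 0L)

  # naming a property as a term is an unresolved identifier
  expect_qdb_error(qdb_attach_regression(archive, "p1 = 0.5 + 1.0*p1"),
                   "qdb_unresolved_identifier")
  expect_qdb_error(qdb_attach_regression(archive, "nope = 1 + 0.5*logp"),
                   "qdb_unresolved_identifier")
})

test_that("attach_regression on an empty archive yields an empty training table", {
  a <- qdb_archive()
  a <- qdb_add(a, qdb_property("p1"))
  a <- qdb_add(a, qdb_descriptor("x"))
  grown <- qdb_attach_regression(a, "p1 = 1 + 2*x")
  expect_length(grown$models, 1L)
  prediction <- grown$predictions$members[[1L]]
  expect_length(qdb_parse_values(qdb_get_cargo(prediction, "values")), 0L)
})

test_that("references mappings attach to the parameter and resolve", {
  tab <- rbind(c("1", "2.0", "key1"),
               c("2", "3.0", "key1"))
  archive <- qdb_convert_table(tab, list(
    qdb_map_attribute(1, "id"),
    qdb_map_values(2, "p1", "property"),
    qdb_map_references(3, "p1")), header = FALSE)
  p <- qdb_get(archive$properties, "p1")
  expect_true(qdb_has_cargo(p, "references"))
  refs <- qdb_parse_references(qdb_get_cargo(p, "references"))
  expect_identical(refs$key, c("key1", "key1"))
})
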