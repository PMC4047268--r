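test_that("prefixed identifiers are abstract container paths", {
  expect_identical(qdb_prefixed_id("property", "p1"), "properties/p1")
  expect_identical(qdb_prefixed_id("descriptor", "logp"), "descriptors/logp")
  expect_identical(qdb_parse_prefixed_id("properties/p1"),
                   list(type = "property", id = "p1"))
  expect_qdb_error(qdb_parse_prefixed_id("nowhere/p1"), "qdb_invalid_identifier")
  expect_qdb_error(qdb_parse_prefixed_id("p1"), "qdb_invalid_identifier")

  # parse . make identity over all types and generated ids
  set.seed(7)
  for (i in 1:25) {
    type <- sample(c("compound", "property", "descriptor", "model", "prediction"), 1L)
    id <- paste0(sample(c(letters, 0:9, ".", "-", "_"), 8L, replace = TRUE),
                 collapse = "")
    parsed <- qdb_parse_prefixed_id(qdb_prefixed_id(type, id))
    expect_identical(parsed, list(type = type, id = id))
  }
})

test_that("the model constructor enforces registry-of-origin rules", {
  expect_qdb_error(qdb_pmml("descriptors/logp", character(), numeric(), 0),
                   "qdb_invalid_identifier")
  expect_qdb_error(qdb_pmml("properties/p1", "properties/p2", 1, 0),
                   "qdb_invalid_identifier")  # terms must be descriptors
  expect_qdb_error(qdb_pmml("properties/p1", "descriptors/x", numeric(), 0),
                   "qdb_type_error")          # coefficient count mismatch
})

test_that("write/read round trips preserve structure and coefficients exactly", {
  m <- qdb_pmml("properties/p1", c("descriptors/logp", "descriptors/mw"),
                c(0.123456789012345678, -1 / 3), exp(1))
  xml <- qdb_write_pmml(m)
  doc <- xml2::read_xml(xml)
  xml2::xml_ns_strip(doc)
  # DataDictionary lists 1 target + 2 terms
  expect_length(xml2::xml_find_all(doc, "./DataDictionary/DataField"), 3L)
  again <- qdb_read_pmml(xml)
  expect_identical(again$target_ref, m$target_ref)
  expect_identical(again$term_refs, m$term_refs)
  expect_identical(again$coefficients, m$coefficients)  # full double fidelity
  expect_identical(again$intercept, m$intercept)

  # ids colliding across registries stay distinct through the prefix
  collide <- qdb_pmml("properties/1", "descriptors/1", 2, 0)
  names <- xml2::xml_attr(xml2::xml_find_all(
    {d <- xml2::read_xml(qdb_write_pmml(collide)); xml2::xml_ns_strip(d); d},
    "./DataDictionary/DataField"), "name")
  expect_setequal(names, c("properties/1", "descriptors/1"))
})

test_that("foreign model types and malformed documents are rejected loudly", {
  nn <- paste0('<PMML version="4.2"><DataDictionary numberOfFields="1">',
               '<DataField name="properties/p1" optype="continuous" dataType="double"/>',
               '</DataDictionary><NeuralNetwork functionName="regression"/></PMML>')
  err <- tryCatch(qdb_read_pmml(nn), condition = identity)
  expect_s3_class(err, "qdb_unsupported_model_type")
  expect_match(conditionMessage(err), "NeuralNetwork")

  bad_field <- paste0('<PMML version="4.2"><DataDictionary numberOfFields="1">',
                      '<DataField name="p1" optype="continuous" dataType="double"/>',
                      '</DataDictionary><RegressionModel functionName="regression">',
                      '<MiningSchema><MiningField name="p1" usageType="target"/></MiningSchema>',
                      '<RegressionTable intercept="0"/></RegressionModel></PMML>')
  err2 <- tryCatch(qdb_read_pmml(bad_field), condition = identity)
  expect_s3_class(err2, "qdb_malformed_pmml")
  expect_match(conditionMessage(err2), "'p1'")

  expect_qdb_error(qdb_read_pmml("<notpmml/>"), "qdb_malformed_pmml")
  expect_qdb_error(qdb_read_pmml("not xml at all <"), "qdb_malformed_pmml")
})

test_that("the reader tolerates other PMML versions with regression vocabulary", {
  v3 <- paste0('<PMML version="3.0" xmlns="http://www.dmg.org/PMML-3_0">',
               '<DataDictionary numberOfFields="2">',
               '<DataField name="properties/p1" optype="continuous" dataType="double"/>',
               '<DataField name="descriptors/x" optype="continuous" dataType="double"/>',
               '</DataDictionary><RegressionModel functionName="regression">',
               '<MiningSchema><MiningField name="properties/p1" usageType="predicted"/>',
               '<MiningField name="descriptors/x"/></MiningSchema>',
               '<RegressionTable intercept="1.5">',
               '<NumericPredictor name="descriptors/x" coefficient="2"/>',
               '</RegressionTable></RegressionModel></PMML>')
  m <- qdb_read_pmml(v3)
  expect_identical(m$target_ref, "properties/p1")
  expect_equal(m$coefficients, 2)
  expect_equal(m$intercept, 1.5)
})

test_that("evaluation handles normal, abnormal and missing inputs", {
  m <- qdb_pmml("properties/p1", "descriptors/x", 0.5, 1.2)
  out <- qdb_evaluate(m, list("1" = c("descriptors/x" = "2.0"),
                              "2" = c("descriptors/x" = "N/A"),
                              "3" = character()))
  expect_identical(out$id, c("1", "2", "3"))
  expect_equal(as.numeric(out$value[[1L]]), 1.2 + 0.5 * 2.0)
  expect_identical(out$value[2:3], c("N/A", "N/A"))

  # all-zero coefficients: every prediction equals the intercept
  m0 <- qdb_pmml("properties/p1", "descriptors/x", 0, 7.5)
  out0 <- qdb_evaluate(m0, list("1" = c("descriptors/x" = "1"),
                                "2" = c("descriptors/x" = "99")))
  expect_identical(unique(out0$value), qdb_format_number(7.5))
})

test_that("evaluation is linear and matches a matrix-product oracle", {
  set.seed(99)
  # linearity: evaluate(m, a*x) - b == a*(evaluate(m, x) - b), single term
  m <- qdb_pmml("properties/p1", "descriptors/x", 1.75, -0.4)
  for (a in c(2, -3, 0.5)) {
    x <- runif(1)
    f_x <- as.numeric(qdb_evaluate(m, list("1" = c("descriptors/x" = qdb_format_number(x))))$value)
    f_ax <- as.numeric(qdb_evaluate(m, list("1" = c("descriptors/x" = qdb_format_number(a * x))))$value)
    expect_equal(f_ax - m$intercept, a * (f_x - m$intercept), tolerance = 1e-12)
  }

  # random models vs X %*% beta + b
  for (rep in 1:10) {
    n <- sample(1:100, 1L)
    k <- sample(1:10, 1L)
    beta <- rnorm(k)
    b <- rnorm(1)
    x <- matrix(runif(n * k, -5, 5), n, k)
    refs <- paste0("descriptors/d", seq_len(k))
    m <- qdb_pmml("properties/p1", refs, beta, b)
    rows <- lapply(seq_len(n), function(i)
      stats::setNames(qdb_format_number(x[i, ]), refs))
    names(rows) <- as.character(seq_len(n))
    got <- as.numeric(qdb_evaluate(m, rows)$value)
    want <- as.vector(x %*% beta + b)
    expect_equal(got, want, tolerance = 1e-12)
  }
})
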