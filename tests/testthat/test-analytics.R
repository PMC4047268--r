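test_that("perfect fits give r_squared 1 and rmse 0", {
  a <- tiny_archive()
  # replace the prediction values with the experimental values
  experimental <- qdb_get_cargo(qdb_get(a$properties, "p1"), "values")
  a$predictions$members[[1L]] <-
    qdb_set_cargo(a$predictions$members[[1L]], "values", experimental)
  fit <- qdb_fit(a, "tr1")
  expect_identical(fit$n, 2L)
  expect_identical(fit$r_squared, 1)
  expect_identical(fit$rmse, 0)
  expect_identical(unname(fit$residuals), c(0, 0))
})

test_that("fit statistics match a hand-computed sum-of-squares oracle", {
  a <- qdb_archive()
  for (i in 1:4) a <- qdb_add(a, qdb_compound(as.character(i)))
  p <- qdb_set_cargo(qdb_property("p1"), "values", "1\t1.0\n2\t2.0\n3\t3.0\n4\t6.0\n")
  a <- qdb_add(a, p)
  m <- qdb_model("m1", property_id = "p1")
  m <- qdb_set_cargo(m, "pmml",
                     qdb_write_pmml(qdb_pmml("properties/p1", character(), numeric(), 0)))
  a <- qdb_add(a, m)
  pr <- qdb_prediction("tr", model_id = "m1", type = "training")
  pr <- qdb_set_cargo(pr, "values", "1\t3.0\n2\t3.0\n3\t3.0\n4\t3.0\n")
  a <- qdb_add(a, pr)

  fit <- qdb_fit(a, "tr")
  y <- c(1, 2, 3, 6); yhat <- rep(3, 4)
  ss_res <- sum((yhat - y)^2)                 # 4 + 1 + 0 + 9 = 14
  ss_tot <- sum((y - mean(y))^2)              # 14
  expect_identical(fit$n, 4L)
  expect_equal(fit$r_squared, 1 - ss_res / ss_tot)  # exactly 0: constant fit boundary
  expect_equal(fit$rmse, sqrt(ss_res / 4))
  expect_equal(fit$residuals, c(`1` = 2, `2` = 1, `3` = 0, `4` = -3))  # predicted - experimental

  # a fit worse than the mean reports a negative r_squared, not clamped
  pr2 <- qdb_prediction("tr2", model_id = "m1", type = "training")
  pr2 <- qdb_set_cargo(pr2, "values", "1\t9.0\n2\t9.0\n3\t9.0\n4\t9.0\n")
  a2 <- qdb_add(a, pr2)
  expect_lt(qdb_fit(a2, "tr2")$r_squared, 0)
})

test_that("abnormal values on either side are excluded from n", {
  a <- qdb_archive()
  for (i in 1:5) a <- qdb_add(a, qdb_compound(as.character(i)))
  p <- qdb_set_cargo(qdb_property("p1"), "values",
                     "1\t1.0\n2\t2.0\n3\t3.0\n4\t4.0\n5\t5.0\n")
  a <- qdb_add(a, p)
  m <- qdb_set_cargo(qdb_model("m1", property_id = "p1"), "pmml",
                     qdb_write_pmml(qdb_pmml("properties/p1", character(), numeric(), 0)))
  a <- qdb_add(a, m)
  pr <- qdb_prediction("tr", model_id = "m1", type = "training")
  pr <- qdb_set_cargo(pr, "values", "1\t1.1\n2\t2.1\n3\tN/A\n4\t4.1\n5\t5.1\n")
  a <- qdb_add(a, pr)
  expect_identical(qdb_fit(a, "tr")$n, 4L)

  # no overlap at all is an error, not a silent zero
  pr_na <- qdb_set_cargo(qdb_prediction("trna", model_id = "m1", type = "training"),
                         "values", "1\tN/A\n2\tN/A\n3\tN/A\n4\tN/A\n5\tN/A\n")
  expect_qdb_error(qdb_fit(qdb_add(a, pr_na), "trna"), "qdb_no_overlap")
})

test_that("fit errors carry the failure mode", {
  a <- tiny_archive()
  a$predictions$members[[1L]]$model_id <- "gone"
  expect_qdb_error(qdb_fit(a, "tr1"), "qdb_broken_chain")
  expect_qdb_error(qdb_fit(tiny_archive(), "nope"), "qdb_not_found")
})

test_that("noise ordering: r_squared rises and rmse falls as sigma shrinks", {
  fits <- lapply(c(0, 0.01, 0.1), function(sigma) {
    a <- qdb_generate(qdb_synthetic_spec(n_compounds = 40, noise_sigma = sigma,
                                         abnormal_fraction = 0, seed = 17))
    qdb_fit(a, "m1-training")
  })
  r2 <- vapply(fits, `[[`, numeric(1L), "r_squared")
  rmse <- vapply(fits, `[[`, numeric(1L), "rmse")
  expect_identical(r2[[1L]], 1)
  expect_identical(rmse[[1L]], 0)
  expect_true(all(diff(r2) < 0))   # sigma up => fit down
  expect_true(all(diff(rmse) > 0))
})

validation_fixture <- function(validation_ids, training_ids = c("1", "2", "3")) {
  a <- qdb_archive()
  for (i in as.character(1:8)) a <- qdb_add(a, qdb_compound(i))
  p <- qdb_set_cargo(qdb_property("p1"), "values",
                     qdb_format_values(qdb_values(as.character(1:8), rep("1.0", 8L))))
  a <- qdb_add(a, p)
  m <- qdb_set_cargo(qdb_model("m1", property_id = "p1"), "pmml",
                     qdb_write_pmml(qdb_pmml("properties/p1", character(), numeric(), 0)))
  a <- qdb_add(a, m)
  tr <- qdb_set_cargo(qdb_prediction("tr", model_id = "m1", type = "training"),
                      "values",
                      qdb_format_values(qdb_values(training_ids, rep("1.0", length(training_ids)))))
  a <- qdb_add(a, tr)
  v <- qdb_set_cargo(qdb_prediction("v", model_id = "m1", type = "validation"),
                     "values",
                     qdb_format_values(qdb_values(validation_ids, rep("1.0", length(validation_ids)))))
  qdb_add(a, v)
}

test_that("validation subtype follows the set algebra", {
  expect_identical(qdb_validation_subtype(validation_fixture(c("1", "2")), "v"),
                   "internal")
  expect_identical(qdb_validation_subtype(validation_fixture(c("7", "8")), "v"),
                   "external")
  expect_warning(
    subtype <- qdb_validation_subtype(validation_fixture(c("3", "7")), "v"),
    "mixed")
  expect_identical(subtype, "mixed")

  # invariant to registry ordering
  a <- validation_fixture(c("1", "2"))
  a$predictions$members <- rev(a$predictions$members)
  a$compounds$members <- rev(a$compounds$members)
  expect_identical(qdb_validation_subtype(a, "v"), "internal")

  # missing training prediction is a dedicated error
  b <- validation_fixture(c("1", "2"))
  b$predictions$members <- Filter(function(p) p$id != "tr", b$predictions$members)
  expect_qdb_error(qdb_validation_subtype(b, "v"), "qdb_no_training_prediction")
  expect_qdb_error(qdb_validation_subtype(validation_fixture("1"), "tr"),
                   "qdb_type_error")
})

test_that("label queries follow the grammar and registry order", {
  r <- qdb_registry("compound")
  r <- qdb_add(r, qdb_compound("c1", labels = "train"))
  r <- qdb_add(r, qdb_compound("c2", labels = "test"))
  r <- qdb_add(r, qdb_compound("c3", labels = c("train", "outlier")))
  expect_identical(qdb_query(r, "train"), c("c1", "c3"))
  expect_identical(qdb_query(r, "train AND NOT outlier"), "c1")
  expect_identical(qdb_query(r, "(train OR test) AND NOT outlier"), c("c1", "c2"))
  expect_identical(qdb_query(r, "NOT (train OR test)"), character())
  # precedence: NOT > AND > OR
  expect_identical(qdb_query(r, "test OR train AND NOT outlier"), c("c1", "c2"))

  err <- tryCatch(qdb_query(r, "train AND"), condition = identity)
  expect_s3_class(err, "qdb_query_syntax_error")
  expect_true(is.numeric(err$position))
  expect_qdb_error(qdb_query(r, "(train"), "qdb_query_syntax_error")
  expect_qdb_error(qdb_query(r, "train ! test"), "qdb_query_syntax_error")
})

test_that("queries agree with brute-force evaluation, incl. De Morgan", {
  set.seed(5150)
  for (i in 1:40) {
    r <- random_labeled_registry()
    expr <- random_label_expr()
    expect_identical(qdb_query(r, expr), oracle_query(r, expr), label = expr)
  }
  for (i in 1:20) {
    r <- random_labeled_registry()
    e1 <- random_label_expr(2L)
    e2 <- random_label_expr(2L)
    expect_identical(qdb_query(r, sprintf("NOT (%s OR %s)", e1, e2)),
                     qdb_query(r, sprintf("NOT (%s) AND NOT (%s)", e1, e2)))
    expect_identical(qdb_query(r, sprintf("NOT (%s AND %s)", e1, e2)),
                     qdb_query(r, sprintf("NOT (%s) OR NOT (%s)", e1, e2)))
  }
})

test_that("summaries mirror the serialised layout", {
  empty <- qdb_summary(qdb_archive())
  expect_true(all(empty$counts == 0L))
  expect_identical(empty$root_listing, "archive.xml")

  a <- qdb_generate(qdb_synthetic_spec(n_compounds = 4, seed = 3))
  s <- qdb_summary(a)
  expect_identical(sum(s$counts > 0L), 5L)  # fully developed: all five
  d <- withr::local_tempdir()
  qdb_save(a, file.path(d, "a"))
  expect_setequal(s$root_listing, list.files(file.path(d, "a")))
  # per-registry counts equal directory listing counts
  for (subdir in names(s$counts)) {
    entries <- list.files(file.path(d, "a", subdir))
    expect_identical(s$counts[[subdir]],
                     length(setdiff(entries, paste0(subdir, ".xml"))))
  }
})
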