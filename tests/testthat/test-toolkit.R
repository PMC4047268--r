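test_that("the generator is deterministic and produces valid archives", {
  spec <- qdb_synthetic_spec(n_compounds = 7, seed = 123)
  a <- qdb_generate(spec)
  b <- qdb_generate(spec)
  expect_identical(a, b)
  d <- withr::local_tempdir()
  qdb_save(a, file.path(d, "a.qdb.zip"))
  qdb_save(b, file.path(d, "b.qdb.zip"))
  expect_identical(readBin(file.path(d, "a.qdb.zip"), "raw", file.size(file.path(d, "a.qdb.zip"))),
                   readBin(file.path(d, "b.qdb.zip"), "raw", file.size(file.path(d, "b.qdb.zip"))))
  expect_identical(nrow(qdb_validate(a)), 0L)
  # CAS numbers are checksum-correct by construction
  for (compound in a$compounds$members) expect_true(qdb_cas_check(compound$cas))
  # different seeds differ
  expect_false(identical(a, qdb_generate(qdb_synthetic_spec(n_compounds = 7, seed = 124))))
})

test_that("the generator honours the degenerate corners of its spec", {
  empty <- qdb_generate(qdb_synthetic_spec(n_compounds = 0, seed = 1))
  expect_length(empty$compounds, 0L)
  expect_identical(nrow(qdb_validate(empty)), 0L)

  clean <- qdb_generate(qdb_synthetic_spec(n_compounds = 12, noise_sigma = 0,
                                           abnormal_fraction = 0, seed = 4))
  fit <- qdb_fit(clean, "m1-training")
  expect_identical(fit$r_squared, 1)
  expect_identical(fit$rmse, 0)

  frac <- qdb_generate(qdb_synthetic_spec(n_compounds = 20, abnormal_fraction = 0.25,
                                          seed = 4))
  values <- qdb_parse_values(qdb_get_cargo(qdb_get(frac$properties, "pLC50"), "values"))
  expect_identical(sum(values$value == "N/A"), 5L)
})

test_that("predict reproduces the stored training prediction exactly", {
  # predictions use descriptor values only, so this is sigma-independent
  a <- qdb_generate(qdb_synthetic_spec(n_compounds = 9, noise_sigma = 0.4, seed = 6))
  stored <- qdb_parse_values(qdb_get_cargo(qdb_get(a$predictions, "m1-training"), "values"))
  recomputed <- qdb_predict(a, "m1")
  expect_identical(recomputed$id, stored$id)
  expect_identical(recomputed$value, stored$value)
})

test_that("the generator restores the caller's RNG state", {
  set.seed(77)
  expected <- runif(1)
  set.seed(77)
  invisible(qdb_generate(qdb_synthetic_spec(n_compounds = 3, seed = 1)))
  expect_identical(runif(1), expected)
})

# ---- CLI ------------------------------------------------------------------

run_cli <- function(...) {
  args <- c(...)
  msgs <- character()
  status <- NA_integer_
  stdout <- withCallingHandlers(
    capture.output(status <- qdb_cli(args), type = "output"),
    message = function(m) {
      msgs <<- c(msgs, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  list(status = status, stdout = stdout, messages = msgs)
}

test_that("validate exits 0 on a clean archive and 1 with findings", {
  d <- withr::local_tempdir()
  clean <- file.path(d, "clean")
  qdb_save(qdb_generate(qdb_synthetic_spec(n_compounds = 4, seed = 8)), clean)
  res <- run_cli("validate", clean)
  expect_identical(res$status, 0L)
  expect_length(res$stdout, 0L)

  # desynchronise the cargos attribute on disk: r1 must fire, exit 1
  corrupted <- file.path(d, "corrupted")
  qdb_save(qdb_generate(qdb_synthetic_spec(n_compounds = 4, seed = 8)), corrupted)
  writeLines("orphan", file.path(corrupted, "compounds", "1", "orphan"))
  res2 <- run_cli("validate", corrupted)
  expect_identical(res2$status, 1L)
  expect_true(any(grepl("^error\tr1\t", res2$stdout)))
})

test_that("usage errors exit 2 without stack traces", {
  expect_identical(suppressMessages(qdb_cli(character())), 2L)
  expect_identical(suppressMessages(qdb_cli("frobnicate")), 2L)
  expect_identical(suppressMessages(qdb_cli(c("import", "--out", "x"))), 2L)
  expect_identical(suppressMessages(qdb_cli(c("pack", "onlyone"))), 2L)
})

test_that("synth, info, pack, unpack and predict round trip through the CLI", {
  d <- withr::local_tempdir()
  archive_dir <- file.path(d, "synth")
  expect_identical(suppressMessages(qdb_cli(c("synth", archive_dir, "--n", "5",
                                              "--seed", "42"))), 0L)
  info <- run_cli("info", archive_dir)
  expect_identical(info$status, 0L)
  expect_true(any(grepl("^compounds\t5$", info$stdout)))

  zipfile <- file.path(d, "packed.qdb.zip")
  expect_identical(suppressMessages(qdb_cli(c("pack", archive_dir, zipfile))), 0L)
  unpacked <- file.path(d, "unpacked")
  expect_identical(suppressMessages(qdb_cli(c("unpack", zipfile, unpacked))), 0L)
  # recursive diff: identical file sets with identical bytes
  files <- list.files(archive_dir, recursive = TRUE)
  expect_setequal(files, list.files(unpacked, recursive = TRUE))
  for (f in files) {
    expect_identical(readBin(file.path(unpacked, f), "raw", file.size(file.path(unpacked, f))),
                     readBin(file.path(archive_dir, f), "raw", file.size(file.path(archive_dir, f))),
                     label = f)
  }

  out2 <- file.path(d, "with-prediction")
  expect_identical(suppressMessages(qdb_cli(c("predict", archive_dir,
                                              "--model", "m1", "--id", "v1",
                                              "--type", "validation",
                                              "--out", out2))), 0L)
  grown <- qdb_load(out2)
  expect_true(qdb_has(grown$predictions, "v1"))
  stats <- run_cli("stats", archive_dir, "--prediction", "m1-training")
  expect_identical(stats$status, 0L)
  expect_true(any(grepl("^r2\t", stats$stdout)))
})

test_that("the import subcommand converts tables end to end", {
  d <- withr::local_tempdir()
  table_file <- file.path(d, "table.tsv")
  writeLines(c("50-00-0\tC=O\t5.24\t1.0",
               "74-82-8\tC\t4.1\t2.0",
               "64-17-5\tCCO\t3.1\t3.0"), table_file)
  out <- file.path(d, "imported.qdb.zip")
  status <- suppressMessages(qdb_cli(c(
    "import", "--in", table_file,
    "--map", "0=cas", "--map", "1=cargo:smiles",
    "--map", "2=property:pLC50", "--map", "3=descriptor:logp",
    "--equation", "pLC50 = 1.0 + 1.5*logp",
    "--out", out)))
  expect_identical(status, 0L)
  archive <- qdb_load(out)
  expect_length(archive$compounds, 3L)
  expect_length(archive$models, 1L)
  summary <- qdb_summary(archive)
  expect_identical(sum(summary$counts > 0L), 5L)  # fully developed in one command
  findings <- qdb_validate(archive)
  expect_identical(nrow(findings[findings$severity == "error", ]), 0L)
})
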