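# Synthetic fully-developed archives.  The generator stands in for real
# digitised data sets (e.g. acute aquatic toxicity collections): compounds
# with checksum-correct CAS numbers and single-line SMILES structure
# cargos, descriptors drawn uniform(0,1), one property generated by a known
# linear model plus Gaussian noise, the model itself as a PMML cargo and
# its training prediction.  Identical specifications yield byte-identical
# serialised archives.

# small fixed alphabet of real single-line SMILES; enough to exercise
# structure-cargo plumbing without a chemistry toolkit
.qdb_smiles_alphabet <- c("C", "CC", "CCO", "CC(=O)O", "c1ccccc1",
                          "Cc1ccccc1", "CCN(CC)CC", "C1CCCCC1",
                          "CC(C)O", "OCC(O)CO")

# a syntactically valid, checksum-correct synthetic CAS number
synth_cas <- function(base_digits) {
  digits <- as.integer(strsplit(base_digits, "")[[1L]])
  check <- sum(rev(digits) * seq_along(digits)) %% 10L
  sprintf("%s-%s-%d", substr(base_digits, 1L, nchar(base_digits) - 2L),
          substr(base_digits, nchar(base_digits) - 1L, nchar(base_digits)), check)
}

#' Specification for a synthetic archive
#'
#' The defaults describe a small but realistic QSAR training exercise: 30
#' compounds, two descriptors, a known linear relationship with Gaussian
#' noise of 0.1 response units, and 5% of the experimental rows replaced by
#' the `"N/A"` error code (measurements attempted but void).
#'
#' @param n_compounds number of compounds.
#' @param n_descriptors number of descriptors.
#' @param coefficients numeric vector of length `n_descriptors`: the true
#'   model coefficients (recycled defaults alternate 1.5, -0.8).
#' @param intercept true model intercept.
#' @param noise_sigma standard deviation of the Gaussian noise added to the
#'   property values, in property units.
#' @param abnormal_fraction fraction in `[0, 1]` of property rows replaced
#'   by `"N/A"`.
#' @param seed integer seed; identical specifications generate
#'   byte-identical archives.
#' @return a `qdb_synthetic_spec`.
#' @export
qdb_synthetic_spec <- function(n_compounds = 30L, n_descriptors = 2L,
                               coefficients = NULL, intercept = 0.5,
                               noise_sigma = 0.1, abnormal_fraction = 0.05,
                               seed = 1L) {
  qdb_assert(n_compounds >= 0L, "qdb_type_error", "n_compounds must be >= 0")
  qdb_assert(n_descriptors >= 0L, "qdb_type_error", "n_descriptors must be >= 0")
  qdb_assert(noise_sigma >= 0, "qdb_type_error", "noise_sigma must be >= 0")
  qdb_assert(abnormal_fraction >= 0 && abnormal_fraction <= 1, "qdb_type_error",
             "abnormal_fraction must be in [0, 1]")
  if (is.null(coefficients)) {
    coefficients <- rep_len(c(1.5, -0.8), n_descriptors)
  }
  qdb_assert(length(coefficients) == n_descriptors, "qdb_type_error",
             "one coefficient per descriptor is required")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept),
                 noise_sigma = as.numeric(noise_sigma),
                 abnormal_fraction = as.numeric(abnormal_fraction),
                 seed = as.integer(seed)),
            class = "qdb_synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Generate a synthetic fully-developed archive
#'
#' Builds, per the specification: compounds `"1"..."n"` with valid
#' synthetic CAS numbers, SMILES structure cargos and `train`/`test`
#' labels; descriptors `"d1"..."dk"` with uniform(0,1) values, UCUM and
#' BODO cargos; one property `"pLC50"` with values
#' `intercept + sum(beta * x) + N(0, sigma)` (an `abnormal_fraction` of the
#' rows is replaced by `"N/A"`), UCUM, BibTeX and references cargos; one
#' model `"m1"` whose PMML cargo carries the true coefficients; and its
#' training prediction computed with [qdb_predict()].  With
#' `noise_sigma = 0` the training prediction reproduces the property values
#' exactly on the normal rows, so [qdb_fit()] reports `r_squared = 1` and
#' `rmse = 0`.
#'
#' @param spec a [qdb_synthetic_spec()] (or arguments for one, via `...`).
#' @param ... passed to [qdb_synthetic_spec()] when `spec` is missing.
#' @return a `qdb_archive` that passes [qdb_validate()] with no findings.
#' @examples
#' a <- qdb_generate(qdb_synthetic_spec(n_compounds = 5, seed = 7))
#' qdb_fit(a, "m1-training")
#' @export
qdb_generate <- function(spec = qdb_synthetic_spec(...), ...) {
  stopifnot(inherits(spec, "qdb_synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_compounds
    k <- spec$n_descriptors
    ids <- as.character(seq_len(n))

    archive <- qdb_archive(
      name = "Synthetic linear QSAR data set",
      description = sprintf(
        "Synthetic archive: %d compounds, %d descriptors, true model y = %s%s, noise sigma = %s.",
        n, k, qdb_format_number(spec$intercept),
        if (k) paste0(" + ", paste(sprintf("%s*d%d", qdb_format_number(spec$coefficients),
                                           seq_len(k)), collapse = " + ")) else "",
        qdb_format_number(spec$noise_sigma)))

    train <- rep(TRUE, n)
    if (n > 1L) train[sample.int(n, size = max(1L, round(n * 0.2)))] <- FALSE
    for (i in seq_len(n)) {
      base <- paste0(sample(0:9, 6L, replace = TRUE), collapse = "")
      compound <- qdb_compound(ids[[i]],
                               name = sprintf("synthetic compound %d", i),
                               labels = if (train[[i]]) "train" else "test",
                               cas = synth_cas(base))
      compound <- qdb_set_cargo(compound, "smiles",
                                paste0(sample(.qdb_smiles_alphabet, 1L), "\n"))
      archive <- qdb_add(archive, compound)
    }

    x <- matrix(runif(n * k), nrow = n, ncol = k)
    # canonical text form first, then parse back: the stored representation
    # is authoritative, and %.17g round-trips doubles exactly
    for (j in seq_len(k)) {
      descriptor <- qdb_descriptor(paste0("d", j),
                                   name = sprintf("synthetic descriptor %d", j),
                                   application = "qsardb-synth 0.1")
      descriptor <- qdb_set_cargo(descriptor, "ucum", "1")
      descriptor <- qdb_set_cargo(descriptor, "bodo", qdb_format_bodo(list(
        ontologyReference = sprintf("bodo:synthetic-%d", j),
        implementations = list(list(application = "qsardb-synth 0.1",
                                    parameterization = "default")))))
      if (n > 0L) {
        descriptor <- qdb_set_cargo(descriptor, "values",
          qdb_format_values(qdb_values(ids, qdb_format_number(x[, j]))))
      }
      archive <- qdb_add(archive, descriptor)
    }

    property <- qdb_property("pLC50",
                             name = "Acute aquatic toxicity, -log10(LC50)",
                             endpoint = "Acute toxicity to aquatic invertebrates",
                             species = "Tetrahymena pyriformis")
    property <- qdb_set_cargo(property, "ucum", "-lg(mmol/l)")
    property <- qdb_set_cargo(property, "bibtex", paste0(
      "@article{synthetic2014,\n",
      "  title = {Synthetic toxicity measurements},\n",
      "  journal = {Journal of Synthetic Data},\n",
      "  year = {2014}\n",
      "}\n"))
    if (n > 0L) {
      # same arithmetic (and summation order) as the PMML evaluator, so a
      # noiseless archive reproduces its training prediction bit-exactly
      truth <- vapply(seq_len(n), function(i)
        spec$intercept + sum(spec$coefficients * x[i, ]), numeric(1L))
      y <- truth + rnorm(n, sd = spec$noise_sigma)
      raw <- qdb_format_number(y)
      n_abnormal <- round(n * spec$abnormal_fraction)
      if (n_abnormal > 0L) raw[sample.int(n, n_abnormal)] <- "N/A"
      property <- qdb_set_cargo(property, "values",
                                qdb_format_values(qdb_values(ids, raw)))
      property <- qdb_set_cargo(property, "references",
                                qdb_format_values(qdb_references(ids, rep("synthetic2014", n))))
    } else {
      property <- qdb_set_cargo(property, "values", "")
    }
    archive <- qdb_add(archive, property)

    spec_terms <- stats::setNames(spec$coefficients,
                                  if (k) paste0("d", seq_len(k)) else character())
    qdb_attach_regression(archive,
                          qdb_regression("pLC50", spec_terms, spec$intercept),
                          model_id = "m1",
                          application = "qsardb-synth 0.1")
  })
}
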