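# Fixtures are built in code; no files ship with the tests.

# A tiny hand-made archive exercising the whole strong chain:
# 2 compounds, 1 property (values + references + bibtex), 1 descriptor
# (values), 1 model (pmml), 1 training prediction (values).
tiny_archive <- function() {
  a <- qdb_archive("Tiny archive", "Hand-made fixture.")
  a <- qdb_add(a, qdb_compound("1", name = "methane", cas = "74-82-8",
                               inchi = "InChI=1S/CH4/h1H4", labels = "train"))
  a <- qdb_add(a, qdb_compound("2", name = "ethanol", labels = c("train", "outlier")))

  p <- qdb_property("p1", endpoint = "Acute toxicity", species = "Homo sapiens (Human)")
  p <- qdb_set_cargo(p, "values", "1\t2.5\n2\t3.5\n")
  p <- qdb_set_cargo(p, "references", "1\tschultz1999\n2\tschultz1999\n")
  p <- qdb_set_cargo(p, "bibtex",
                     "@article{schultz1999,\n  title = {Tox data},\n  year = {1999}\n}\n")
  p <- qdb_set_cargo(p, "ucum", "mmol/l")
  a <- qdb_add(a, p)

  d <- qdb_descriptor("logp", application = "toolkit 1.0")
  d <- qdb_set_cargo(d, "values", "1\t1.0\n2\t3.0\n")
  a <- qdb_add(a, d)

  pm <- qdb_pmml("properties/p1", "descriptors/logp", 0.5, 2.0)
  m <- qdb_model("m1", property_id = "p1")
  m <- qdb_set_cargo(m, "pmml", qdb_write_pmml(pm))
  a <- qdb_add(a, m)

  pr <- qdb_prediction("tr1", model_id = "m1", type = "training")
  pr <- qdb_set_cargo(pr, "values", qdb_format_values(qdb_predict(a, "m1")))
  qdb_add(a, pr)
}

# Independent CAS check-digit oracle: textual digit walk, written without
# vector arithmetic so it shares nothing with the implementation.
oracle_cas <- function(casrn) {
  digits <- gsub("-", "", casrn)
  n <- nchar(digits)
  check <- as.integer(substr(digits, n, n))
  acc <- 0L
  pos <- 1L
  for (i in seq(n - 1L, 1L)) {     # right-to-left over non-check digits
    acc <- acc + as.integer(substr(digits, i, i)) * pos
    pos <- pos + 1L
  }
  (acc %% 10L) == check
}

# Brute-force label query oracle: translate the expression into an R
# logical expression over per-member membership and eval() it.
oracle_query <- function(registry, expression) {
  r_expr <- gsub("\\bAND\\b", "&", gsub("\\bOR\\b", "|", gsub("\\bNOT\\b", "!", expression)))
  # quote bare labels as membership tests
  r_expr <- gsub("(?<![!&|(\\s])\\b([A-Za-z0-9._-]+)\\b", "\\1", r_expr, perl = TRUE)
  hits <- vapply(registry$members, function(member) {
    env <- new.env()
    labels <- member$labels
    tokens <- unique(unlist(regmatches(expression,
                                       gregexpr("[A-Za-z0-9._-]+", expression))))
    tokens <- setdiff(tokens, c("AND", "OR", "NOT"))
    for (tok in tokens) assign(tok, tok %in% labels, envir = env)
    isTRUE(eval(parse(text = r_expr), envir = env))
  }, logical(1L))
  qdb_ids(registry)[hits]
}

# random label expression over a fixed alphabet (for property-based tests)
random_label_expr <- function(depth = 3L, alphabet = c("a", "b", "c", "d")) {
  if (depth <= 0L || runif(1) < 0.35) return(sample(alphabet, 1L))
  switch(sample(3L, 1L),
         sprintf("NOT (%s)", random_label_expr(depth - 1L, alphabet)),
         sprintf("(%s AND %s)", random_label_expr(depth - 1L, alphabet),
                 random_label_expr(depth - 1L, alphabet)),
         sprintf("(%s OR %s)", random_label_expr(depth - 1L, alphabet),
                 random_label_expr(depth - 1L, alphabet)))
}

# registry of members carrying random subsets of the label alphabet
random_labeled_registry <- function(n = 12L, alphabet = c("a", "b", "c", "d")) {
  r <- qdb_registry("compound")
  for (i in seq_len(n)) {
    labels <- alphabet[runif(length(alphabet)) < 0.5]
    r <- qdb_add(r, qdb_compound(sprintf("c%d", i), labels = labels))
  }
  r
}

expect_qdb_error <- function(expr, class) {
  expect_error(expr, class = class)
}

# Seeded corruptions, one per validation rule; each takes a pristine
# generated archive and breaks exactly the invariant its rule checks.
corruptions <- list(
  r1 = function(a) {
    a$properties$members[[1L]]$payloads[["orphan"]] <- charToRaw("x")
    a
  },
  r2 = function(a) {
    a$predictions$members[[1L]]$model_id <- "missing"
    a
  },
  r3 = function(a) {
    p <- qdb_get(a$properties, "pLC50")
    payload <- paste0(qdb_get_cargo(p, "values", as = "character"), "999\t1.0\n")
    a$properties$members[[1L]] <- qdb_set_cargo(p, "values", payload)
    a
  },
  r4 = function(a) {
    p <- qdb_get(a$properties, "pLC50")
    refs <- qdb_parse_references(qdb_get_cargo(p, "references"))
    refs$key[1L] <- "missing2001"
    a$properties$members[[1L]] <- qdb_set_cargo(p, "references", qdb_format_values(refs))
    a
  },
  r5 = function(a) {
    a$predictions$members[[1L]]$id <- "bad id"
    a
  },
  r6 = function(a) {
    a$compounds$members[[1L]]$cas <- "50-00-1"
    a$compounds$members[[2L]]$inchi <- "InChI=1/CH4/h1H4"
    a
  },
  r7 = function(a) {
    a$predictions$members[[1L]]$type <- "guessing"
    a
  },
  r8 = function(a) {
    a$properties$members[[1L]] <-
      qdb_set_cargo(qdb_get(a$properties, "pLC50"), "mycargo", "payload")
    a
  },
  r9 = function(a) {
    bad <- qdb_pmml("properties/pLC50", "descriptors/zzz", 1, 0)
    a$models$members[[1L]] <-
      qdb_set_cargo(qdb_get(a$models, "m1"), "pmml", qdb_write_pmml(bad))
    a
  },
  r10 = function(a) {
    p <- qdb_get(a$properties, "pLC50")
    payload <- paste0(qdb_get_cargo(p, "values", as = "character"), "1\t2.0\n")
    a$properties$members[[1L]] <- qdb_set_cargo(p, "values", payload)
    a
  })
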