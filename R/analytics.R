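# On-demand statistics.  Goodness-of-fit figures (R^2, RMSE, residuals) are
# secondary data: they are computed from the primary values in the archive
# whenever asked for, and are never persisted back into it.

#' Goodness of fit of a prediction
#'
#' Pairs the experimental values of the predicted property with the
#' prediction's values by compound identifier.  Pairs where either side is
#' abnormal (e.g. `"N/A"`) are excluded; `n` counts the remaining pairs.
#' Residuals are `predicted - experimental`.  `r_squared = 1 -
#' SS_res/SS_tot` with `SS_tot` taken about the experimental mean of the
#' paired subset, and `rmse = sqrt(SS_res/n)`; `r_squared` is reported as
#' `NA` when `n < 2` or `SS_tot = 0` (it may be negative for fits worse
#' than the mean -- it is reported, not clamped).
#'
#' @param archive a `qdb_archive`.
#' @param prediction_id identifier of a prediction whose strong chain
#'   resolves and whose property carries a `values` cargo.
#' @return a `qdb_fit` list: `n`, `r_squared`, `rmse`, `residuals` (named
#'   numeric, by compound id).
#' @export
qdb_fit <- function(archive, prediction_id) {
  chain <- qdb_resolve_prediction(archive, prediction_id)
  qdb_assert(qdb_has_cargo(chain$property, "values"), "qdb_not_found",
             sprintf("property '%s' has no 'values' cargo", chain$property$id))
  qdb_assert(qdb_has_cargo(chain$prediction, "values"), "qdb_not_found",
             sprintf("prediction '%s' has no 'values' cargo", prediction_id))
  experimental <- as.data.frame(qdb_parse_values(qdb_get_cargo(chain$property, "values")))
  predicted <- as.data.frame(qdb_parse_values(qdb_get_cargo(chain$prediction, "values")))
  merged <- merge(experimental, predicted, by = "id", suffixes = c(".exp", ".pred"))
  ok <- merged$kind.exp == "normal" & merged$kind.pred == "normal"
  merged <- merged[ok, , drop = FALSE]
  n <- nrow(merged)
  qdb_assert(n > 0L, "qdb_no_overlap",
             sprintf("no compounds with paired normal values between property '%s' and prediction '%s'",
                     chain$property$id, prediction_id))
  residuals <- stats::setNames(merged$numeric.pred - merged$numeric.exp, merged$id)
  ss_res <- sum(residuals^2)
  ss_tot <- sum((merged$numeric.exp - mean(merged$numeric.exp))^2)
  structure(list(n = n,
                 r_squared = if (n < 2L || ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
                 rmse = sqrt(ss_res / n),
                 residuals = residuals),
            class = "qdb_fit")
}

#' @export
print.qdb_fit <- function(x, ...) {
  cat(sprintf("<qdb fit> n = %d, R^2 = %s, RMSE = %s\n", x$n,
              format(x$r_squared, digits = 6), format(x$rmse, digits = 6)))
  invisible(x)
}

#' Classify a validation prediction as internal, external or mixed
#'
#' The validation subtype is implicit, determined by the intersection of
#' the validation compound set with the model's training set: `"internal"`
#' (cross-validation) if contained in the training set, `"external"` if
#' disjoint, `"mixed"` otherwise.  Mixed sets are flagged with an R warning
#' because they are expected to be divided into concrete validation and
#' testing sets.  The result does not depend on registry ordering.
#'
#' @param archive a `qdb_archive`.
#' @param prediction_id identifier of a prediction of type `"validation"`.
#' @return `"internal"`, `"external"` or `"mixed"`.
#' @export
qdb_validation_subtype <- function(archive, prediction_id) {
  prediction <- qdb_get(archive$predictions, prediction_id)
  qdb_assert(identical(prediction$type, "validation"), "qdb_type_error",
             sprintf("prediction '%s' has type '%s', expected 'validation'",
                     prediction_id, prediction$type %||% "<missing>"))
  training <- Filter(function(p) identical(p$model_id, prediction$model_id) &&
                       identical(p$type, "training"),
                     archive$predictions$members)
  qdb_assert(length(training) >= 1L, "qdb_no_training_prediction",
             sprintf("model '%s' has no training prediction", prediction$model_id))
  ids_of <- function(p) {
    if (!qdb_has_cargo(p, "values")) return(character())
    qdb_parse_values(qdb_get_cargo(p, "values"))$id
  }
  validation_ids <- unique(ids_of(prediction))
  training_ids <- unique(unlist(lapply(training, ids_of), use.names = FALSE))
  if (all(validation_ids %in% training_ids)) return("internal")
  if (!any(validation_ids %in% training_ids)) return("external")
  warning(sprintf("prediction '%s' mixes compounds inside and outside the training set; mixed sets should be divided into concrete validation and testing sets",
                  prediction_id), call. = FALSE)
  "mixed"
}

# ---- label queries --------------------------------------------------------

# grammar: expr := or ; or := and ('OR' and)* ; and := unary ('AND' unary)* ;
# unary := 'NOT' unary | '(' expr ')' | LABEL.  Keywords are case-sensitive;
# labels use the identifier charset; precedence NOT > AND > OR.
query_tokens <- function(expression) {
  tokens <- list()
  pos <- 1L
  n <- nchar(expression)
  while (pos <= n) {
    rest <- substr(expression, pos, n)
    ws <- regexpr("^\\s+", rest)
    if (ws > 0L) { pos <- pos + attr(ws, "match.length"); next }
    ch <- substr(expression, pos, pos)
    if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, text = ch, pos = pos)
      pos <- pos + 1L
      next
    }
    m <- regexpr("^[A-Za-z0-9._-]+", rest)
    if (m < 0L) {
      qdb_stop("qdb_query_syntax_error",
               sprintf("unexpected character '%s' at position %d", ch, pos),
               position = pos)
    }
    text <- substr(rest, 1L, attr(m, "match.length"))
    type <- if (text %in% c("AND", "OR", "NOT")) text else "LABEL"
    tokens[[length(tokens) + 1L]] <- list(type = type, text = text, pos = pos)
    pos <- pos + attr(m, "match.length")
  }
  tokens
}

parse_query <- function(expression) {
  tokens <- query_tokens(expression)
  i <- 1L
  peek <- function() if (i <= length(tokens)) tokens[[i]] else NULL
  take <- function() { t <- peek(); i <<- i + 1L; t }
  fail <- function(what, tok) {
    pos <- if (is.null(tok)) nchar(expression) + 1L else tok$pos
    qdb_stop("qdb_query_syntax_error",
             sprintf("%s at position %d", what, pos), position = pos)
  }
  parse_or <- function() {
    node <- parse_and()
    while (!is.null(peek()) && peek()$type == "OR") {
      take()
      node <- list(op = "or", lhs = node, rhs = parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_unary()
    while (!is.null(peek()) && peek()$type == "AND") {
      take()
      node <- list(op = "and", lhs = node, rhs = parse_unary())
    }
    node
  }
  parse_unary <- function() {
    tok <- peek()
    if (is.null(tok)) fail("unexpected end of expression", tok)
    if (tok$type == "NOT") {
      take()
      return(list(op = "not", rhs = parse_unary()))
    }
    if (tok$type == "(") {
      take()
      node <- parse_or()
      closing <- take()
      if (is.null(closing) || closing$type != ")") fail("expected ')'", closing)
      return(node)
    }
    if (tok$type == "LABEL") {
      take()
      return(list(op = "label", label = tok$text))
    }
    fail(sprintf("unexpected token '%s'", tok$text), tok)
  }
  node <- parse_or()
  leftover <- peek()
  if (!is.null(leftover)) fail(sprintf("unexpected token '%s'", leftover$text), leftover)
  node
}

eval_query <- function(node, labels) {
  switch(node$op,
         label = node$label %in% labels,
         not = !eval_query(node$rhs, labels),
         and = eval_query(node$lhs, labels) && eval_query(node$rhs, labels),
         or = eval_query(node$lhs, labels) || eval_query(node$rhs, labels))
}

#' Select containers by a boolean label expression
#'
#' Every label defines a set with the same name; a container may belong to
#' any number of sets.  The query grammar is `label`, `NOT e`, `e AND e`,
#' `e OR e` and parentheses, with case-sensitive keywords and precedence
#' `NOT > AND > OR`.  Matching is case-sensitive.
#'
#' @param registry a `qdb_registry` (or a `qdb_archive` plus `type`).
#' @param expression a query string.
#' @param type when `registry` is an archive: which registry to query.
#' @return identifiers of the matching members, in registry order.
#' @examples
#' r <- qdb_add(qdb_registry("compound"), qdb_compound("c1", labels = "train"))
#' qdb_query(r, "train AND NOT outlier")
#' @export
qdb_query <- function(registry, expression, type = "compound") {
  if (inherits(registry, "qdb_archive")) {
    registry <- qdb_registry_of(registry, type)
  }
  stopifnot(inherits(registry, "qdb_registry"))
  ast <- parse_query(expression)
  hit <- vapply(registry$members, function(member) eval_query(ast, member$labels),
                logical(1L))
  qdb_ids(registry)[hit]
}

# ---- summary --------------------------------------------------------------

#' Summarise an archive
#'
#' Per-type container counts, per-container cargo counts and the root
#' directory listing exactly as [qdb_save()] would serialise it (only
#' non-empty registries produce subdirectories).
#'
#' @param archive a `qdb_archive`.
#' @return a `qdb_summary` list with elements `name`, `counts` (named
#'   integer per registry subdirectory), `cargo_counts` (named integer per
#'   container path) and `root_listing` (character).
#' @export
qdb_summary <- function(archive) {
  stopifnot(inherits(archive, "qdb_archive"))
  counts <- vapply(.qdb_concrete, function(type)
    length(qdb_registry_of(archive, type)), integer(1L))
  names(counts) <- unname(.qdb_subdirs[.qdb_concrete])
  cargo_counts <- integer()
  for (type in .qdb_concrete) {
    for (member in qdb_registry_of(archive, type)$members) {
      cargo_counts[[container_path(type, member)]] <- length(member$payloads)
    }
  }
  root_listing <- c("archive.xml",
                    names(counts)[counts > 0L],
                    unique(vapply(names(archive$extras), function(p)
                      strsplit(p, "/", fixed = TRUE)[[1L]][1L], character(1L))))
  structure(list(name = archive$name,
                 counts = counts,
                 cargo_counts = cargo_counts,
                 root_listing = sort(unique(root_listing), method = "radix")),
            class = "qdb_summary")
}

#' @export
print.qdb_summary <- function(x, ...) {
  cat("<qdb archive summary>", if (!is.null(x$name)) sQuote(x$name), "\n")
  for (subdir in names(x$counts)) {
    cat(sprintf("  %-12s %d\n", subdir, x$counts[[subdir]]))
  }
  cat("  root:", paste(x$root_listing, collapse = ", "), "\n")
  invisible(x)
}
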