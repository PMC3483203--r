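# Stratified k-fold cross-validation and success-rate metrics.
#
# Sensitivity Sn = (N+ - miss+)/N+, specificity Sp = (N- - miss-)/N-,
# and the overall success rate Acc = 1 - (miss+ + miss-)/(N+ + N-),
# pooled over folds (micro-average).  Acc is the convex combination of
# Sn and Sp with weights N+/(N+ + N-) and N-/(N+ + N-), and equals 1
# iff no sequence of either class is mispredicted.

#' Stratified fold assignment
#'
#' Splits each class as evenly as possible across `k` folds, shuffled
#' deterministically under `seed`.
#'
#' @param y Class labels (each class must have at least `k` members).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector in `1..k` parallel to `y`.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- check_labels(y, length(y))
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2")
  counts <- table(y)
  if (any(counts < k))
    stop("each class needs at least k = ", k, " samples; counts: ",
         paste(counts, collapse = ", "))
  set.seed(seed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Success-rate metrics from miss counts
#'
#' @param n_pos,n_neg Class sizes.
#' @param miss_pos,miss_neg Numbers of mispredicted samples per class.
#' @param extra Optional named list merged into the result (fold count,
#'   seed, feature set, ...).
#' @return Object of class `"cd_eval"`: counts plus `sn`, `sp`, `acc`.
#' @examples
#' eval_metrics(5000, 5000, 50, 100)  # sn 0.99, sp 0.98, acc 0.985
#' @export
eval_metrics <- function(n_pos, n_neg, miss_pos, miss_neg, extra = list()) {
  stopifnot(miss_pos >= 0, miss_neg >= 0, miss_pos <= n_pos,
            miss_neg <= n_neg)
  out <- c(list(n_pos = n_pos, n_neg = n_neg,
                miss_pos = miss_pos, miss_neg = miss_neg,
                sn = (n_pos - miss_pos) / n_pos,
                sp = (n_neg - miss_neg) / n_neg,
                acc = (n_pos + n_neg - miss_pos - miss_neg) / (n_pos + n_neg)),
           extra)
  class(out) <- "cd_eval"
  out
}

#' @export
print.cd_eval <- function(x, ...) {
  cat("Cross-validated success rates\n")
  cat(sprintf("  positives: %d (missed %d)   Sn  = %.4f\n",
              x$n_pos, x$miss_pos, x$sn))
  cat(sprintf("  negatives: %d (missed %d)   Sp  = %.4f\n",
              x$n_neg, x$miss_neg, x$sp))
  cat(sprintf("  overall success rate        Acc = %.4f\n", x$acc))
  invisible(x)
}

#' Cross-validate a covariant discriminant model
#'
#' Stratified k-fold cross-validation: for each fold, fit on the other
#' k-1 folds and predict the held-out fold; miss counts are pooled over
#' folds before computing Sn/Sp/Acc.
#'
#' @param x Feature matrix.
#' @param y Labels (first level = positive class).
#' @param features Column subset to use (default all).
#' @param k Folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param ridge Ridge passed to [cd_fit()].
#' @param folds Optional precomputed fold assignment (overrides
#'   `k`/`seed`); used by [ifs()] to share one split across subset sizes.
#' @return A `"cd_eval"` with config recorded.
#' @export
cross_validate <- function(x, y, features = NULL, k = 5L, seed = 1L,
                           ridge = 0, folds = NULL) {
  x <- as.matrix(x)
  y <- check_labels(y, nrow(x))
  if (is.null(folds)) folds <- stratified_folds(y, k, seed)
  stopifnot(length(folds) == nrow(x))
  lev <- levels(y)
  miss <- c(0L, 0L)
  for (f in sort(unique(folds))) {
    test <- folds == f
    m <- cd_fit(x[!test, , drop = FALSE], y[!test], features, ridge)
    pred <- predict(m, x[test, , drop = FALSE])
    for (g in 1:2)
      miss[g] <- miss[g] + sum(pred != y[test] & y[test] == lev[g])
  }
  eval_metrics(sum(y == lev[1L]), sum(y == lev[2L]), miss[1L], miss[2L],
               extra = list(k = length(unique(folds)), seed = seed,
                            ridge = ridge,
                            features = features %||% seq_len(ncol(x))))
}

#' Per-property classification performance
#'
#' Restricts the full concatenated encoding to each property's
#' contiguous positional block in turn and cross-validates a covariant
#' discriminant in that sub-space, giving one Sn/Sp/Acc triple per
#' physicochemical property.  One fold assignment is shared by all 12
#' runs so the comparison is like-for-like.
#'
#' @param x Full feature matrix (`12 * (seq_length - 1)` columns).
#' @param y Labels.
#' @param seq_length Sequence length of the encoding (default 150).
#' @inheritParams cross_validate
#' @return `data.frame` with 12 rows: property, sn, sp, acc.
#' @export
per_property_rates <- function(x, y, seq_length = 150L, k = 5L, seed = 1L,
                               ridge = 0) {
  w <- seq_length - 1L
  if (ncol(x) != 12L * w)
    stop("expected the full ", 12L * w, "-column encoding")
  y <- check_labels(y, nrow(x))
  folds <- stratified_folds(y, k, seed)
  res <- lapply(1:12, function(j)
    cross_validate(x, y, features = property_block(j, seq_length),
                   ridge = ridge, folds = folds, seed = seed))
  data.frame(property = paste0("P", 1:12), name = property_names(),
             sn = vapply(res, `[[`, 0, "sn"),
             sp = vapply(res, `[[`, 0, "sp"),
             acc = vapply(res, `[[`, 0, "acc"))
}

#' Write an evaluation report
#'
#' Serializes a `"cd_eval"` (counts, rates, config) as JSON.
#'
#' @param eval A `"cd_eval"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  rec <- unclass(eval)
  rec$features <- NULL   # can be thousands of indices; keep report small
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
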