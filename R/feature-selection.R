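# F-score feature ranking and incremental feature selection (IFS).
#
# Per feature u the F-score is
#   F(u) = [ (mean+_u - mean_u)^2 + (mean-_u - mean_u)^2 ]
#          / [ var+_u + var-_u ]
# with per-class variances using divisor n-1; larger means more
# discriminative.  IFS walks the ranking, evaluating nested top-k
# subsets by cross-validation with ONE shared fold assignment, and
# picks the smallest k attaining the maximum overall success rate.

#' Per-feature F-scores
#'
#' @param x Feature matrix.
#' @param y Labels (two classes, each with >= 2 rows).
#' @param features Columns to score (default all).
#' @return Numeric vector of non-negative scores, one per requested
#'   feature.  A feature with zero within-class variance in both classes
#'   scores `Inf` if the class means differ and 0 if they coincide.
#' @examples
#' x <- cbind(c(1, 3, -1, -3))
#' f_score(x, c("a", "a", "b", "b"))  # 2
#' @export
f_score <- function(x, y, features = NULL) {
  x <- as.matrix(x)
  y <- check_labels(y, nrow(x))
  if (is.null(features)) features <- seq_len(ncol(x))
  lev <- levels(y)
  xp <- x[y == lev[1L], features, drop = FALSE]
  xn <- x[y == lev[2L], features, drop = FALSE]
  if (nrow(xp) < 2L || nrow(xn) < 2L)
    stop("both classes need at least 2 samples")
  mp <- colMeans(xp); mn <- colMeans(xn)
  m <- (colSums(xp) + colSums(xn)) / (nrow(xp) + nrow(xn))
  num <- (mp - m)^2 + (mn - m)^2
  den <- apply(xp, 2L, stats::var) + apply(xn, 2L, stats::var)
  s <- num / den
  # degenerate rule: zero variance in both classes
  zero <- den == 0
  s[zero] <- ifelse(mp[zero] != mn[zero], Inf, 0)
  unname(s)
}

#' Rank all features by F-score
#'
#' @inheritParams f_score
#' @return Object of class `"feature_ranking"`: list with `order`
#'   (feature indices, best first; ties broken by ascending original
#'   index) and `scores` (parallel to `order`, non-increasing).
#' @export
rank_features <- function(x, y) {
  s <- f_score(x, y)
  ord <- order(-s, seq_along(s))   # stable: ties by ascending index
  structure(list(order = ord, scores = s[ord]),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("Feature ranking by F-score:", length(x$order), "features\n")
  n <- min(10L, length(x$order))
  cat("  top:", paste(sprintf("#%d (%.3g)", x$order[1:n], x$scores[1:n]),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Incremental feature selection along an F-score ranking
#'
#' Evaluates nested top-k feature subsets \eqn{S_1 \subset S_2 \subset
#' \dots} of a ranking by stratified k-fold cross-validation of the
#' covariant discriminant, all subset sizes sharing one fold assignment
#' drawn once from `seed` so the curve is comparable point to point.
#' The optimal subset is the smallest k attaining the maximum overall
#' success rate.
#'
#' By default every subset size is evaluated.  For large feature spaces
#' `k_grid` thins the sweep (e.g. every 4th size); with
#' `refine = TRUE` all sizes adjacent to the running optimum are then
#' evaluated at full resolution.
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param ranking A `"feature_ranking"` from [rank_features()]
#'   (computed from `x`/`y` if `NULL`).
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for the shared fold assignment.
#' @param ridge Ridge for [cd_fit()].
#' @param k_grid Subset sizes to evaluate (default `1:ncol(x)`).
#' @param refine After a thinned sweep, also evaluate every size between
#'   the grid neighbours of the best grid point.
#' @return Object of class `"ifs_curve"`: `points` (data.frame k, sn,
#'   sp, acc), `optimal_k`, `optimal_set` (original feature indices),
#'   `ranking`.
#' @export
ifs <- function(x, y, ranking = NULL, folds = 5L, seed = 1L, ridge = 0,
                k_grid = NULL, refine = TRUE) {
  x <- as.matrix(x)
  y <- check_labels(y, nrow(x))
  if (is.null(ranking)) ranking <- rank_features(x, y)
  if (length(ranking$order) != ncol(x))
    stop("ranking must cover all ", ncol(x), " features")
  if (is.null(k_grid)) k_grid <- seq_len(ncol(x))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L) || any(k_grid > ncol(x)))
    stop("'k_grid' must lie in 1..", ncol(x))
  fold_assign <- stratified_folds(y, folds, seed)
  eval_k <- function(k) {
    r <- tryCatch(
      cross_validate(x, y, features = ranking$order[seq_len(k)],
                     ridge = ridge, folds = fold_assign, seed = seed),
      error = function(e) stop("IFS failed at subset size k = ", k, ": ",
                               conditionMessage(e)))
    c(k = k, sn = r$sn, sp = r$sp, acc = r$acc)
  }
  pts <- t(vapply(k_grid, eval_k, numeric(4L)))
  if (refine && length(k_grid) < ncol(x)) {
    i <- which.max(pts[, "acc"])
    lo <- if (i > 1L) k_grid[i - 1L] + 1L else k_grid[1L]
    hi <- if (i < length(k_grid)) k_grid[i + 1L] - 1L else k_grid[i]
    extra <- setdiff(seq(lo, hi), k_grid)
    if (length(extra))
      pts <- rbind(pts, t(vapply(extra, eval_k, numeric(4L))))
  }
  pts <- as.data.frame(pts[order(pts[, "k"]), , drop = FALSE])
  rownames(pts) <- NULL
  pts$k <- as.integer(pts$k)
  best <- pts$k[which.max(pts$acc)]   # which.max: smallest k on ties
  structure(list(points = pts,
                 optimal_k = best,
                 optimal_set = ranking$order[seq_len(best)],
                 ranking = ranking,
                 folds = folds, seed = seed),
            class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat("Incremental feature selection curve\n")
  cat(sprintf("  %d subset sizes evaluated (%d-fold CV, seed %d)\n",
              nrow(x$points), x$folds, x$seed))
  i <- match(x$optimal_k, x$points$k)
  cat(sprintf("  peak: k = %d, Acc = %.4f (Sn %.4f, Sp %.4f)\n",
              x$optimal_k, x$points$acc[i], x$points$sn[i], x$points$sp[i]))
  invisible(x)
}

#' Plot an IFS curve
#'
#' @param x An `"ifs_curve"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.ifs_curve <- function(x, ...) {
  graphics::plot(x$points$k, x$points$acc, type = "l",
                 xlab = "number of top-ranked features",
                 ylab = "overall success rate", ...)
  graphics::abline(v = x$optimal_k, lty = 2, col = "grey50")
  invisible(x)
}

#' Sign of each feature's association with the positive class
#'
#' Reports, per selected feature, the sign of the difference between
#' the positive- and negative-class means — which way the feature
#' correlates with nucleosome-forming sequences.
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param features Feature indices to report (default all).
#' @return Character vector (`"positive"`, `"negative"`, `"none"`)
#'   named by feature index.
#' @export
correlation_signs <- function(x, y, features = NULL) {
  x <- as.matrix(x)
  y <- check_labels(y, nrow(x))
  if (is.null(features)) features <- seq_len(ncol(x))
  if (!length(features)) stop("'features' must be non-empty")
  lev <- levels(y)
  d <- colMeans(x[y == lev[1L], features, drop = FALSE]) -
       colMeans(x[y == lev[2L], features, drop = FALSE])
  out <- ifelse(d > 0, "positive", ifelse(d < 0, "negative", "none"))
  names(out) <- as.character(features)
  out
}

#' Export an IFS curve and its optimal feature set
#'
#' Writes the curve as TSV (k, sn, sp, acc) and, optionally, the optimal
#' feature set as a text file of 1-based original indices with
#' property/position decoding.
#'
#' @param curve An `"ifs_curve"`.
#' @param path Curve TSV path.
#' @param features_path Optional path for the optimal-set listing.
#' @param seq_length Sequence length for index decoding.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(curve, path, features_path = NULL,
                            seq_length = 150L) {
  utils::write.table(curve$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(features_path)) {
    df <- data.frame(feature = curve$optimal_set,
                     label = decode_features(curve$optimal_set, seq_length))
    utils::write.table(df, features_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
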