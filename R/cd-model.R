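# Covariant (equal-prior quadratic) discriminant classifier.
#
# Per class g the model stores the mean vector mu_g and covariance C_g
# (unbiased, divisor N-1).  A query x is scored with
#     F(x; g) = (x - mu_g)' C_g^{-1} (x - mu_g) + ln |C_g|
# and assigned to the class with the smaller score; ties go to the
# positive (nucleosome) class.  With balanced classes and no prior term
# this is quadratic discriminant analysis with equal priors.

#' Fit a covariant discriminant model
#'
#' Estimates per-class mean and covariance on (a feature subset of) a
#' feature matrix.  The covariance uses the unbiased divisor N-1.  When
#' the per-class covariance is not positive definite (it cannot be when
#' the feature count exceeds the class size), a ridge is added to the
#' diagonal — the supplied `ridge`, plus an automatic fallback of
#' `1e-6 * trace(C)/p` escalated tenfold until a Cholesky factorization
#' succeeds — and the amount actually applied is recorded per class.
#'
#' @param x Numeric feature matrix, rows = samples.
#' @param y Class labels with two levels; the first level is the
#'   positive (nucleosome) class.
#' @param features Integer indices of the columns to use (an ordered
#'   subset of the original feature space); default all columns.
#' @param ridge Non-negative ridge added to each class covariance
#'   diagonal before inversion (default 0).
#' @param prior Optional length-2 numeric class priors (positive,
#'   negative) summing to 1; when supplied, `-2 ln prior_g` is added to
#'   the class score.  Off (`NULL`, equal-prior behaviour) by default.
#' @return An object of class `"cd_model"`: list with `positive` and
#'   `negative` class components (each holding `mean`, `cov`,
#'   `precision`, `log_det`, `n`, `ridge_used`), `features`,
#'   `input_dim`, `levels`, and `prior`.
#' @seealso [predict.cd_model()], [cross_validate()], [scan_sequence()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 1), 20), matrix(rnorm(60, -1), 20))
#' y <- rep(c("nucleosome", "linker"), each = 20)
#' m <- cd_fit(x, y)
#' table(predict(m, x), y)
#' @export
cd_fit <- function(x, y, features = NULL, ridge = 0, prior = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("feature matrix must be finite numeric")
  y <- check_labels(y, nrow(x))
  if (is.null(features)) features <- seq_len(ncol(x))
  features <- as.integer(features)
  if (any(features < 1L) || any(features > ncol(x)) ||
      anyDuplicated(features))
    stop("'features' must be distinct column indices of x")
  if (ridge < 0) stop("'ridge' must be >= 0")
  if (!is.null(prior)) {
    if (length(prior) != 2L || any(prior <= 0) ||
        abs(sum(prior) - 1) > 1e-8)
      stop("'prior' must be two positive probabilities summing to 1")
  }
  xs <- x[, features, drop = FALSE]
  lev <- levels(y)
  fit1 <- function(level) {
    rows <- xs[y == level, , drop = FALSE]
    if (nrow(rows) < 2L)
      stop("class '", level, "' has fewer than 2 samples")
    cm <- list(class_id = level,
               mean = colMeans(rows),
               cov = stats::cov(rows),
               n = nrow(rows))
    finish_class_model(cm, ridge)
  }
  structure(list(positive = fit1(lev[1L]),
                 negative = fit1(lev[2L]),
                 features = features,
                 input_dim = ncol(x),
                 levels = lev,
                 prior = prior),
            class = "cd_model")
}

# Regularize a class covariance until Cholesky succeeds; attach the
# precision matrix and log-determinant.  ridge_used is the total ridge
# actually on the diagonal.
finish_class_model <- function(cm, ridge = 0) {
  p <- length(cm$mean)
  C <- cm$cov
  C <- (C + t(C)) / 2            # enforce symmetry against FP drift
  applied <- ridge
  R <- try_chol(C + diag(applied, p))
  if (is.null(R)) {
    eps <- 1e-6 * sum(diag(C)) / p
    if (eps <= 0) eps <- 1e-8
    repeat {
      applied <- ridge + eps
      R <- try_chol(C + diag(applied, p))
      if (!is.null(R)) break
      eps <- eps * 10
      if (!is.finite(eps)) stop("covariance cannot be regularized")
    }
  }
  cm$cov <- C
  cm$ridge_used <- applied
  cm$precision <- chol2inv(R)
  cm$log_det <- 2 * sum(log(diag(R)))
  cm
}

try_chol <- function(M) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  # guard against near-zero pivots that chol() lets through
  if (!is.null(R) && any(diag(R) < sqrt(.Machine$double.eps))) return(NULL)
  R
}

#' Squared Mahalanobis distance to a class mean
#'
#' Computes \eqn{(x - \mu)' C^{-1} (x - \mu)} with the class's
#' (regularized) precision matrix; always non-negative, and zero exactly
#' at the class mean.
#'
#' @param x Numeric vector, or matrix with one sample per row.
#' @param class_model A class component of a [cd_fit()] model (e.g.
#'   `model$positive`).
#' @return Numeric vector of squared distances.
#' @export
mahalanobis_sq <- function(x, class_model) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != length(class_model$mean))
    stop("dimension mismatch: x has ", ncol(X), " columns, class model has ",
         length(class_model$mean))
  d <- sweep(X, 2L, class_model$mean)
  unname(rowSums((d %*% class_model$precision) * d))
}

#' Covariant discriminant score for one class
#'
#' The per-class score minimized at prediction time: squared Mahalanobis
#' distance plus the log-determinant of the class covariance.
#'
#' @inheritParams mahalanobis_sq
#' @return Numeric vector of scores.
#' @export
cd_discriminant <- function(x, class_model) {
  mahalanobis_sq(x, class_model) + class_model$log_det
}

# project full-width input down to the model's feature subset
project_features <- function(object, newdata) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  p <- length(object$positive$mean)
  if (ncol(X) == p) return(X)
  if (ncol(X) == object$input_dim)
    return(X[, object$features, drop = FALSE])
  stop("newdata has ", ncol(X), " columns; expected ", p,
       " (model features) or ", object$input_dim, " (full encoding)")
}

#' Predict class labels, margins, or raw scores
#'
#' Scores each sample against both class models and assigns the class
#' with the smaller covariant discriminant score.  An exact tie is
#' assigned to the positive (nucleosome) class.  The margin
#' `F(negative) - F(positive)` is a signed confidence: positive values
#' favour the nucleosome class.
#'
#' @param object A `"cd_model"`.
#' @param newdata Feature matrix (rows = samples) or single vector, in
#'   either the model's feature subspace or the full original space.
#' @param type `"class"` (factor, with the margins attached as attribute
#'   `"margin"`), `"margin"` (numeric), or `"scores"` (two-column matrix
#'   of per-class scores).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.cd_model <- function(object, newdata,
                             type = c("class", "margin", "scores"), ...) {
  type <- match.arg(type)
  X <- project_features(object, newdata)
  fp <- cd_discriminant(X, object$positive)
  fn <- cd_discriminant(X, object$negative)
  if (!is.null(object$prior)) {
    fp <- fp - 2 * log(object$prior[1L])
    fn <- fn - 2 * log(object$prior[2L])
  }
  switch(type,
    scores = cbind(positive = fp, negative = fn),
    margin = fn - fp,
    class = {
      cl <- factor(ifelse(fp <= fn, object$levels[1L], object$levels[2L]),
                   levels = object$levels)
      attr(cl, "margin") <- fn - fp
      cl
    })
}

#' @export
print.cd_model <- function(x, ...) {
  p <- length(x$positive$mean)
  cat("Covariant discriminant model\n")
  cat(sprintf("  classes: %s (n=%d) vs %s (n=%d)\n",
              x$levels[1L], x$positive$n, x$levels[2L], x$negative$n))
  cat(sprintf("  features: %d of %d\n", p, x$input_dim))
  cat(sprintf("  ln|C|: %+.4f (%s), %+.4f (%s)\n",
              x$positive$log_det, x$levels[1L],
              x$negative$log_det, x$levels[2L]))
  if (x$positive$ridge_used > 0 || x$negative$ridge_used > 0)
    cat(sprintf("  ridge applied: %.3g / %.3g\n",
                x$positive$ridge_used, x$negative$ridge_used))
  invisible(x)
}

#' @export
summary.cd_model <- function(object, ...) {
  p <- length(object$positive$mean)
  dmu <- object$positive$mean - object$negative$mean
  out <- list(n_features = p, input_dim = object$input_dim,
              levels = object$levels,
              n = c(object$positive$n, object$negative$n),
              log_det = c(object$positive$log_det, object$negative$log_det),
              ridge_used = c(object$positive$ridge_used,
                             object$negative$ridge_used),
              mean_separation = sqrt(sum(dmu^2)))
  class(out) <- "summary.cd_model"
  out
}

#' @export
print.summary.cd_model <- function(x, ...) {
  cat("Covariant discriminant model summary\n")
  cat(sprintf("  %s: n=%d, ln|C|=%+.4f, ridge=%.3g\n", x$levels[1L],
              x$n[1L], x$log_det[1L], x$ridge_used[1L]))
  cat(sprintf("  %s: n=%d, ln|C|=%+.4f, ridge=%.3g\n", x$levels[2L],
              x$n[2L], x$log_det[2L], x$ridge_used[2L]))
  cat(sprintf("  features: %d of %d; ||mu+ - mu-|| = %.4f\n",
              x$n_features, x$input_dim, x$mean_separation))
  invisible(x)
}

#' Class mean vectors of a fitted model
#'
#' @param object A `"cd_model"`.
#' @param ... Unused.
#' @return Matrix with one row per class (positive first), one column
#'   per model feature.
#' @export
coef.cd_model <- function(object, ...) {
  m <- rbind(object$positive$mean, object$negative$mean)
  rownames(m) <- object$levels
  m
}

#' Simulate feature vectors from a fitted model
#'
#' Draws samples from the two fitted class Gaussians (using the
#' regularized covariances), e.g. for parametric-bootstrap checks.
#'
#' @param object A `"cd_model"`.
#' @param nsim Samples per class.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List with feature matrix `x` (positives first) and labels `y`.
#' @export
simulate.cd_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(cm) {
    R <- chol(cm$cov + diag(cm$ridge_used, length(cm$mean)))
    z <- matrix(stats::rnorm(nsim * length(cm$mean)), nsim)
    sweep(z %*% R, 2L, cm$mean, "+")
  }
  x <- rbind(draw(object$positive), draw(object$negative))
  y <- factor(rep(object$levels, each = nsim), levels = object$levels)
  list(x = x, y = y)
}

#' Plot per-property class mean profiles of a full-encoding model
#'
#' For a model fitted on the full 1788-dimensional encoding of 150-bp
#' segments, draws the 12 per-property panels of the two class mean
#' profiles against window position.
#'
#' @param x A `"cd_model"` over the full encoding.
#' @param seq_length Sequence length the encoding was built from.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.cd_model <- function(x, seq_length = 150L, ...) {
  w <- seq_length - 1L
  if (length(x$features) != 12L * w)
    stop("plotting expects a model over the full ", 12L * w,
         "-dimensional encoding")
  op <- graphics::par(mfrow = c(4L, 3L), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (j in 1:12) {
    blk <- property_block(j, seq_length)
    graphics::matplot(seq_len(w),
                      cbind(x$positive$mean[blk], x$negative$mean[blk]),
                      type = "l", lty = 1, col = c("red3", "blue3"),
                      xlab = "", ylab = "", main = property_names()[j], ...)
  }
  invisible(x)
}
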