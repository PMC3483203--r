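# F-score ranking and incremental feature selection.

test_that("F-score matches the hand-computed toy and degenerate rules", {
  # positives {1, 3}, negatives {-1, -3}: numerator 8, denominator 4
  x <- cbind(c(1, 3, -1, -3))
  y <- c("a", "a", "b", "b")
  expect_equal(f_score(x, y), 2)
  # identical class distributions score zero
  x2 <- cbind(c(1, 2, 1, 2))
  expect_equal(f_score(x2, y), 0)
  # zero variance in both classes: Inf if means differ, 0 if equal
  x3 <- cbind(c(1, 1, 2, 2), c(3, 3, 3, 3))
  expect_equal(f_score(x3, y), c(Inf, 0))
})

test_that("F-score is affine- and permutation-invariant", {
  set.seed(20)
  x <- matrix(rnorm(40 * 6), 40)
  y <- rep(c("a", "b"), each = 20)
  s0 <- f_score(x, y)
  for (i in 1:5) {
    a <- runif(1, 0.2, 4); b <- rnorm(1)
    expect_equal(f_score(a * x + b, y), s0, tolerance = 1e-10)
    perm <- sample(nrow(x))
    expect_equal(f_score(x[perm, ], y[perm]), s0, tolerance = 1e-12)
  }
})

test_that("ranking is descending with stable index tie-break", {
  # columns 1 and 3 are identical (exact tie, tiny within-class
  # variance -> huge score); column 2 separates more in mean but with
  # much larger variance, so it scores lower
  x <- cbind(c(1, 1.1, -1, -1.1),
             c(5, 6, -5, -6),
             c(1, 1.1, -1, -1.1))
  y <- c("a", "a", "b", "b")
  r <- rank_features(x, y)
  expect_identical(r$order, c(1L, 3L, 2L))
  expect_true(all(diff(r$scores) <= 0))
})

test_that("ranking matches a naive re-scoring oracle", {
  set.seed(21)
  x <- matrix(rnorm(60 * 10), 60)
  x[, 4] <- x[, 4] + rep(c(2, 0), each = 30)
  y <- rep(c("a", "b"), each = 30)
  r <- rank_features(x, y)
  naive <- vapply(seq_len(ncol(x)), function(u) {
    xp <- x[y == "a", u]; xn <- x[y == "b", u]
    ((mean(xp) - mean(x[, u]))^2 + (mean(xn) - mean(x[, u]))^2) /
      (var(xp) + var(xn))
  }, 0)
  expect_identical(r$order, order(-naive, seq_along(naive)))
  expect_identical(r$order[1L], 4L)   # the planted feature ranks first
})

test_that("planted informative features outrank all noise features", {
  set.seed(22)
  g <- gen_gaussian(n_per_class = 150, p = 20, informative = c(3, 11, 17),
                    delta = 3, seed = 22)
  r <- rank_features(g$x, g$y)
  expect_setequal(r$order[1:3], c(3L, 11L, 17L))
})

test_that("IFS finds the plateau, nests subsets, and is deterministic", {
  g <- gen_gaussian(n_per_class = 100, p = 10, informative = 1:2,
                    delta = 3, seed = 23)
  curve <- ifs(g$x, g$y, folds = 5, seed = 23)
  expect_identical(nrow(curve$points), 10L)           # full 1..N sweep
  expect_identical(curve$points$k, 1:10)
  # signal lives in exactly two features: the optimum is small and the
  # curve has plateaued by k = 2
  expect_lte(curve$optimal_k, 4L)
  acc_at <- function(k) curve$points$acc[match(k, curve$points$k)]
  expect_gt(acc_at(2L), 0.9)
  expect_lt(max(curve$points$acc) - acc_at(2L), 0.05)
  # nesting S_k subset of S_{k+1} along the evaluated sizes
  for (i in seq_len(nrow(curve$points) - 1L)) {
    sk <- curve$ranking$order[seq_len(curve$points$k[i])]
    sk1 <- curve$ranking$order[seq_len(curve$points$k[i + 1L])]
    expect_true(all(sk %in% sk1))
  }
  # same seed twice -> identical curve
  curve2 <- ifs(g$x, g$y, folds = 5, seed = 23)
  expect_identical(curve$points, curve2$points)
  expect_identical(curve$optimal_set, curve2$optimal_set)
})

test_that("a thinned IFS grid refines around the running peak", {
  g <- gen_gaussian(n_per_class = 80, p = 12, informative = 1:3,
                    delta = 2, seed = 24)
  curve <- ifs(g$x, g$y, seed = 24, k_grid = c(1, 4, 8, 12), refine = TRUE)
  expect_true(all(c(1, 4, 8, 12) %in% curve$points$k))
  # the optimum attains the maximum Acc, at the smallest such k
  best <- curve$points[curve$points$k == curve$optimal_k, ]
  expect_equal(best$acc, max(curve$points$acc))
  smaller <- curve$points$k < curve$optimal_k
  if (any(smaller))
    expect_true(all(curve$points$acc[smaller] < best$acc))
})

test_that("correlation signs report the direction of the mean difference", {
  x <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 1, 1, 1))
  y <- c("a", "a", "b", "b")
  expect_identical(unname(correlation_signs(x, y)),
                   c("positive", "negative", "none"))
  set.seed(25)
  xr <- matrix(rnorm(40), 10)
  yr <- rep(c("a", "b"), each = 5)
  sg <- correlation_signs(xr, yr)
  d <- colMeans(xr[1:5, ]) - colMeans(xr[6:10, ])
  expect_identical(unname(sg), ifelse(d > 0, "positive", "negative"))
  expect_error(correlation_signs(x, y, integer(0)), "non-empty")
})

test_that("IFS curve export writes the curve and decoded feature set", {
  g <- gen_gaussian(n_per_class = 50, p = 8, informative = 1:2,
                    delta = 3, seed = 26)
  curve <- ifs(g$x, g$y, seed = 26)
  tsv <- tempfile(fileext = ".tsv"); feats <- tempfile(fileext = ".tsv")
  write_ifs_curve(curve, tsv, feats, seq_length = 3L)  # 8 <= 12*(3-1)
  got <- read.delim(tsv)
  expect_identical(names(got), c("k", "sn", "sp", "acc"))
  expect_identical(nrow(got), nrow(curve$points))
  expect_identical(read.delim(feats)$feature, curve$optimal_set)
})
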