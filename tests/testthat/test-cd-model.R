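# Covariant discriminant classifier: fitting, scoring, prediction.

test_that("per-class mean and covariance follow the N-1 convention", {
  x <- rbind(c(0, 0), c(2, 2), c(5, 1), c(6, 0), c(7, 2))
  y <- c("nucleosome", "nucleosome", "linker", "linker", "linker")
  m <- cd_fit(x, y)
  expect_equal(unname(m$positive$mean), c(1, 1))
  # hand sum: (0-1)^2 + (2-1)^2 = 2, divisor N-1 = 1
  expect_equal(unname(diag(m$positive$cov)), c(2, 2))
  expect_equal(m$positive$ridge_used, 0)
  # precision really inverts the covariance
  expect_equal(m$negative$precision %*% m$negative$cov, diag(2),
               tolerance = 1e-10)
})

test_that("singular covariance triggers recorded ridge regularization", {
  set.seed(2)
  base <- matrix(rnorm(12), 6)
  x <- cbind(base, base[, 1])            # duplicated feature column
  y <- rep(c("a", "b"), each = 3)
  m <- cd_fit(x, y)
  expect_gt(m$positive$ridge_used, 0)
  expect_gt(m$negative$ridge_used, 0)
  # regularized covariance is positive definite
  expect_true(all(eigen(m$positive$cov +
                        diag(m$positive$ridge_used, 3))$values > 0))
})

test_that("fit rejects degenerate inputs", {
  x <- matrix(rnorm(8), 4)
  expect_error(cd_fit(x, c("a", "a", "a", "b")), "fewer than 2")
  x[1, 1] <- NA
  expect_error(cd_fit(x, c("a", "a", "b", "b")), "finite")
  expect_error(cd_fit(matrix(rnorm(8), 4), c("a", "a", "b", "b"),
                      features = c(1, 1)), "distinct")
})

test_that("squared Mahalanobis distance matches brute-force algebra", {
  set.seed(3)
  x <- rbind(matrix(rnorm(30), 10), matrix(rnorm(30, 2), 10))
  y <- rep(c("a", "b"), each = 10)
  m <- cd_fit(x, y)
  # zero at the class mean, identity reduction, non-negativity
  expect_equal(mahalanobis_sq(m$positive$mean, m$positive), 0)
  cm_id <- nucleoscan:::finish_class_model(
    list(class_id = "x", mean = c(0, 0), cov = diag(2), n = 10))
  expect_equal(mahalanobis_sq(c(3, 4), cm_id), 25)
  for (i in 1:10) {
    q <- rnorm(3)
    d_pkg <- mahalanobis_sq(q, m$positive)
    d_ora <- mahal_oracle(q, m$positive$mean, m$positive$cov)
    expect_equal(d_pkg, d_ora, tolerance = 1e-10)
    expect_gte(d_pkg, 0)
  }
  expect_error(mahalanobis_sq(c(1, 2), m$positive), "dimension")
})

test_that("discriminant adds the class log-determinant", {
  cm_id <- nucleoscan:::finish_class_model(
    list(class_id = "x", mean = c(1, -1), cov = diag(2), n = 10))
  expect_equal(cd_discriminant(c(4, 3), cm_id), sum(c(3, 4)^2))  # ln|I| = 0
  cm2 <- nucleoscan:::finish_class_model(
    list(class_id = "x", mean = c(0, 0), cov = 2 * diag(2), n = 10))
  expect_equal(cd_discriminant(c(0, 0), cm2), 2 * log(2))
  # scaling the covariance up strictly increases the ln-det term
  cm3 <- nucleoscan:::finish_class_model(
    list(class_id = "x", mean = c(0, 0), cov = 3 * diag(2), n = 10))
  expect_gt(cm3$log_det, cm2$log_det)
})

test_that("prediction picks the nearer class; exact ties go positive", {
  cm <- function(mu) nucleoscan:::finish_class_model(
    list(class_id = "x", mean = mu, cov = diag(2), n = 10))
  m <- structure(list(positive = cm(c(1, 0)), negative = cm(c(-1, 0)),
                      features = 1:2, input_dim = 2L,
                      levels = c("nucleosome", "linker"), prior = NULL),
                 class = "cd_model")
  expect_identical(as.character(predict(m, c(0.9, 0))), "nucleosome")
  expect_identical(as.character(predict(m, c(-0.9, 0))), "linker")
  # x = (0, y): exactly equidistant, equal covariances -> positive
  expect_identical(as.character(predict(m, c(0, 3))), "nucleosome")
  expect_equal(predict(m, c(0, 3), type = "margin"), 0)
  # margin sign convention: positive favours nucleosome
  expect_gt(predict(m, c(2, 0), type = "margin"), 0)
})

test_that("predictions equal an independent QDA oracle on random instances", {
  n_agree <- 0L
  for (s in 1:30) {
    inst <- rand_gauss_instance(1000 + s)
    m <- cd_fit(inst$x, inst$y, ridge = 0)
    expect_equal(m$positive$ridge_used, 0)
    pred <- as.character(predict(m, inst$x))
    ora <- qda_oracle_predict(inst$x, inst$y, inst$x)
    expect_identical(pred, ora)
    n_agree <- n_agree + 1L
  }
  expect_identical(n_agree, 30L)
})

test_that("predictions match MASS::qda with equal priors", {
  skip_if_not_installed("MASS")
  for (s in 1:3) {
    inst <- rand_gauss_instance(77 + s)
    m <- cd_fit(inst$x, inst$y, ridge = 0)
    q <- MASS::qda(inst$x, inst$y, prior = c(0.5, 0.5))
    expect_identical(as.character(predict(m, inst$x)),
                     as.character(predict(q, inst$x)$class))
  }
})

test_that("prediction is invariant under a common invertible linear map", {
  set.seed(5)
  inst <- rand_gauss_instance(123)
  A <- matrix(rnorm(inst$p^2), inst$p) + diag(inst$p)
  m1 <- cd_fit(inst$x, inst$y, ridge = 0)
  m2 <- cd_fit(inst$x %*% A, inst$y, ridge = 0)
  p1 <- as.character(predict(m1, inst$x))
  p2 <- as.character(predict(m2, inst$x %*% A))
  # loose tolerance: allow a handful of flips from conditioning
  expect_gt(mean(p1 == p2), 0.99)
})

test_that("fitting recovers generating parameters as n grows", {
  err <- vapply(c(100L, 10000L), function(n) {
    g <- gen_gaussian(n_per_class = n, p = 4L, informative = 1:2,
                      delta = 1, seed = 99L)
    m <- cd_fit(g$x, g$y)
    max(abs(m$positive$mean - g$mu_pos),
        abs(m$positive$cov - g$sigma))
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.1)
})

test_that("optional prior term shifts the decision boundary", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, 1), 20), matrix(rnorm(40, -1), 20))
  y <- rep(c("a", "b"), each = 20)
  m0 <- cd_fit(x, y)
  m1 <- cd_fit(x, y, prior = c(0.999, 0.001))
  # a heavy positive prior can only increase positive calls
  expect_gte(sum(predict(m1, x) == "a"), sum(predict(m0, x) == "a"))
})

test_that("serialized models round-trip with identical predictions", {
  set.seed(7)
  inst <- rand_gauss_instance(55)
  m <- cd_fit(inst$x, inst$y)
  path <- tempfile(fileext = ".json")
  write_cd_model(m, path)
  m2 <- read_cd_model(path)
  expect_identical(m2$features, m$features)
  expect_equal(m2$positive$mean, m$positive$mean)
  expect_identical(as.character(predict(m2, inst$x)),
                   as.character(predict(m, inst$x)))
  expect_error(read_cd_model(write_temp_fasta(c(a = "ACGT"))))
})

test_that("simulate draws reproducibly from the fitted Gaussians", {
  set.seed(8)
  inst <- rand_gauss_instance(66)
  m <- cd_fit(inst$x, inst$y)
  s1 <- simulate(m, nsim = 50, seed = 4)
  s2 <- simulate(m, nsim = 50, seed = 4)
  expect_identical(s1$x, s2$x)
  expect_identical(dim(s1$x), c(100L, inst$p))
})
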