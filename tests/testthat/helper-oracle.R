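# Independent brute-force oracles used to cross-check the classifier.

# Equal-prior quadratic discriminant, coded from first principles:
# per-class mean by summation, covariance by explicit centered cross
# product with divisor n-1, score via solve() and det().  Ties go to
# the first class level.
qda_oracle_predict <- function(xtr, ytr, xte) {
  lev <- levels(factor(ytr, levels = unique(ytr)))
  params <- lapply(lev, function(g) {
    rows <- xtr[ytr == g, , drop = FALSE]
    n <- nrow(rows)
    mu <- colSums(rows) / n
    ctr <- sweep(rows, 2, mu)
    C <- t(ctr) %*% ctr / (n - 1)
    list(mu = mu, Cinv = solve(C), logdet = log(det(C)))
  })
  score <- function(x, p) {
    d <- x - p$mu
    drop(t(d) %*% p$Cinv %*% d) + p$logdet
  }
  apply(xte, 1L, function(x) {
    f <- vapply(params, function(p) score(x, p), 0)
    lev[which.min(f)]   # which.min keeps the first (positive) on ties
  })
}

# brute-force triple product for the squared Mahalanobis distance
mahal_oracle <- function(x, mu, C) drop(t(x - mu) %*% solve(C) %*% (x - mu))

# random well-conditioned two-Gaussian instance (n rows per class > p)
rand_gauss_instance <- function(seed) {
  set.seed(seed)
  p <- sample(2:20, 1L)
  n <- sample(seq(2 * p + 5L, 200L), 1L)   # per class; keeps cov full rank
  mk_cov <- function() {
    A <- matrix(rnorm(p * p), p)
    crossprod(A) / p + diag(p)
  }
  r_mvn <- function(n, mu, C) {
    sweep(matrix(rnorm(n * p), n) %*% chol(C), 2, mu, "+")
  }
  mu1 <- rnorm(p); mu2 <- rnorm(p)
  x <- rbind(r_mvn(n, mu1, mk_cov()), r_mvn(n, mu2, mk_cov()))
  y <- factor(rep(c("nucleosome", "linker"), each = n),
              levels = c("nucleosome", "linker"))
  list(x = x, y = y, p = p, n = n)
}

# tiny labeled FASTA pair written to a temp dir
write_temp_fasta <- function(seqs, file = tempfile(fileext = ".fa")) {
  write_fasta(seqs, file)
  file
}

rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")
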