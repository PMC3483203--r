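# Synthetic fixtures: labeled Gaussian feature matrices with known
# parameters, and two-class 150-bp sequence sets with controllable
# separability.  These emulate the benchmark's structure (two balanced
# classes of fixed-length segments) for testing; they are test
# fixtures, not a biological model of nucleosome sequence.

#' Two-class Gaussian feature matrix with known parameters
#'
#' Draws `n_per_class` samples per class from multivariate normals with
#' identity covariance; only the `informative` features separate the
#' class means (positive class shifted by `delta`).  True parameters
#' and the closed-form Bayes success rate `pnorm(||mu+ - mu-|| / 2)`
#' are returned for recovery and calibration tests.
#'
#' @param n_per_class Samples per class.
#' @param p Feature count.
#' @param informative Indices of mean-separated features.
#' @param delta Mean shift on each informative feature.
#' @param seed Integer seed (identical config => identical output).
#' @return List: `x`, `y` (levels `nucleosome`, `linker`), `mu_pos`,
#'   `mu_neg`, `sigma`, `bayes_rate`.
#' @export
gen_gaussian <- function(n_per_class = 200L, p = 10L, informative = 1:2,
                         delta = 1, seed = 1L) {
  stopifnot(p >= 1L, n_per_class >= 2L)
  if (length(informative) &&
      (min(informative) < 1L || max(informative) > p))
    stop("'informative' indices must lie in 1..p")
  set.seed(seed)
  mu_pos <- numeric(p); mu_pos[informative] <- delta
  mu_neg <- numeric(p)
  x <- rbind(matrix(stats::rnorm(n_per_class * p), n_per_class,
                    byrow = TRUE) + rep(mu_pos, each = n_per_class),
             matrix(stats::rnorm(n_per_class * p), n_per_class,
                    byrow = TRUE) + rep(mu_neg, each = n_per_class))
  y <- factor(rep(c("nucleosome", "linker"), each = n_per_class),
              levels = c("nucleosome", "linker"))
  list(x = x, y = y, mu_pos = mu_pos, mu_neg = mu_neg,
       sigma = diag(p),
       bayes_rate = stats::pnorm(sqrt(sum((mu_pos - mu_neg)^2)) / 2))
}

# one positive (nucleosome-like) sequence: i.i.d. uniform background
# with a favoured dinucleotide (AA/TT/TA/GC) planted at ~10-bp period
.gen_pos_seq <- function(len, effect) {
  s <- sample(BASES, len, replace = TRUE)
  for (a in seq(1L, len - 1L, by = 10L)) {
    if (stats::runif(1) < effect) {
      d <- sample(c("AA", "TT", "TA", "GC"), 1L)
      s[a] <- substr(d, 1L, 1L); s[a + 1L] <- substr(d, 2L, 2L)
    }
  }
  paste(s, collapse = "")
}

# one negative (linker-like) sequence: background enriched in A/T
# homopolymer runs
.gen_neg_seq <- function(len, effect, run = 5L) {
  s <- sample(BASES, len, replace = TRUE)
  for (a in seq(1L, len - run, by = 10L)) {
    if (stats::runif(1) < effect)
      s[a:(a + run - 1L)] <- sample(c("A", "T"), 1L)
  }
  paste(s, collapse = "")
}

#' Generate a paired two-class FASTA benchmark stand-in
#'
#' Writes a positive file of nucleosome-like sequences (a ~10-bp
#' periodic planting of the favoured dinucleotides AA/TT/TA/GC over a
#' uniform background) and a negative file of linker-like sequences
#' (A/T homopolymer runs over the same background), plus a JSON truth
#' record of the generating parameters.  At `effect_size = 0` both
#' classes are the identical i.i.d. uniform background (null case).
#'
#' @param n_per_class Sequences per class.
#' @param seq_length Sequence length in bp (default 150).
#' @param effect_size Planting rate in `[0, 1]`; 0 = null, 1 = every
#'   periodic slot carries signal.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return List with paths `positive`, `negative`, `truth`, and the
#'   parameter list `config`.
#' @export
gen_sequences <- function(n_per_class = 200L, seq_length = 150L,
                          effect_size = 1, seed = 1L,
                          dir = tempfile("synthseq")) {
  if (seq_length < 2L) stop("'seq_length' must be >= 2")
  if (effect_size < 0 || effect_size > 1)
    stop("'effect_size' must lie in [0, 1]")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  pos <- vapply(seq_len(n_per_class),
                function(i) .gen_pos_seq(seq_length, effect_size), "")
  neg <- vapply(seq_len(n_per_class),
                function(i) .gen_neg_seq(seq_length, effect_size), "")
  names(pos) <- sprintf("nuc_%04d", seq_len(n_per_class))
  names(neg) <- sprintf("lnk_%04d", seq_len(n_per_class))
  paths <- list(positive = file.path(dir, "positive.fa"),
                negative = file.path(dir, "negative.fa"),
                truth = file.path(dir, "truth.json"))
  write_fasta(pos, paths$positive)
  write_fasta(neg, paths$negative)
  config <- list(n_per_class = n_per_class, seq_length = seq_length,
                 effect_size = effect_size, seed = seed,
                 positive_model = "10-bp periodic AA/TT/TA/GC planting",
                 negative_model = "A/T homopolymer runs, 10-bp slots")
  jsonlite::write_json(config, paths$truth, auto_unbox = TRUE,
                       pretty = TRUE)
  c(paths, list(config = config))
}
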