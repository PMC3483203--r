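# Dinucleotide physicochemical property table and scale normalization.

DINUCLEOTIDES <- paste0(rep(c("A", "C", "G", "T"), each = 4L),
                        rep(c("A", "C", "G", "T"), times = 4L))

PROPERTY_NAMES <- c(
  "A-philicity", "base stacking", "B-DNA twist", "bendability",
  "DNA bending stiffness", "DNA denaturation", "duplex disrupt energy",
  "duplex free energy", "propeller twist", "protein deformation",
  "protein-DNA twist", "Z-DNA")

# cache for the shipped table (read once per session)
.nucleoscan_env <- new.env(parent = emptyenv())

#' Shipped dinucleotide physicochemical property table
#'
#' Returns the canonical 16 x 12 matrix of normalized dinucleotide
#' physicochemical values used for sequence encoding: one row per
#' dinucleotide (AA, AC, ..., TT in lexicographic order), one column per
#' property in the frozen order P1 "A-philicity" through P12 "Z-DNA".
#'
#' The values are shipped verbatim as canonical constants.  Most lie in
#' \eqn{[-1, 1]} but a few exceed 1 (e.g. bendability of TA is 2.37);
#' they are used as-is and are never re-normalized.
#'
#' @return A numeric matrix with 16 rows (dinucleotides) and 12 columns
#'   (`P1` ... `P12`).  Attribute `property_names` carries the long
#'   property names in column order.
#' @seealso [property_lookup()], [normalize_scale()], [encode_sequence()]
#' @examples
#' tab <- dinuc_property_table()
#' tab["AA", "P1"]   # A-philicity of AA
#' @export
dinuc_property_table <- function() {
  if (!is.null(.nucleoscan_env$property_table))
    return(.nucleoscan_env$property_table)
  path <- system.file("extdata", "dinucleotide_properties.tsv",
                      package = "nucleoscan")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged property table 'dinucleotide_properties.tsv' is missing")
  df <- utils::read.delim(path, comment.char = "#", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!identical(df[[1L]], DINUCLEOTIDES) || ncol(df) != 13L)
    stop("packaged property table is malformed: expected 16 dinucleotide ",
         "rows AA..TT and 12 property columns")
  m <- as.matrix(df[, -1L])
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    stop("packaged property table contains non-finite values")
  dimnames(m) <- list(DINUCLEOTIDES, paste0("P", 1:12))
  attr(m, "property_names") <- PROPERTY_NAMES
  .nucleoscan_env$property_table <- m
  m
}

#' Look up one normalized property value for a dinucleotide
#'
#' @param dinuc Two-letter DNA string over A/C/G/T; case-insensitive.
#' @param property Property identifier: an integer 1..12, `"P4"`, or a
#'   long name such as `"bendability"`.
#' @param table Property matrix, by default the shipped table.
#' @return The normalized value (a single number).
#' @examples
#' property_lookup("AA", 1)              # 0.85
#' property_lookup("ta", "bendability")  # 2.37
#' @export
property_lookup <- function(dinuc, property, table = dinuc_property_table()) {
  dinuc <- toupper(as.character(dinuc))
  if (length(dinuc) != 1L || !dinuc %in% DINUCLEOTIDES)
    stop("invalid dinucleotide '", dinuc,
         "': expected two characters from {A,C,G,T}")
  j <- match_property(property)
  table[dinuc, j]
}

# resolve a property given as index, "P<i>", or long name -> column index
match_property <- function(property) {
  if (is.numeric(property)) {
    j <- as.integer(property)
  } else {
    p <- as.character(property)
    j <- match(toupper(p), paste0("P", 1:12))
    if (is.na(j)) j <- match(tolower(p), tolower(PROPERTY_NAMES))
  }
  if (is.na(j) || j < 1L || j > 12L)
    stop("unknown property identifier: ", deparse(substitute(property)),
         " (use 1..12, 'P1'..'P12', or a property name)")
  j
}

#' Min-max normalize a user-supplied dinucleotide scale to [-1, 1]
#'
#' Linearly rescales the 16 original values of a dinucleotide scale so
#' that the minimum maps to -1 and the maximum to +1:
#' \deqn{\tilde x = 2 (x - \min x) / (\max x - \min x) - 1.}
#' This is a utility for adding user-supplied scales; the shipped table
#' is canonical and is not regenerated with it.
#'
#' @param raw Named numeric vector of 16 original values, names covering
#'   all 16 dinucleotides (any order, case-insensitive).
#' @return Named numeric vector in table row order (AA ... TT), with
#'   minimum exactly -1 and maximum exactly +1.
#' @examples
#' normalize_scale(setNames(1:16, dinuc_names()))
#' @export
normalize_scale <- function(raw) {
  if (length(raw) != 16L)
    stop("expected 16 dinucleotide values, got ", length(raw))
  names(raw) <- toupper(names(raw))
  if (!setequal(names(raw), DINUCLEOTIDES) || anyDuplicated(names(raw)))
    stop("names of 'raw' must be exactly the 16 dinucleotides AA..TT")
  raw <- raw[DINUCLEOTIDES]
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("all 16 original values must be finite")
  rng <- range(raw)
  if (rng[1] == rng[2])
    stop("constant scale (max == min): normalization undefined")
  2 * (raw - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Dinucleotide and property names
#'
#' `dinuc_names()` returns the 16 dinucleotides in table row order;
#' `property_names()` the 12 property long names in frozen column order.
#' @return Character vector.
#' @export
dinuc_names <- function() DINUCLEOTIDES

#' @rdname dinuc_names
#' @export
property_names <- function() PROPERTY_NAMES
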