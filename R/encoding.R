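# Sequence -> physicochemical feature-vector encoding.
#
# A sequence of length L is read with a 2-bp window and 1-bp step, giving
# an (L-1)-long profile per property; the 12 profiles are concatenated
# property-major (all of P1, then all of P2, ...).  For the canonical
# 150-bp segments this yields 12 * 149 = 1788 components.

BASES <- c("A", "C", "G", "T")

# integer codes 1..4 for A,C,G,T; NA for anything else
.base_codes <- function(chars) match(chars, BASES)

# dinucleotide row indices (1..16) for a sequence string; NA where a
# window overlaps a non-ACGT character
dinuc_indices <- function(residues) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) stop("sequence must have length >= 2")
  code <- .base_codes(chars)
  4L * (code[-n] - 1L) + code[-1L]
}

check_strict <- function(idx, id = "<sequence>") {
  bad <- which(is.na(idx))
  if (length(bad))
    stop("sequence '", id, "' contains non-ACGT bases at window position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  idx
}

#' Encode one sequence as a single-property positional profile
#'
#' Slides a 2-bp window with 1-bp step along the sequence and replaces
#' each dinucleotide by its normalized value for one physicochemical
#' property, giving a numeric profile of length L - 1 (149 for a 150-bp
#' segment).  Windows are indexed 1-based by start position on the given
#' (forward) strand.
#'
#' @param residues DNA sequence as a character string (case-insensitive).
#' @param property Property identifier (1..12, `"P4"`, or long name).
#' @param table Property matrix, default the shipped table.
#' @param id Sequence id used in error messages.
#' @return Numeric vector of length `nchar(residues) - 1`.
#' @examples
#' encode_property("AAA", "P1")  # c(0.85, 0.85)
#' @export
encode_property <- function(residues, property,
                            table = dinuc_property_table(),
                            id = "<sequence>") {
  idx <- check_strict(dinuc_indices(residues), id)
  j <- match_property(property)
  unname(table[idx, j])
}

#' Encode one sequence as the full concatenated feature vector
#'
#' Concatenates the 12 per-property profiles in the frozen property
#' order: components 1..(L-1) are the A-philicity profile, the next
#' (L-1) the base-stacking profile, and so on through Z-DNA.  A 150-bp
#' sequence yields a 1788-dimensional vector.
#'
#' @inheritParams encode_property
#' @return Numeric vector of length `12 * (nchar(residues) - 1)`.
#' @seealso [encode_fasta()] for whole files, [encode_property()] for a
#'   single property block.
#' @export
encode_sequence <- function(residues, table = dinuc_property_table(),
                            id = "<sequence>") {
  idx <- check_strict(dinuc_indices(residues), id)
  # column-major flattening of the (L-1) x 12 value matrix gives the
  # property-major concatenation
  as.vector(table[idx, , drop = FALSE])
}

#' Column index block for one property in a full feature matrix
#'
#' For feature vectors over sequences of length `seq_length`, returns
#' the column indices belonging to one property's positional block.
#'
#' @param property Property identifier.
#' @param seq_length Sequence length L (default 150).
#' @return Integer vector of length `seq_length - 1`.
#' @export
property_block <- function(property, seq_length = 150L) {
  j <- match_property(property)
  w <- seq_length - 1L
  (j - 1L) * w + seq_len(w)
}

#' Decode feature indices to property/position labels
#'
#' Maps 1-based feature-vector indices back to `"P<i>:pos<p>"` labels,
#' where `p` is the 1-based window start position.
#'
#' @param features Integer feature indices.
#' @param seq_length Sequence length the vectors were built from.
#' @return Character vector of labels.
#' @export
decode_features <- function(features, seq_length = 150L) {
  w <- seq_length - 1L
  stopifnot(all(features >= 1L), all(features <= 12L * w))
  p <- (features - 1L) %/% w + 1L
  pos <- (features - 1L) %% w + 1L
  sprintf("P%d:pos%d", p, pos)
}

#' Encode a FASTA file into a feature matrix
#'
#' Reads a FASTA file and encodes every record with [encode_sequence()].
#' Records are uppercased on ingest; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param expected_length If set (training mode uses 150), every record
#'   must have exactly this length; offending ids are reported.
#' @param table Property matrix.
#' @return Numeric matrix, one row per record, with record ids as row
#'   names.  All records must share one length.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", strrep("ACGT", 38), "AC"), fa)
#' dim(encode_fasta(fa))  # 1 x 1788
#' @export
encode_fasta <- function(path, expected_length = NULL,
                         table = dinuc_property_table()) {
  seqs <- read_fasta(path)
  if (!is.null(expected_length)) {
    bad <- nchar(seqs) != expected_length
    if (any(bad))
      stop("records with length != ", expected_length, " in '", path, "': ",
           paste(utils::head(names(seqs)[bad], 10L), collapse = ", "),
           if (sum(bad) > 10L) " ..." else "")
  }
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L)
    stop("records in '", path, "' have unequal lengths; encode them ",
         "separately or set expected_length")
  x <- t(vapply(seq_along(seqs),
                function(i) encode_sequence(seqs[[i]], table, names(seqs)[i]),
                numeric(12L * (lens - 1L))))
  rownames(x) <- names(seqs)
  x
}

#' Read a labeled two-file training set
#'
#' Encodes a positive (nucleosome-forming) and a negative (linker) FASTA
#' file, each of fixed-length records, into one feature matrix with a
#' parallel label factor.  Labels are carried per file.
#'
#' @param positive,negative Paths to the two FASTA files.
#' @param expected_length Required record length (default 150).
#' @param table Property matrix.
#' @return List with `x` (feature matrix, positives first), `y` (factor
#'   with levels `nucleosome`, `linker`), and `ids`.
#' @export
read_training_set <- function(positive, negative, expected_length = 150L,
                              table = dinuc_property_table()) {
  xp <- encode_fasta(positive, expected_length, table)
  xn <- encode_fasta(negative, expected_length, table)
  x <- rbind(xp, xn)
  y <- factor(rep(c("nucleosome", "linker"), c(nrow(xp), nrow(xn))),
              levels = c("nucleosome", "linker"))
  list(x = x, y = y, ids = rownames(x))
}

#' Per-class component-wise mean profiles
#'
#' Computes the per-class mean feature vector (the class "standard
#' vector"): the component-wise arithmetic mean over all rows of each
#' class.  These are the curves plotted in per-property profile panels.
#'
#' @param x Feature matrix (rows = sequences).
#' @param y Class labels, two levels, positives first.
#' @return List with `positive` and `negative` mean vectors.
#' @export
class_mean_profiles <- function(x, y) {
  y <- check_labels(y, nrow(x))
  lev <- levels(y)
  if (any(tabulate(y, 2L) == 0L)) stop("both classes must be non-empty")
  list(positive = colMeans(x[y == lev[1L], , drop = FALSE]),
       negative = colMeans(x[y == lev[2L], , drop = FALSE]))
}

# normalize labels to a 2-level factor, first level = positive class
check_labels <- function(y, n) {
  if (!is.factor(y)) y <- factor(y, levels = unique(y))
  if (length(y) != n) stop("labels must parallel the matrix rows")
  if (nlevels(y) != 2L) stop("exactly two classes required, got ", nlevels(y))
  y
}

#' Export a feature matrix as TSV
#'
#' Writes `id`, `label`, then one column per feature component, for
#' debugging and interoperability.
#'
#' @param x Feature matrix with row names.
#' @param y Optional labels (else "unknown").
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path, y = NULL) {
  lab <- if (is.null(y)) rep("unknown", nrow(x)) else as.character(y)
  df <- data.frame(id = rownames(x) %||% seq_len(nrow(x)), label = lab,
                   x, check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("f", seq_len(ncol(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
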