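# Sliding-window scanning of arbitrary-length sequences.
#
# Every window of the model's training length (150 bp by default) is
# encoded and classified; a sequence of length L yields L - 149 windows,
# numbered 1-based by start position (#1 ... #(L-149)).  Runs of
# consecutive equal labels are merged into segment calls, which tile the
# window range without gaps and alternate labels.

# window length implied by a model over the full concatenated encoding
model_window_length <- function(model) {
  if (model$input_dim %% 12L != 0L)
    stop("model input dimension ", model$input_dim,
         " is not a full 12-property encoding")
  model$input_dim %/% 12L + 1L
}

# all-window feature matrix restricted to the model's feature subset:
# window w, feature f=(j-1)*(win-1)+p  ->  profile[w + p - 1, j]
window_feature_matrix <- function(idx, model, table, win) {
  w1 <- win - 1L
  nwin <- length(idx) - w1 + 1L
  V <- table[idx, , drop = FALSE]         # (L-1) x 12 profile matrix
  feats <- model$features
  prop <- (feats - 1L) %/% w1 + 1L
  pos <- (feats - 1L) %% w1 + 1L
  starts <- seq_len(nwin)
  X <- matrix(0, nwin, length(feats))
  for (i in seq_along(feats))
    X[, i] <- V[starts + pos[i] - 1L, prop[i]]
  X
}

#' Scan a sequence with a sliding 150-bp window
#'
#' Classifies every window of the model's training length along a
#' sequence (step 1 bp) and merges consecutive windows sharing a label
#' into segment calls.
#'
#' @param residues DNA sequence (character string), length >= the
#'   window length.
#' @param model A `"cd_model"` fitted on the full concatenated encoding
#'   (any feature subset of it).
#' @param id Sequence id for the report.
#' @param table Property matrix.
#' @param policy `"strict"` (error on non-ACGT bases) or `"skip"` (drop
#'   windows overlapping ambiguous bases and report them).
#' @return A `data.frame` of class `"segment_calls"` with columns
#'   `sequence_id`, `first_window`, `last_window`, `label`, `n_windows`.
#'   Attribute `window_labels` carries the per-window label vector
#'   (`NA` for dropped windows) and `n_dropped` the dropped count.
#' @examples
#' \dontrun{
#' scan_sequence(my_502bp_sequence, model)  # 353 windows
#' }
#' @export
scan_sequence <- function(residues, model, id = "<sequence>",
                          table = dinuc_property_table(),
                          policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  win <- model_window_length(model)
  L <- nchar(residues)
  if (L < win)
    stop("sequence '", id, "' shorter than window: ", L, " < ", win, " bp")
  idx <- dinuc_indices(residues)
  if (policy == "strict") check_strict(idx, id)
  nwin <- L - win + 1L
  # windows touching an ambiguous base (NA dinucleotide index)
  bad_dinuc <- which(is.na(idx))
  drop <- rep(FALSE, nwin)
  for (b in bad_dinuc)
    drop[max(1L, b - win + 2L):min(nwin, b)] <- TRUE
  labels <- rep(NA_character_, nwin)
  if (any(!drop)) {
    idx_clean <- idx
    idx_clean[is.na(idx_clean)] <- 1L   # placeholder; rows later masked
    X <- window_feature_matrix(idx_clean, model, table, win)
    pred <- as.character(predict(model, X[!drop, , drop = FALSE]))
    labels[!drop] <- pred
  }
  segs <- merge_window_labels(labels, id)
  attr(segs, "window_labels") <- labels
  attr(segs, "n_dropped") <- sum(drop)
  class(segs) <- c("segment_calls", "data.frame")
  segs
}

# run-length merge of per-window labels (NA runs are omitted from calls)
merge_window_labels <- function(labels, id) {
  r <- rle(labels)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  keep <- !is.na(r$values)
  data.frame(sequence_id = id,
             first_window = first[keep],
             last_window = last[keep],
             label = r$values[keep],
             n_windows = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Expand segment calls back to per-window labels
#'
#' Inverse of the merge step: reconstructs the label of every window
#' from a segment-call table (the merge is lossless).
#'
#' @param segments A `"segment_calls"` data.frame for one sequence.
#' @return Character vector of per-window labels.
#' @export
expand_segments <- function(segments) {
  n <- max(segments$last_window)
  out <- rep(NA_character_, n)
  for (i in seq_len(nrow(segments)))
    out[segments$first_window[i]:segments$last_window[i]] <-
      segments$label[i]
  out
}

#' Convert segment calls to BED intervals
#'
#' Window `w` covers the 0-based half-open interval `[w-1, w+win-1)` on
#' its sequence; a merged segment spans from its first window's start to
#' its last window's end.  Scores are window counts.
#'
#' @param segments A `"segment_calls"` data.frame.
#' @param window_length Window length used in the scan (default 150).
#' @param path Optional output path; when given, writes BED6.
#' @return The BED `data.frame` (invisibly if written).
#' @export
segments_to_bed <- function(segments, window_length = 150L, path = NULL) {
  bed <- data.frame(chrom = segments$sequence_id,
                    start = segments$first_window - 1L,
                    end = segments$last_window + window_length - 1L,
                    name = segments$label,
                    score = segments$n_windows,
                    strand = "+",
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

#' Classify or scan every record of a FASTA file
#'
#' Records exactly one window long get a single verdict; longer records
#' are scanned with [scan_sequence()].  Records shorter than the window
#' produce a per-record error entry and the run continues.
#'
#' @param path FASTA input.
#' @param model A `"cd_model"`.
#' @param table Property matrix.
#' @param policy Ambiguity policy, see [scan_sequence()].
#' @return List with `segments` (combined `"segment_calls"` table over
#'   all records) and `errors` (named character vector of per-record
#'   failures; empty when all records scanned).
#' @export
scan_fasta <- function(path, model, table = dinuc_property_table(),
                       policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  seqs <- read_fasta(path)
  segs <- list()
  errors <- character()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    res <- tryCatch(scan_sequence(seqs[[i]], model, id, table, policy),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) errors[id] <- res else segs[[id]] <- res
  }
  out <- if (length(segs)) do.call(rbind, c(segs, make.row.names = FALSE))
         else merge_window_labels(character(), "")[0L, ]
  class(out) <- c("segment_calls", "data.frame")
  list(segments = out, errors = errors)
}
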