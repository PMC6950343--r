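# Prefiltering: score discretized profiles with affine-gap Smith-Waterman
# so that only promising pairs receive a full co-emission alignment.

#' Smith-Waterman score between two state sequences
#'
#' Best local-alignment score with affine gaps over the alphabet's integer
#' substitution matrix. A gap of length `g` costs
#' `gap_open + g * gap_extend`. The score is non-negative and symmetric in
#' its arguments; an empty sequence scores 0.
#'
#' @param s1,s2 `state_sequence` objects (or plain integer vectors of state
#'   indices) over the same alphabet.
#' @param alphabet The shared [column_alphabet()].
#' @param gap_open,gap_extend Affine gap parameters in matrix units
#'   (defaults 6 and 1 at substitution scale 2).
#' @return Integer score.
#' @export
smith_waterman <- function(s1, s2, alphabet, gap_open = 6, gap_extend = 1) {
  stopifnot(inherits(alphabet, "column_alphabet"))
  s1 <- as.integer(s1); s2 <- as.integer(s2)
  if (length(s1) == 0 || length(s2) == 0) return(0L)
  if (max(s1, s2) > alphabet$K || min(s1, s2) < 1)
    stop("state indices outside the alphabet")
  sw_score_cpp(s1, s2, alphabet$subst, as.integer(gap_open),
               as.integer(gap_extend))
}

#' All-vs-all Smith-Waterman prefilter scores
#'
#' @param seqs Named list of `state_sequence`s (one per model).
#' @inheritParams smith_waterman
#' @return Symmetric integer matrix of SW scores with model names as
#'   dimnames (diagonal = self scores).
#' @export
prefilter_scores <- function(seqs, alphabet, gap_open = 6, gap_extend = 1) {
  n <- length(seqs)
  nm <- vapply(seqs, function(s) attr(s, "name") %||% "", character(1))
  if (any(nm == "")) nm <- names(seqs) %||% paste0("m", seq_len(n))
  S <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n))
    for (j in i:n) {
      S[i, j] <- S[j, i] <- smith_waterman(seqs[[i]], seqs[[j]], alphabet,
                                           gap_open, gap_extend)
    }
  S
}

#' Select candidate pairs by prefilter score
#'
#' Retains pairs either above an absolute score threshold or within each
#' query's top N scores. Self pairs are always retained and the output is
#' symmetric: if `(i, j)` is kept so is `(j, i)`.
#'
#' @param seqs Named list of `state_sequence`s.
#' @param mode `"threshold"` or `"topN"`.
#' @param value Threshold score, or N for `"topN"`.
#' @inheritParams smith_waterman
#' @param scores Optional precomputed matrix from [prefilter_scores()].
#' @return A tibble with columns `query`, `target`, `sw_score`, `keep`,
#'   one row per unordered pair (including self pairs).
#' @export
prefilter_pairs <- function(seqs, mode = c("threshold", "topN"), value,
                            alphabet = NULL, gap_open = 6, gap_extend = 1,
                            scores = NULL) {
  mode <- match.arg(mode)
  if (missing(value) || !is.numeric(value) || length(value) != 1 || is.na(value))
    stop("prefilter value must be a single number")
  if (mode == "topN" && value < 0) stop("topN value must be >= 0")
  if (is.null(scores))
    scores <- prefilter_scores(seqs, alphabet, gap_open, gap_extend)
  n <- nrow(scores)
  keep <- matrix(FALSE, n, n)
  diag(keep) <- TRUE
  if (mode == "threshold") {
    keep <- keep | (scores >= value)
  } else {
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      top <- others[order(scores[i, others], decreasing = TRUE)]
      keep[i, head(top, value)] <- TRUE
    }
  }
  keep <- keep | t(keep)  # symmetric closure
  idx <- which(upper.tri(keep, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(query = rownames(scores)[idx[, 1]],
                 target = colnames(scores)[idx[, 2]],
                 sw_score = scores[idx],
                 keep = keep[idx])
}
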