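# Shared constants and small numeric helpers.

# HMMER3 amino-acid column order (alphabetical one-letter codes).
AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Robinson & Robinson amino-acid background frequencies, reordered to the
# HMMER column order and renormalized. Used whenever a profile carries no
# composition line of its own.
.AA_BACKGROUND_RAW <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
)

#' Standard amino-acid background frequencies
#'
#' Robinson-Robinson frequencies in HMMER column order (ACDEFGHIKLMNPQRSTVWY),
#' normalized to sum to one. This is the default null model used for
#' co-emission scoring and pseudocount construction when a profile file does
#' not supply its own composition.
#'
#' @return Named numeric vector of 20 probabilities.
#' @export
#' @examples
#' sum(aa_background())
aa_background <- function() {
  .AA_BACKGROUND_RAW / sum(.AA_BACKGROUND_RAW)
}

# Transition column layout used throughout: row k of a transition matrix
# holds the probabilities out of node k (row 0/1 in R indexing = BEGIN).
TRANS_COLS <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

# log2(sum(2^x)) without overflow; -Inf-safe.
logsumexp2 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log2(sum(2^(x - m)))
}

# Normalize a non-negative vector to sum 1; all-zero input falls back to
# the supplied default.
norm1 <- function(x, default = NULL) {
  s <- sum(x)
  if (s <= 0) {
    if (is.null(default)) stop("cannot normalize an all-zero vector")
    return(default)
  }
  x / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic k-means under a fixed seed; Hartigan-Wong can abort on an
# empty cluster for degenerate inputs, in which case MacQueen is used.
safe_kmeans <- function(X, K, seed, nstart = 5) {
  set.seed(seed)
  tryCatch(
    suppressWarnings(kmeans(X, centers = K, iter.max = 100, nstart = nstart)),
    error = function(e) {
      set.seed(seed)
      suppressWarnings(kmeans(X, centers = K, iter.max = 100, nstart = nstart,
                              algorithm = "MacQueen"))
    })
}
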