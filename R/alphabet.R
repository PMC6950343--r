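# Column-state alphabet: a small set of representative amino-acid
# distributions that discretizes profile columns into letters, turning
# pHMM-pHMM comparison into fast string alignment.

#' Construct a column-state alphabet
#'
#' @param profiles K x 20 matrix of state profiles (rows sum to 1).
#' @param background Background frequencies used for the log-odds
#'   substitution matrix.
#' @param scale Integer quantization scale for the substitution matrix in
#'   half-bits per unit (default 2).
#' @param floor_bits Log-odds floor in bits applied before quantization
#'   (default -16), so orthogonal point-mass states get a finite minimum.
#' @return Object of class `column_alphabet` with fields `K`,
#'   `state_profiles`, `subst`, `scale`, `floor_bits`, `background`.
#' @export
column_alphabet <- function(profiles, background = aa_background(),
                            scale = 2, floor_bits = -16) {
  profiles <- as.matrix(profiles)
  K <- nrow(profiles)
  if (K < 1) stop("a column-state alphabet needs at least one state")
  if (ncol(profiles) != 20 || any(abs(rowSums(profiles) - 1) > 1e-6))
    stop("state profiles must be K x 20 rows summing to 1")
  colnames(profiles) <- AA
  structure(list(K = K, state_profiles = profiles,
                 subst = state_substitution_matrix(profiles, background,
                                                   scale, floor_bits),
                 scale = scale, floor_bits = floor_bits,
                 background = norm1(background)),
            class = "column_alphabet")
}

#' @export
print.column_alphabet <- function(x, ...) {
  cat(sprintf("Column-state alphabet: %d letters (substitution scale %g)\n",
              x$K, x$scale))
  invisible(x)
}

#' Train a column-state alphabet by k-means on profile columns
#'
#' Clusters 20-dimensional probability columns in square-root coordinates
#' (so squared Euclidean distance approximates the Hellinger geometry of
#' distributions) into `K` states. Each state's profile is the mean of its
#' assigned original probability columns, renormalized. Deterministic under
#' the given seed. The default `K = 219` is the standard discretized-alphabet
#' size for profile prefiltering.
#'
#' @param columns N x 20 matrix of probability columns, `N >= K`.
#' @param K Number of states (default 219).
#' @param seed Integer seed.
#' @inheritParams column_alphabet
#' @return A [column_alphabet()].
#' @export
train_alphabet <- function(columns, K = 219, seed = 1,
                           background = aa_background(), scale = 2,
                           floor_bits = -16) {
  columns <- as.matrix(columns)
  if (nrow(columns) < K)
    stop(sprintf("%d columns cannot support K = %d states; reduce K",
                 nrow(columns), K))
  km <- safe_kmeans(sqrt(columns), K, seed)
  prof <- matrix(0, K, 20)
  for (k in seq_len(K)) {
    members <- columns[km$cluster == k, , drop = FALSE]
    prof[k, ] <- norm1(colMeans(members))
  }
  column_alphabet(prof, background, scale, floor_bits)
}

#' Log-odds substitution matrix between column states
#'
#' `S(a, b) = round(scale * log2(sum_x p_a(x) p_b(x) / f(x)))` — the
#' quantized co-emission log-odds of two states against the background —
#' floored at `scale * floor_bits`. Symmetric by construction.
#'
#' @param alphabet A `column_alphabet` or a K x 20 profile matrix.
#' @param background Length-20 background frequencies.
#' @param scale Quantization scale.
#' @param floor_bits Floor (bits) for zero or tiny co-emission.
#' @return K x K integer matrix.
#' @export
state_substitution_matrix <- function(alphabet, background = aa_background(),
                                      scale = 2, floor_bits = -16) {
  prof <- if (inherits(alphabet, "column_alphabet"))
    alphabet$state_profiles else as.matrix(alphabet)
  background <- norm1(background)
  if (any(background <= 0)) stop("background must be strictly positive")
  co <- prof %*% diag(1 / background) %*% t(prof)
  lo <- suppressWarnings(log2(co))
  lo[!is.finite(lo) | lo < floor_bits] <- floor_bits
  S <- round(scale * lo)
  storage.mode(S) <- "integer"
  (S + t(S)) %/% 2L  # exact symmetry despite rounding of float noise
}

#' Discretize a profile HMM to a state sequence
#'
#' Each match column is assigned the alphabet state with the maximum
#' co-emission log-odds against it (ties broken by the lowest state index).
#'
#' @param model A `profile_hmm`.
#' @param alphabet A [column_alphabet()].
#' @return Object of class `state_sequence`: integer vector of state indices
#'   in `1..K` with attributes `name` and `K`.
#' @export
discretize <- function(model, alphabet) {
  stopifnot(inherits(model, "profile_hmm"), inherits(alphabet, "column_alphabet"))
  odds <- t(model$match) / alphabet$background          # 20 x L
  A <- alphabet$state_profiles %*% odds                 # K x L co-emission
  states <- apply(A, 2, which.max)                      # first max = lowest index
  structure(as.integer(states), name = model$name, K = alphabet$K,
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("State sequence '%s': length %d over %d letters\n",
              attr(x, "name"), length(x), attr(x, "K")))
  invisible(x)
}

#' Read or write a column-state alphabet via the context-library format
#'
#' An alphabet is stored as a context library with window length 1 (one
#' prior plus one 20-probability row per state); the substitution matrix is
#' recomputed on load.
#'
#' @param path File path.
#' @inheritParams column_alphabet
#' @return `read_alphabet`: a [column_alphabet()]; `write_alphabet`: `path`.
#' @export
read_alphabet <- function(path, background = aa_background(), scale = 2,
                          floor_bits = -16) {
  lib <- read_context_library(path)
  if (lib$w != 1)
    stop("alphabet files must have window length 1 (found w = ", lib$w, ")")
  prof <- do.call(rbind, lib$profiles)
  column_alphabet(prof, background, scale, floor_bits)
}

#' @rdname read_alphabet
#' @param alphabet A `column_alphabet` to serialize.
#' @export
write_alphabet <- function(alphabet, path) {
  stopifnot(inherits(alphabet, "column_alphabet"))
  lib <- context_library(lapply(seq_len(alphabet$K), function(k)
    alphabet$state_profiles[k, , drop = FALSE]))
  write_context_library(lib, path)
}

#' The package's default 219-letter alphabet
#'
#' Trains the default column-state alphabet (K = 219) from a fixed internal
#' corpus of simulated profile columns under a fixed seed, so no external
#' alphabet download is needed. Cached per session.
#'
#' @param K Number of states (default 219).
#' @return A [column_alphabet()].
#' @export
default_alphabet <- function(K = 219) {
  key <- paste0("default_alphabet_", K)
  if (is.null(.prcx_cache[[key]])) {
    hmms <- make_toy_hmms(n = 40, L = 30, seed = 20190219)
    cols <- do.call(rbind, lapply(hmms, function(h) h$match))
    .prcx_cache[[key]] <- train_alphabet(cols, K = K, seed = 20190219)
  }
  .prcx_cache[[key]]
}
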