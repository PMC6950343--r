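# Co-emission scoring of profile HMM pairs over the five-state pair HMM
# {MM, MI, IM, DG, GD}. A pair step's weight is the product of the two
# models' component transition probabilities; insert states contribute
# transition weight only (inserts are near-background, co-emitting them
# mostly adds noise). All scores are in bits (log2).

#' Co-emission score of two profile columns
#'
#' `log2(sum_a q1(a) q2(a) / f(a))` — the log-odds that both columns emit
#' the same residue relative to the background. Symmetric in `q1`, `q2`;
#' floored at `floor_bits` when the co-emission sum is zero (orthogonal
#' point masses).
#'
#' @param q1,q2 Length-20 probability vectors.
#' @param background Length-20 strictly positive background frequencies.
#' @param floor_bits Minimum returned value (default -16 bits).
#' @return Score in bits.
#' @export
#' @examples
#' pm <- c(1, rep(0, 19))
#' coemission_column_score(pm, pm, rep(1 / 20, 20))  # log2(20)
coemission_column_score <- function(q1, q2, background = aa_background(),
                                    floor_bits = -16) {
  if (any(background <= 0)) stop("background must be strictly positive")
  s <- sum(q1 * q2 / background)
  max(floor_bits, log2(max(s, 0)))
}

# L1 x L2 matrix of column co-emission scores (bits).
coemission_matrix <- function(h1, h2, background, floor_bits = -16) {
  co <- h1$match %*% (t(h2$match) / background)  # vector recycles over rows
  lo <- suppressWarnings(log2(co))
  lo[!is.finite(lo) | lo < floor_bits] <- floor_bits
  lo
}

# Shared comparison background: the normalized average of the two models'
# own backgrounds (a single null must be common to both sides).
pair_background <- function(h1, h2, background = NULL) {
  norm1(background %||% ((h1$background + h2$background) / 2))
}

.pair_dp <- function(h1, h2, mode, forward, want_trace = FALSE,
                     background = NULL, floor_bits = -16) {
  stopifnot(inherits(h1, "profile_hmm"), inherits(h2, "profile_hmm"))
  bg <- pair_background(h1, h2, background)
  S <- coemission_matrix(h1, h2, bg, floor_bits)
  ta <- suppressWarnings(log2(h1$transitions))
  tb <- suppressWarnings(log2(h2$transitions))
  pair_dp_cpp(S, ta, tb, mode == "local", forward, want_trace)
}

new_pair_score <- function(h1, h2, mode, forward_bits = NA_real_,
                           viterbi_bits = NA_real_, trace = NULL) {
  structure(list(query = h1$name, target = h2$name,
                 qlen = h1$L, tlen = h2$L, mode = mode,
                 forward_bits = forward_bits, viterbi_bits = viterbi_bits,
                 trace = trace),
            class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf("Pair score %s vs %s (%s): forward %s bits, Viterbi %s bits\n",
              x$query, x$target, x$mode,
              format(x$forward_bits, digits = 6),
              format(x$viterbi_bits, digits = 6)))
  invisible(x)
}

#' Forward (summed) co-emission score of two profile HMMs
#'
#' Log-sum over all co-emission alignment paths of the five-state pair HMM.
#' In local mode (the default used for tree building) any match-match cell
#' can start or end a path at no cost; in global mode paths are anchored at
#' the model ends through the BEGIN and exit transitions. This local forward
#' score is the "simple" co-emission score used for distance matrices.
#'
#' @param h1,h2 `profile_hmm` objects.
#' @param mode `"local"` (default) or `"global"`.
#' @param background Optional shared null model; defaults to the normalized
#'   average of the two models' backgrounds.
#' @param floor_bits Column-score floor in bits.
#' @return A `pair_score` with `forward_bits` filled.
#' @export
pair_forward <- function(h1, h2, mode = c("local", "global"),
                         background = NULL, floor_bits = -16) {
  mode <- match.arg(mode)
  r <- .pair_dp(h1, h2, mode, forward = TRUE, background = background,
                floor_bits = floor_bits)
  new_pair_score(h1, h2, mode, forward_bits = r$score)
}

#' Viterbi (best-path) co-emission score of two profile HMMs
#'
#' As [pair_forward()] but maximizing over paths; returns the best path
#' score and its trace as a matrix of `(i, j, state)` steps, where state is
#' 1 = MM, 2 = MI, 3 = IM, 4 = DG, 5 = GD.
#'
#' @inheritParams pair_forward
#' @param want_trace Keep the best alignment trace (default `TRUE`).
#' @return A `pair_score` with `viterbi_bits` (and `trace`) filled.
#' @export
pair_viterbi <- function(h1, h2, mode = c("local", "global"),
                         background = NULL, floor_bits = -16,
                         want_trace = TRUE) {
  mode <- match.arg(mode)
  r <- .pair_dp(h1, h2, mode, forward = FALSE, want_trace = want_trace,
                background = background, floor_bits = floor_bits)
  tr <- r$trace
  if (!is.null(tr)) colnames(tr) <- c("i", "j", "state")
  new_pair_score(h1, h2, mode, viterbi_bits = r$score, trace = tr)
}

#' Compare two profile HMMs (forward and Viterbi)
#'
#' @inheritParams pair_forward
#' @return One-row tibble: query, target, lengths, forward and Viterbi bits.
#' @export
compare_hmms <- function(h1, h2, mode = c("local", "global"),
                         background = NULL) {
  mode <- match.arg(mode)
  f <- pair_forward(h1, h2, mode, background = background)
  v <- pair_viterbi(h1, h2, mode, background = background, want_trace = FALSE)
  tibble::tibble(query = h1$name, target = h2$name, qlen = h1$L, tlen = h2$L,
                 mode = mode, forward_bits = f$forward_bits,
                 viterbi_bits = v$viterbi_bits)
}

#' Reverse-normalized co-emission score
#'
#' The simple (forward) score of `h1` against `h2` minus the score of `h1`
#' against the position-reversed `h2` — an optional normalization that
#' cancels composition-driven signal. Near zero for palindromic targets.
#'
#' @inheritParams pair_forward
#' @return Difference in bits.
#' @export
reverse_score <- function(h1, h2, mode = c("local", "global"),
                          background = NULL) {
  mode <- match.arg(mode)
  pair_forward(h1, h2, mode, background = background)$forward_bits -
    pair_forward(h1, reverse_hmm(h2), mode, background = background)$forward_bits
}

#' Brute-force enumeration of all pair-HMM alignment paths
#'
#' Reference implementation for validating [pair_forward()] and
#' [pair_viterbi()]: recursively enumerates every path of the five-state
#' pair HMM (feasible only for very short models) and returns all path
#' scores, whose max is the Viterbi score and whose log-sum-exp is the
#' forward score.
#'
#' @inheritParams pair_forward
#' @return Numeric vector of path scores in bits.
#' @export
enumerate_pair_alignments <- function(h1, h2, mode = c("local", "global"),
                                      background = NULL, floor_bits = -16) {
  mode <- match.arg(mode)
  bg <- pair_background(h1, h2, background)
  S <- coemission_matrix(h1, h2, bg, floor_bits)
  ta <- suppressWarnings(log2(h1$transitions))  # row k+1 = node k
  tb <- suppressWarnings(log2(h2$transitions))
  L1 <- h1$L; L2 <- h2$L
  acc <- new.env(parent = emptyenv())
  acc$w <- numeric(0)
  emit <- function(x) if (is.finite(x)) acc$w <- c(acc$w, x)
  # state codes: MM, MI, IM, DG, GD; (i, j) = match columns consumed
  step <- function(st, i, j, wgt) {
    if (!is.finite(wgt)) return(invisible())
    if (mode == "local" && st == "MM") emit(wgt)
    if (mode == "global" && i == L1 && j == L2 && !(i == 0 && j == 0)) {
      if (st == "MM") emit(wgt + ta[L1 + 1, "MM"] + tb[L2 + 1, "MM"])
      if (st == "DG") emit(wgt + ta[L1 + 1, "DM"] + tb[L2 + 1, "MM"])
      if (st == "GD") emit(wgt + ta[L1 + 1, "MM"] + tb[L2 + 1, "DM"])
    }
    if (st %in% c("MM")) {
      if (i < L1 && j < L2)
        step("MM", i + 1, j + 1, wgt + ta[i + 1, "MM"] + tb[j + 1, "MM"] +
               S[i + 1, j + 1])
      if (i < L1) {
        step("MI", i + 1, j, wgt + ta[i + 1, "MM"] + tb[j + 1, "MI"])
        step("DG", i + 1, j, wgt + ta[i + 1, "MD"])
      }
      if (j < L2) {
        step("IM", i, j + 1, wgt + ta[i + 1, "MI"] + tb[j + 1, "MM"])
        step("GD", i, j + 1, wgt + tb[j + 1, "MD"])
      }
    } else if (st == "MI") {
      if (i < L1)
        step("MI", i + 1, j, wgt + ta[i + 1, "MM"] + tb[j + 1, "II"])
      if (i < L1 && j < L2)
        step("MM", i + 1, j + 1, wgt + ta[i + 1, "MM"] + tb[j + 1, "IM"] +
               S[i + 1, j + 1])
    } else if (st == "IM") {
      if (j < L2)
        step("IM", i, j + 1, wgt + ta[i + 1, "II"] + tb[j + 1, "MM"])
      if (i < L1 && j < L2)
        step("MM", i + 1, j + 1, wgt + ta[i + 1, "IM"] + tb[j + 1, "MM"] +
               S[i + 1, j + 1])
    } else if (st == "DG") {
      if (i < L1)
        step("DG", i + 1, j, wgt + ta[i + 1, "DD"])
      if (i < L1 && j < L2)
        step("MM", i + 1, j + 1, wgt + ta[i + 1, "DM"] + tb[j + 1, "MM"] +
               S[i + 1, j + 1])
    } else if (st == "GD") {
      if (j < L2)
        step("GD", i, j + 1, wgt + tb[j + 1, "DD"])
      if (i < L1 && j < L2)
        step("MM", i + 1, j + 1, wgt + ta[i + 1, "MM"] + tb[j + 1, "DM"] +
               S[i + 1, j + 1])
    }
    invisible()
  }
  if (mode == "global") {
    step("MM", 0, 0, 0)  # virtual start at the BEGIN nodes
  } else {
    for (i in seq_len(L1))
      for (j in seq_len(L2))
        step("MM", i, j, S[i, j])  # free entry at any match-match cell
  }
  acc$w
}
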