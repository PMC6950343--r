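#' Construct a profile HMM
#'
#' In-memory representation of a protein profile hidden Markov model in the
#' plan-7 style: per match node a 20-dimensional match emission distribution,
#' an insert emission distribution, and a 7-tuple of transition probabilities
#' `(M->M, M->I, M->D, I->M, I->I, D->M, D->D)`. Transition row `k` holds the
#' probabilities out of node `k`; row 1 (node 0) is the BEGIN node and the
#' final row doubles as the exit row (`M->M` there is `M->E`, `D->M` is
#' `D->E`), mirroring the HMMER3 layout.
#'
#' @param name Model identifier (single string).
#' @param match L x 20 matrix of match emission probabilities, columns in
#'   order `ACDEFGHIKLMNPQRSTVWY`.
#' @param insert L x 20 matrix of insert emission probabilities; defaults to
#'   the background in every row.
#' @param transitions (L+1) x 7 matrix of transition probabilities; defaults
#'   to a sticky standard set (M->M 0.9) with a deterministic exit row.
#' @param background Length-20 null frequencies; defaults to
#'   [aa_background()].
#' @param metadata Free-form named list (format version, effective sequence
#'   number, annotation columns, ...).
#' @return Object of class `profile_hmm`.
#' @seealso [read_hmmer3()], [build_hmm()], [pair_forward()]
#' @export
#' @examples
#' h <- profile_hmm("toy", match = diag(20)[1:3, ])
#' h$L
profile_hmm <- function(name, match, insert = NULL, transitions = NULL,
                        background = aa_background(), metadata = list()) {
  match <- as.matrix(match)
  L <- nrow(match)
  if (is.null(insert)) {
    insert <- matrix(rep(background, each = L), nrow = L)
  }
  if (is.null(transitions)) {
    transitions <- matrix(rep(c(0.9, 0.05, 0.05, 0.8, 0.2, 0.7, 0.3),
                              each = L + 1), nrow = L + 1)
    transitions[L + 1, ] <- c(1, 0, 0, 1, 0, 1, 0)  # exit row
  }
  transitions <- as.matrix(transitions)
  colnames(transitions) <- TRANS_COLS
  colnames(match) <- AA
  colnames(insert) <- AA
  h <- structure(
    list(name = as.character(name), L = L, match = match, insert = insert,
         transitions = transitions,
         background = norm1(as.numeric(background)),
         metadata = metadata),
    class = "profile_hmm")
  validate_profile_hmm(h)
  h
}

#' Validate profile HMM invariants
#'
#' Checks that all probabilities lie in `[0, 1]`, that every emission row and
#' each defined transition group (`M->`, `I->`, `D->`) sums to one within
#' `tol`, and that the model has at least one match state.
#'
#' @param h A `profile_hmm`.
#' @param tol Tolerance on row sums (default `1e-6`).
#' @return `h`, invisibly; stops with an informative error on violation.
#' @export
validate_profile_hmm <- function(h, tol = 1e-6) {
  stopifnot(inherits(h, "profile_hmm"))
  if (h$L < 1) stop("profile HMM must have at least one match state")
  if (nrow(h$match) != h$L || ncol(h$match) != 20)
    stop("match emission matrix must be L x 20")
  if (nrow(h$insert) != h$L || ncol(h$insert) != 20)
    stop("insert emission matrix must be L x 20")
  if (nrow(h$transitions) != h$L + 1 || ncol(h$transitions) != 7)
    stop("transition matrix must be (L+1) x 7")
  all_p <- c(h$match, h$insert, h$transitions, h$background)
  if (any(all_p < -tol) || any(all_p > 1 + tol))
    stop("probabilities must lie in [0, 1]")
  chk_rows <- function(m, what) {
    bad <- which(abs(rowSums(m) - 1) > tol)
    if (length(bad))
      stop(sprintf("%s row(s) %s of model '%s' do not sum to 1",
                   what, paste(head(bad, 3), collapse = ","), h$name))
  }
  chk_rows(h$match, "match emission")
  chk_rows(h$insert, "insert emission")
  for (grp in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))) {
    s <- rowSums(h$transitions[, grp, drop = FALSE])
    bad <- which(abs(s - 1) > tol & s > tol)  # all-zero group = undefined
    if (length(bad))
      stop(sprintf("transition group (%s), row(s) %s of model '%s' do not sum to 1",
                   paste(grp, collapse = ","), paste(head(bad, 3), collapse = ","),
                   h$name))
  }
  if (abs(sum(h$background) - 1) > tol) stop("background must sum to 1")
  invisible(h)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM '%s': %d match states\n", x$name, x$L))
  if (!is.null(x$metadata$version))
    cat(sprintf("  format: HMMER%s\n", x$metadata$version))
  if (!is.null(x$metadata$neff))
    cat(sprintf("  effective sequences: %.3f\n", x$metadata$neff))
  invisible(x)
}

#' Position-reverse a profile HMM
#'
#' Returns the model read right to left: emission rows are reversed and
#' transition rows are mirrored (`rev[k] = orig[L - k]`), so the BEGIN row of
#' the reversal is the exit row of the original. This positional reversal is
#' an involution and is the reference model used by [reverse_score()]
#' normalization.
#'
#' @param h A `profile_hmm`.
#' @return A `profile_hmm` of the same length.
#' @export
reverse_hmm <- function(h) {
  stopifnot(inherits(h, "profile_hmm"))
  L <- h$L
  h2 <- h
  h2$name <- paste0(h$name, "_rev")
  h2$match <- h$match[L:1, , drop = FALSE]
  h2$insert <- h$insert[L:1, , drop = FALSE]
  h2$transitions <- h$transitions[(L + 1):1, , drop = FALSE]
  colnames(h2$transitions) <- TRANS_COLS
  h2
}
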