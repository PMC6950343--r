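# Profile HMM construction from single sequences or alignments.

#' Position-based (Henikoff) sequence weights
#'
#' For each column, each sequence carrying residue `a` receives `1/(r*s)`
#' where `r` is the number of distinct residues in the column and `s` the
#' number of sequences carrying `a`. Gaps and `X` contribute nothing.
#' Weights are normalized to sum to one, so total observed counts do not
#' grow with redundant copies of the same sequence.
#'
#' @param mat Character matrix of an alignment (rows = sequences).
#' @param cols Columns to use (default: all).
#' @return Numeric vector of weights, one per sequence, summing to 1.
#' @export
henikoff_weights <- function(mat, cols = seq_len(ncol(mat))) {
  n <- nrow(mat)
  w <- numeric(n)
  for (j in cols) {
    col <- mat[, j]
    keep <- col %in% AA
    if (!any(keep)) next
    tab <- table(col[keep])
    r <- length(tab)
    w[keep] <- w[keep] + 1 / (r * as.numeric(tab[col[keep]]))
  }
  if (sum(w) <= 0) w <- rep(1, n)
  w / sum(w)
}

# Conditional substitution probabilities P(a | b) derived from BLOSUM62
# (half-bit log-odds) and the standard background: q(a,b) ~ f(a) f(b)
# 2^(S(a,b)/2), P(a|b) = q(a,b) / sum_a q(a,b). Cached per session.
.prcx_cache <- new.env(parent = emptyenv())

#' BLOSUM62-derived conditional substitution matrix
#'
#' @param background Length-20 background frequencies.
#' @return 20 x 20 matrix with `P[a, b] = P(a | b)`; columns sum to one.
#' @export
blosum_conditional <- function(background = aa_background()) {
  key <- paste0("blosum_", digest_key(background))
  if (!is.null(.prcx_cache[[key]])) return(.prcx_cache[[key]])
  B <- get_blosum62()[AA, AA]
  q <- outer(background, background) * 2^(B / 2)
  q <- q / sum(q)
  P <- sweep(q, 2, colSums(q), "/")
  dimnames(P) <- list(AA, AA)
  .prcx_cache[[key]] <- P
  P
}

digest_key <- function(x) paste(signif(x, 8), collapse = ",")

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Substitution-matrix pseudocount profiles
#'
#' Classic substitution pseudocounts: each observed frequency row is pushed
#' through the conditional substitution matrix, `g(a) = sum_b f_obs(b) P(a|b)`.
#'
#' @param fobs L x 20 matrix of observed residue frequencies (rows sum to 1).
#' @param background Background frequencies used to derive the conditional
#'   matrix.
#' @return L x 20 matrix of pseudocount distributions.
#' @export
substitution_pseudocounts <- function(fobs, background = aa_background()) {
  P <- blosum_conditional(background)
  g <- fobs %*% t(P)
  g / rowSums(g)
}

#' Sequence context-specific pseudocounts
#'
#' For every column, the posterior responsibility of each context profile
#' given the surrounding window of weighted counts is computed (multinomial
#' log-likelihood of the window counts under the context's window profile,
#' plus the context's log prior), and the pseudocount vector is the
#' responsibility-weighted mixture of the contexts' central columns. The
#' returned row is the admixture `(1 - admix) * f_obs + admix * pseudocount`.
#' Alignment edges are padded with background-frequency columns of unit
#' weight.
#'
#' @param counts L x 20 matrix of weighted observed residue counts.
#' @param library A [context_library()].
#' @param admix Pseudocount admixture fraction in `[0, 1]`.
#' @param background Background frequencies for edge padding and empty rows.
#' @return L x 20 matrix of probability rows.
#' @export
context_pseudocounts <- function(counts, library, admix,
                                 background = aa_background()) {
  stopifnot(inherits(library, "context_library"))
  if (!is.numeric(admix) || length(admix) != 1 || is.na(admix) ||
      admix < 0 || admix > 1)
    stop("admix must be a single number in [0, 1]")
  counts <- as.matrix(counts)
  L <- nrow(counts)
  fobs <- t(apply(counts, 1, norm1, default = background))
  if (admix == 0) return(fobs)
  w <- library$w
  h <- (w - 1) / 2
  padded <- rbind(matrix(rep(background, each = h), nrow = h, ncol = 20),
                  counts,
                  matrix(rep(background, each = h), nrow = h, ncol = 20))
  K <- library$K
  logprior <- log(library$priors)
  # Precompute log window profiles with 0*log(0) := 0 handled at use site.
  logp <- lapply(library$profiles, log)
  pc <- matrix(0, L, 20)
  for (i in seq_len(L)) {
    win <- padded[i:(i + w - 1), , drop = FALSE]
    ll <- vapply(seq_len(K), function(k) {
      lp <- logp[[k]]
      v <- win * lp
      v[win == 0] <- 0  # no observation, no contribution
      sum(v) + logprior[k]
    }, numeric(1))
    m <- max(ll)
    resp <- if (is.finite(m)) {
      e <- exp(ll - m)
      e / sum(e)
    } else {
      library$priors  # no context explains the window; fall back to prior
    }
    centrals <- vapply(library$profiles, function(p) p[h + 1, ], numeric(20))
    pc[i, ] <- as.numeric(centrals %*% resp)
  }
  out <- (1 - admix) * fobs + admix * pc
  out / rowSums(out)
}

#' Build a profile HMM from a sequence or alignment
#'
#' Columns with gap fraction below 0.5 become match states. Observed counts
#' are weighted by position-based Henikoff weights and mixed with
#' pseudocounts by the admixture `tau = min(1, c / N_eff)`, where `N_eff` is
#' the effective sequence number (exponential of the mean match-column
#' entropy by default, or the number of unique rows). Transition
#' probabilities are estimated from weighted gap/insert events with Laplace
#' smoothing. Insert emissions are set to the background.
#'
#' @param m A [msa()] (a single sequence is a one-row alignment).
#' @param pseudocount_mode One of `"substitution"` (default), `"none"`,
#'   `"context"`.
#' @param context_library Required for `pseudocount_mode = "context"`.
#' @param name Model name (default: first sequence name).
#' @param background Null frequencies attached to the model.
#' @param params List of tuning parameters: `pc_admix_c` (numerator of the
#'   tau rule, default 0.9), `tau` (explicit admixture overriding the rule),
#'   `laplace` (transition smoothing count, default 0.1), `neff_method`
#'   (`"entropy"` or `"unique"`), `match_threshold` (gap fraction below which
#'   a column is a match state, default 0.5).
#' @return A [profile_hmm()].
#' @export
#' @examples
#' h <- build_hmm(msa("ACD"), pseudocount_mode = "none")
#' h$match[1, "A"]  # 1: point mass, no counts to smooth
build_hmm <- function(m, pseudocount_mode = c("substitution", "none", "context"),
                      context_library = NULL, name = NULL,
                      background = aa_background(), params = list()) {
  stopifnot(inherits(m, "prcx_msa"))
  pseudocount_mode <- match.arg(pseudocount_mode)
  if (pseudocount_mode == "context" && is.null(context_library))
    stop("context pseudocounts require a context_library")
  p <- list(pc_admix_c = 0.9, tau = NULL, laplace = 0.1,
            neff_method = "entropy", match_threshold = 0.5)
  p[names(params)] <- params
  mat <- m$mat
  n <- nrow(mat)
  match_cols <- which(gap_fraction(m) < p$match_threshold)
  L <- length(match_cols)
  if (L == 0) stop("no match columns: alignment is all (or mostly) gaps")
  w <- henikoff_weights(mat, cols = match_cols)

  # Weighted residue counts per match column.
  counts <- matrix(0, L, 20, dimnames = list(NULL, AA))
  for (k in seq_len(L)) {
    col <- mat[, match_cols[k]]
    keep <- col %in% AA
    if (any(keep))
      counts[k, ] <- vapply(AA, function(a) sum(w[keep][col[keep] == a]),
                            numeric(1))
  }
  fobs <- t(apply(counts, 1, norm1, default = background))

  neff <- switch(p$neff_method,
    entropy = {
      hcol <- apply(fobs, 1, function(f) {
        f <- f[f > 0]; -sum(f * log(f))
      })
      exp(mean(hcol))
    },
    unique = length(unique(m$seqs)),
    stop("unknown neff_method: ", p$neff_method))
  tau <- p$tau %||% min(1, p$pc_admix_c / neff)

  emis <- switch(pseudocount_mode,
    none = fobs,
    substitution = {
      g <- substitution_pseudocounts(fobs, background)
      out <- (1 - tau) * fobs + tau * g
      out / rowSums(out)
    },
    context = context_pseudocounts(counts, context_library, admix = tau,
                                   background = background))

  transitions <- estimate_transitions(mat, match_cols, w, alpha = p$laplace)
  profile_hmm(name = name %||% m$names[1], match = emis,
              transitions = transitions, background = background,
              metadata = list(neff = neff, tau = tau,
                              pseudocount_mode = pseudocount_mode,
                              match_cols = match_cols))
}

# Weighted transition counts along each sequence's implied state path
# (match column with residue = M, with gap = D; residues in non-match
# columns between two match columns = inserts), Laplace-smoothed with alpha
# per outcome. Plan-7 has no I->D edge: inserts preceding a deletion are
# folded into a direct ->D step.
estimate_transitions <- function(mat, match_cols, w, alpha = 0.1) {
  L <- length(match_cols)
  n <- nrow(mat)
  cnt <- matrix(0, L + 1, 7, dimnames = list(NULL, TRANS_COLS))
  bounds <- c(0, match_cols, ncol(mat) + 1)
  all_cols <- seq_len(ncol(mat))
  for (s in seq_len(n)) {
    row <- mat[s, ]
    st <- ifelse(row[match_cols] == "-", "D", "M")
    states <- c("M", st, "M")  # BEGIN and END behave as match states
    for (k in seq_len(L + 1)) {
      gap_cols <- all_cols[all_cols > bounds[k] & all_cols < bounds[k + 1]]
      nins <- if (length(gap_cols)) sum(row[gap_cols] != "-") else 0
      from <- states[k]
      to <- states[k + 1]
      if (nins > 0 && to == "M" && from == "M") {
        cnt[k, "MI"] <- cnt[k, "MI"] + w[s]
        if (nins > 1) cnt[k, "II"] <- cnt[k, "II"] + w[s] * (nins - 1)
        cnt[k, "IM"] <- cnt[k, "IM"] + w[s]
      } else {
        # Plan-7 has no D->I or I->D edge: inserts flanking a deletion are
        # folded into the direct step.
        cnt[k, paste0(from, to)] <- cnt[k, paste0(from, to)] + w[s]
      }
    }
  }
  tr <- matrix(0, L + 1, 7, dimnames = list(NULL, TRANS_COLS))
  groups <- list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))
  for (k in seq_len(L + 1)) {
    for (g in groups) {
      cts <- cnt[k, g] + alpha
      if (k == L + 1) {  # exit row: no transitions into a further node
        if ("MD" %in% g) cts["MD"] <- 0
        if ("DD" %in% g) cts["DD"] <- 0
      }
      tr[k, g] <- cts / sum(cts)
    }
  }
  tr
}
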