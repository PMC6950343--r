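# Distance matrices and UPGMA trees from all-vs-all co-emission scores.

#' All-vs-all co-emission scores for a profile HMM library
#'
#' Computes the symmetric matrix of simple (local forward, by default)
#' co-emission scores. With a prefilter configured, pairs whose
#' Smith-Waterman letter-alignment score fails the acceptance rule are
#' skipped and marked `NA`; the diagonal always holds self scores.
#'
#' @param models List of `profile_hmm`s with unique names.
#' @param prefilter `NULL` (score every pair) or a list with elements
#'   `mode` (`"threshold"` or `"topN"`), `value`, and optionally `alphabet`
#'   (a [column_alphabet()]; defaults to [default_alphabet()]), `gap_open`,
#'   `gap_extend`.
#' @param score `"forward"` (default) or `"viterbi"`.
#' @param mode `"local"` (default) or `"global"`.
#' @param background Optional shared null model for all comparisons.
#' @return Symmetric numeric matrix of scores in bits (dimnames = model
#'   names), `NA` marking prefiltered-out pairs.
#' @export
all_vs_all <- function(models, prefilter = NULL,
                       score = c("forward", "viterbi"),
                       mode = c("local", "global"), background = NULL) {
  score <- match.arg(score)
  mode <- match.arg(mode)
  n <- length(models)
  if (n < 2) stop("a library of at least 2 models is required")
  nm <- vapply(models, function(h) h$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate model names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  keep <- matrix(TRUE, n, n)
  if (!is.null(prefilter) && !identical(prefilter$mode, "off")) {
    alphabet <- prefilter$alphabet %||% default_alphabet()
    seqs <- lapply(models, discretize, alphabet = alphabet)
    pf <- prefilter_pairs(seqs, mode = prefilter$mode, value = prefilter$value,
                          alphabet = alphabet,
                          gap_open = prefilter$gap_open %||% 6,
                          gap_extend = prefilter$gap_extend %||% 1)
    keep[] <- FALSE
    ii <- match(pf$query, nm); jj <- match(pf$target, nm)
    keep[cbind(ii, jj)[pf$keep, , drop = FALSE]] <- TRUE
    keep[cbind(jj, ii)[pf$keep, , drop = FALSE]] <- TRUE
  }
  scorer <- function(a, b) {
    if (score == "forward")
      pair_forward(models[[a]], models[[b]], mode, background = background)$forward_bits
    else
      pair_viterbi(models[[a]], models[[b]], mode, background = background,
                   want_trace = FALSE)$viterbi_bits
  }
  M <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    M[i, i] <- scorer(i, i)
    for (j in seq_len(n)) {
      if (j <= i) next
      if (keep[i, j]) M[i, j] <- M[j, i] <- scorer(i, j)
    }
  }
  M
}

#' Convert co-emission scores to a distance matrix
#'
#' Default self-score-normalized transform:
#' `d(i, j) = 1 - max(0, s(i, j)) / max(s(i, i), s(j, j))`, clipped to
#' `[0, 1]`, with a zero diagonal. Pairs skipped by the prefilter (`NA`
#' scores) are imputed with the maximum observed distance — missingness
#' signals non-homology, and UPGMA needs a complete matrix. The transform
#' is pluggable via `transform`.
#'
#' @param scores Symmetric score matrix (e.g. from [all_vs_all()]).
#' @param self_scores Optional vector of self scores; defaults to
#'   `diag(scores)`. Must be positive.
#' @param transform Optional function `(s, si, sj) -> d` replacing the
#'   default formula.
#' @return Symmetric distance matrix with zero diagonal, entries in
#'   `[0, 1]` (class `matrix`).
#' @export
score_to_distance <- function(scores, self_scores = NULL, transform = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  self_scores <- self_scores %||% diag(scores)
  bad <- which(!is.finite(self_scores) | self_scores <= 0)
  if (length(bad))
    stop("non-positive self score for model(s): ",
         paste(rownames(scores)[bad] %||% bad, collapse = ", "))
  f <- transform %||% function(s, si, sj) {
    min(1, max(0, 1 - max(0, s) / max(si, sj)))
  }
  d <- matrix(0, n, n, dimnames = dimnames(scores))
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      if (i == j) next
      s <- scores[i, j]
      d[i, j] <- if (is.na(s)) NA_real_
                 else f(s, self_scores[i], self_scores[j])
    }
  if (anyNA(d)) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- mx
  }
  d <- (d + t(d)) / 2  # guard against asymmetric user transforms
  validate_distance_matrix(d)
  d
}

#' Validate distance-matrix invariants
#'
#' @param d Numeric matrix: symmetric, zero diagonal, finite, non-negative.
#' @param tol Symmetry tolerance.
#' @return `d`, invisibly.
#' @export
validate_distance_matrix <- function(d, tol = 1e-8) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(!is.finite(d))) stop("distances must be finite")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(d - t(d)) > tol)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > tol)) stop("distance matrix must have a zero diagonal")
  invisible(d)
}

# --- UPGMA ----------------------------------------------------------------

# Deterministic pair ordering: smaller distance first, ties by the
# lexicographically smallest (cluster index, cluster index) where a
# cluster's index is the smallest original leaf index it contains.
.pair_better <- function(d1, i1, j1, d2, i2, j2) {
  if (d1 != d2) return(d1 < d2)
  a1 <- min(i1, j1); b1 <- max(i1, j1)
  a2 <- min(i2, j2); b2 <- max(i2, j2)
  if (a1 != a2) return(a1 < a2)
  b1 < b2
}

.upgma_result <- function(labels, merge_a, merge_b, heights, members) {
  structure(list(labels = labels,
                 merges = data.frame(a = merge_a, b = merge_b,
                                     height = heights),
                 members = members),
            class = "upgma_tree")
}

#' UPGMA tree from a distance matrix (O(n^2) agglomeration)
#'
#' Average-linkage agglomeration: the cluster pair at minimal distance is
#' merged, the new node placed at height d/2, and distances to the merged
#' cluster updated as the size-weighted mean of the member distances.
#' Per-cluster nearest-neighbour candidates are maintained so that the whole
#' agglomeration takes O(n^2) work in the typical case (the MUSCLE / Clustal
#' Omega strategy), instead of rescanning the full matrix each round. Ties
#' are broken deterministically by the lexicographically smallest pair of
#' original leaf indices, so results are exactly reproducible and comparable
#' with the naive reference [upgma_naive()].
#'
#' In the merge table, negative entries `-k` refer to leaf `k` and positive
#' entries to earlier merge rows (the `hclust` convention).
#'
#' @param d Symmetric distance matrix with labels as dimnames, `n >= 2`.
#' @return Object of class `upgma_tree`: `labels`, `merges` (columns `a`,
#'   `b`, `height`), and per-merge leaf membership.
#' @seealso [upgma_naive()], [write_newick()], [as.phylo.upgma_tree()]
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("UPGMA needs at least 2 items")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  cl_id <- -(seq_len(n))        # hclust-style id of the cluster in each slot
  cl_min <- seq_len(n)          # smallest original leaf index per slot
  members <- as.list(seq_len(n))
  nn <- integer(n)              # per-slot nearest-neighbour candidate
  scan_nn <- function(i) {
    best <- 0L
    for (j in seq_len(n)) {
      if (!active[j] || j == i) next
      if (best == 0L ||
          .pair_better(d[i, j], cl_min[i], cl_min[j],
                       d[i, best], cl_min[i], cl_min[best]))
        best <- j
    }
    best
  }
  for (i in seq_len(n)) nn[i] <- scan_nn(i)
  merge_a <- integer(n - 1); merge_b <- integer(n - 1)
  heights <- numeric(n - 1)
  merge_members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    # global best = best among per-slot candidates
    bi <- 0L
    for (i in seq_len(n)) {
      if (!active[i] || nn[i] == 0L) next
      j <- nn[i]
      if (bi == 0L ||
          .pair_better(d[i, j], cl_min[i], cl_min[j],
                       d[bi, nn[bi]], cl_min[bi], cl_min[nn[bi]]))
        bi <- i
    }
    i <- min(bi, nn[bi]); j <- max(bi, nn[bi])
    if (cl_min[j] < cl_min[i]) { tmp <- i; i <- j; j <- tmp }
    # merge slot j into slot i (i keeps the smaller original index)
    h <- d[i, j] / 2
    merge_a[step] <- cl_id[i]; merge_b[step] <- cl_id[j]
    heights[step] <- h
    members[[i]] <- c(members[[i]], members[[j]])
    merge_members[[step]] <- members[[i]]
    ni <- size[i]; nj <- size[j]
    for (k in seq_len(n)) {
      if (!active[k] || k == i || k == j) next
      d[i, k] <- d[k, i] <- (ni * d[i, k] + nj * d[j, k]) / (ni + nj)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    cl_id[i] <- step
    cl_min[i] <- min(cl_min[i], cl_min[j])
    if (step == n - 1) break
    nn[i] <- scan_nn(i)
    for (k in seq_len(n)) {
      if (!active[k] || k == i) next
      if (nn[k] == i || nn[k] == j) {
        nn[k] <- scan_nn(k)        # candidate invalidated: rescan row
      } else if (.pair_better(d[k, i], cl_min[k], cl_min[i],
                              d[k, nn[k]], cl_min[k], cl_min[nn[k]])) {
        nn[k] <- i                 # merged cluster became the candidate
      }
    }
  }
  .upgma_result(labels, merge_a, merge_b, heights, merge_members)
}

#' Naive O(n^3) UPGMA reference implementation
#'
#' Full-matrix rescan at every merge under the identical deterministic tie
#' rule — the independent reference against which the accelerated [upgma()]
#' is validated (both must produce identical topologies and node heights).
#'
#' @inheritParams upgma
#' @return An `upgma_tree`.
#' @export
upgma_naive <- function(d) {
  d <- as.matrix(d)
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("UPGMA needs at least 2 items")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  cl_id <- -(seq_len(n))
  cl_min <- seq_len(n)
  members <- as.list(seq_len(n))
  merge_a <- integer(n - 1); merge_b <- integer(n - 1)
  heights <- numeric(n - 1)
  merge_members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    bi <- 0L; bj <- 0L
    for (i in seq_len(n)) {
      if (!active[i]) next
      for (j in seq_len(n)) {
        if (!active[j] || j <= i) next
        if (bi == 0L ||
            .pair_better(d[i, j], cl_min[i], cl_min[j],
                         d[bi, bj], cl_min[bi], cl_min[bj])) {
          bi <- i; bj <- j
        }
      }
    }
    i <- bi; j <- bj
    if (cl_min[j] < cl_min[i]) { tmp <- i; i <- j; j <- tmp }
    merge_a[step] <- cl_id[i]; merge_b[step] <- cl_id[j]
    heights[step] <- d[i, j] / 2
    members[[i]] <- c(members[[i]], members[[j]])
    merge_members[[step]] <- members[[i]]
    ni <- size[i]; nj <- size[j]
    for (k in seq_len(n)) {
      if (!active[k] || k == i || k == j) next
      d[i, k] <- d[k, i] <- (ni * d[i, k] + nj * d[j, k]) / (ni + nj)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    cl_id[i] <- step
    cl_min[i] <- min(cl_min[i], cl_min[j])
  }
  .upgma_result(labels, merge_a, merge_b, heights, merge_members)
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %.6g\n",
              length(x$labels), max(x$merges$height)))
  invisible(x)
}

#' Node heights of a UPGMA tree
#' @param t An `upgma_tree`.
#' @return Numeric vector of merge heights in merge order.
#' @export
tree_heights <- function(t) t$merges$height

# Serialize subtree rooted at merge row r (or leaf -k) relative to a parent
# height. Branch lengths at 6 significant digits; labels quoted if they
# contain Newick metacharacters.
.newick_node <- function(x, id, parent_height, digits) {
  fmt <- function(b) {
    b <- max(b, 0)
    if (b == 0) return("0")
    dec <- max(0, digits - 1 - floor(log10(b)))  # plain decimal, no sci notation
    s <- sprintf("%.*f", min(dec, 30), b)
    if (grepl("\\.", s)) s <- sub("\\.?0+$", "", s)
    s
  }
  if (id < 0) {
    lab <- x$labels[-id]
    if (grepl("[(),:;'\\s\\[\\]]", lab, perl = TRUE))
      lab <- paste0("'", gsub("'", "''", lab), "'")
    return(paste0(lab, ":", fmt(parent_height)))
  }
  h <- x$merges$height[id]
  paste0("(", .newick_node(x, x$merges$a[id], h, digits), ",",
         .newick_node(x, x$merges$b[id], h, digits), "):",
         fmt(parent_height - h))
}

#' Serialize a UPGMA tree as Newick
#'
#' Branch length = parent height minus child height, written at 6
#' significant digits; labels containing Newick-special characters are
#' single-quoted; the string is terminated by a semicolon.
#'
#' @param t An `upgma_tree` (or an `ape::phylo`, passed through
#'   [ape::write.tree()]).
#' @param path Output file, or `NULL` to return the string only.
#' @param digits Significant digits for branch lengths.
#' @return Newick string, invisibly if written to a file.
#' @export
write_newick <- function(t, path = NULL, digits = 6) {
  if (inherits(t, "phylo")) {
    s <- ape::write.tree(t)
  } else {
    stopifnot(inherits(t, "upgma_tree"))
    root <- nrow(t$merges)
    h <- t$merges$height[root]
    s <- paste0("(",
                .newick_node(t, t$merges$a[root], h, digits), ",",
                .newick_node(t, t$merges$b[root], h, digits), ");")
  }
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Convert a UPGMA tree to an ape phylo object
#'
#' @param x An `upgma_tree`.
#' @param ... Unused.
#' @return An `ape::phylo` (rooted, ultrametric).
#' @importFrom ape as.phylo
#' @method as.phylo upgma_tree
#' @export
as.phylo.upgma_tree <- function(x, ...) {
  ape::read.tree(text = write_newick(x, digits = 15))
}

# --- PHYLIP ---------------------------------------------------------------

#' Write a distance matrix in square PHYLIP format
#'
#' First line the number of taxa, then one row per taxon. The relaxed
#' dialect (default) writes full-length whitespace-delimited labels; the
#' strict dialect pads/truncates labels to 10 characters, disambiguating
#' truncation collisions with numeric suffixes. Labels containing
#' whitespace are sanitized with underscores (with a warning).
#'
#' @param d Labelled symmetric distance matrix.
#' @param path Output file.
#' @param strict Use the strict 10-character label dialect.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path, strict = FALSE) {
  d <- as.matrix(d)
  validate_distance_matrix(d)
  labs <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  if (any(grepl("\\s", labs))) {
    warning("labels containing whitespace sanitized with underscores")
    labs <- gsub("\\s+", "_", labs)
  }
  if (strict) {
    labs <- substr(labs, 1, 10)
    while (anyDuplicated(labs)) {
      dup <- which(duplicated(labs) | duplicated(labs, fromLast = TRUE))
      for (k in seq_along(dup))
        labs[dup[k]] <- sprintf("%s%d", substr(labs[dup[k]], 1,
                                               10 - nchar(as.character(k))), k)
    }
    labs <- sprintf("%-10s", labs)
  } else {
    labs <- sprintf("%-12s", labs)
  }
  rows <- vapply(seq_len(nrow(d)), function(i)
    paste0(labs[i], " ", paste(sprintf("%.6f", d[i, ]), collapse = "  ")),
    character(1))
  writeLines(c(sprintf("%5d", nrow(d)), rows), path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' Accepts the relaxed whitespace-delimited dialect written by
#' [write_phylip()] (strict 10-character files parse too since labels
#' contain no internal whitespace).
#'
#' @param path File path.
#' @return Labelled symmetric distance matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 1) stop("malformed PHYLIP header")
  if (length(lines) < n + 1) stop("PHYLIP file truncated")
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    labs[i] <- toks[1]
    vals <- as.numeric(toks[-1])
    if (length(vals) != n) stop("row ", i, " has ", length(vals),
                                " values, expected ", n)
    d[i, ] <- vals
  }
  dimnames(d) <- list(labs, labs)
  d
}
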