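# Independent brute-force oracles and fixture builders shared by the tests.
# These deliberately re-derive results by the most naive route available and
# stay independent of the package's fast implementations.

AA_letters <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# log2(sum(2^x)) of a path-weight vector (test-local copy).
oracle_lse2 <- function(x) {
  m <- max(x)
  m + log2(sum(2^(x - m)))
}

# Brute-force affine-gap local alignment score: enumerate every monotone
# move path (match / gap-in-1 / gap-in-2) from every start cell, recording
# the running score after each move. A gap of length g costs
# gap_open + g * gap_extend, charged open+extend on the first gap character.
brute_sw <- function(s1, s2, subst, gap_open, gap_extend) {
  n <- length(s1); m <- length(s2)
  best <- 0
  rec <- function(i, j, sc, last) {
    if (sc > best) best <<- sc
    if (i < n && j < m)
      rec(i + 1, j + 1, sc + subst[s1[i + 1], s2[j + 1]], "M")
    if (j < m)
      rec(i, j + 1, sc - gap_extend - if (last == "I") 0 else gap_open, "I")
    if (i < n)
      rec(i + 1, j, sc - gap_extend - if (last == "D") 0 else gap_open, "D")
  }
  for (i0 in 0:(n - 1))
    for (j0 in 0:(m - 1))
      if (i0 < n && j0 < m)
        rec(i0 + 1, j0 + 1, subst[s1[i0 + 1], s2[j0 + 1]], "M")
  best
}

# Exhaustive 2-means in sqrt coordinates: tries every 2-partition and
# returns the cluster mean profiles (of the original probability rows,
# renormalized) of the partition minimizing within-cluster squared error.
brute_kmeans2 <- function(columns) {
  n <- nrow(columns)
  X <- sqrt(columns)
  best_ss <- Inf
  best_centroids <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {   # fix point 1 in cluster A to halve work
    inA <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2)))))
    if (!any(inA) || all(inA)) next
    ss <- 0
    for (grp in list(which(inA), which(!inA))) {
      cen <- colMeans(X[grp, , drop = FALSE])
      ss <- ss + sum(sweep(X[grp, , drop = FALSE], 2, cen)^2)
    }
    if (ss < best_ss) {
      best_ss <- ss
      best_centroids <- lapply(list(which(inA), which(!inA)), function(grp) {
        p <- colMeans(columns[grp, , drop = FALSE])
        p / sum(p)
      })
    }
  }
  best_centroids
}

# Direct Bayes posterior over context profiles for a single column window,
# written out longhand: multinomial log-likelihood of the padded window
# counts plus log prior, exponentiated and normalized.
brute_context_posterior <- function(counts, library, column, background) {
  w <- library$w
  h <- (w - 1) / 2
  pad <- matrix(rep(background, each = h), nrow = h, ncol = 20)
  padded <- rbind(pad, counts, pad)
  win <- padded[column:(column + w - 1), , drop = FALSE]
  ll <- numeric(library$K)
  for (k in seq_len(library$K)) {
    p <- library$profiles[[k]]
    tot <- log(library$priors[k])
    for (d in seq_len(w))
      for (a in 1:20)
        if (win[d, a] > 0) tot <- tot + win[d, a] * log(p[d, a])
    ll[k] <- tot
  }
  e <- exp(ll - max(ll))
  e / sum(e)
}

# Small deterministic library of toy models reused across test files.
toy_pair <- function(L = 3, seed = 1) {
  hs <- make_toy_hmms(2, L, seed = seed)
  list(h1 = hs[[1]], h2 = hs[[2]])
}

# Random symmetric distance matrix with zero diagonal; integer-valued
# every third draw to force ties.
random_distance_matrix <- function(n, tie_prone = FALSE) {
  d <- matrix(0, n, n)
  v <- if (tie_prone) sample(1:4, n * (n - 1) / 2, replace = TRUE)
       else runif(n * (n - 1) / 2)
  d[upper.tri(d)] <- v
  d <- d + t(d)
  dimnames(d) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  d
}

# Tree leaves are per-sequence singletons or clusterNNN HMMs; map each leaf
# back to the generating family of its member sequences (NA if a cluster
# mixed families, which counts as a recovery failure).
leaf_family_map <- function(clusters, truth, leaves) {
  vapply(leaves, function(leaf) {
    members <- if (leaf %in% clusters$name) leaf else {
      cid <- as.integer(sub("^cluster", "", leaf))
      clusters$name[clusters$cluster == cid]
    }
    fams <- unique(truth$family[match(members, truth$name)])
    if (length(fams) == 1) fams else NA_character_
  }, character(1))
}

# TRUE when every family's leaves form a clade (and no leaf mixes families).
families_monophyletic <- function(ph, clusters, truth) {
  fam <- leaf_family_map(clusters, truth, ph$tip.label)
  if (anyNA(fam)) return(FALSE)
  all(vapply(unique(fam), function(f)
    ape::is.monophyletic(ph, ph$tip.label[fam == f]), logical(1)))
}

# Max root-to-leaf path-length spread of an upgma_tree, via ape.
ultrametric_spread <- function(tree) {
  ph <- ape::as.phylo(tree)
  depth <- ape::node.depth.edgelength(ph)
  diff(range(depth[seq_along(ph$tip.label)]))
}
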