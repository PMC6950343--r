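# Synthetic protein families with a known generating phylogeny, for
# end-to-end validation without any external data.

#' Specification for a simulated family set
#'
#' @param guide_tree Newick string with branch lengths; each leaf is a
#'   family. Per-branch substitution probability per site is
#'   `1 - exp(-branch_length)` (uniform replacement among the other 19
#'   residues).
#' @param root_length Root sequence length (>= 10).
#' @param seqs_per_leaf Sequences emitted per family.
#' @param indel_rate Expected indel events per site per unit branch length.
#' @param tip_branch Extra branch length applied independently to each
#'   emitted sequence below its family's leaf (within-family divergence).
#' @param seed Integer seed.
#' @return A validated list of class `family_spec`.
#' @export
family_spec <- function(guide_tree = "((famA:0.5,famB:0.5):0.3,(famC:0.5,famD:0.5):0.3);",
                        root_length = 80, seqs_per_leaf = 4,
                        indel_rate = 0.01, tip_branch = 0.25, seed = 1) {
  if (root_length < 10) stop("root_length must be >= 10")
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must lie in [0, 1)")
  tree <- ape::read.tree(text = guide_tree)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("guide tree must carry non-negative branch lengths")
  structure(list(guide_tree = guide_tree, tree = tree,
                 root_length = root_length, seqs_per_leaf = seqs_per_leaf,
                 indel_rate = indel_rate, tip_branch = tip_branch,
                 seed = as.integer(seed)),
            class = "family_spec")
}

.mutate_seq <- function(chars, branch_length, indel_rate) {
  p_sub <- 1 - exp(-branch_length)
  L <- length(chars)
  hit <- which(rbinom(L, 1, p_sub) == 1)
  for (i in hit) chars[i] <- sample(setdiff(AA, chars[i]), 1)
  n_events <- rpois(1, indel_rate * branch_length * L)
  for (e in seq_len(n_events)) {
    len <- 1 + stats::rgeom(1, 0.5)
    if (runif(1) < 0.5 && length(chars) > len + 10) {   # deletion
      pos <- sample(length(chars) - len + 1, 1)
      chars <- chars[-(pos:(pos + len - 1))]
    } else {                                            # insertion
      pos <- sample(length(chars) + 1, 1)
      ins <- sample(AA, len, replace = TRUE, prob = aa_background())
      chars <- append(chars, ins, after = pos - 1)
    }
  }
  chars
}

#' Simulate protein families down a guide tree
#'
#' The root sequence is drawn from the background composition and evolved
#' down the guide tree by i.i.d. per-site substitution (probability
#' `1 - exp(-branch_length)`, uniform replacement among the other 19
#' residues) and Poisson indel events of geometric length. Each leaf then
#' emits `seqs_per_leaf` sequences, each independently evolved an extra
#' `tip_branch` below the leaf. Deterministic under the spec's seed.
#'
#' @param spec A [family_spec()].
#' @return List with `sequences` (named character vector) and `truth`
#'   (tibble: `name`, `family`).
#' @export
simulate_families <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  tree <- spec$tree
  ntip <- length(tree$tip.label)
  if (ntip < 2)
    warning("degenerate guide tree with a single leaf: one family emitted")
  root_chars <- sample(AA, spec$root_length, replace = TRUE,
                       prob = aa_background())
  nnode <- ntip + tree$Nnode
  seq_at <- vector("list", nnode)
  root <- ntip + 1
  seq_at[[root]] <- root_chars
  # edges in preorder so a parent is always materialized before its children
  tr_pre <- ape::reorder.phylo(tree, "cladewise")
  edges <- tr_pre$edge
  lens <- tr_pre$edge.length
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    seq_at[[child]] <- .mutate_seq(seq_at[[parent]], lens[k], spec$indel_rate)
  }
  seqs <- character(0)
  fam <- character(0)
  for (t in seq_len(ntip)) {
    for (r in seq_len(spec$seqs_per_leaf)) {
      chars <- .mutate_seq(seq_at[[t]], spec$tip_branch, spec$indel_rate)
      nm <- sprintf("%s_s%02d", tree$tip.label[t], r)
      seqs[nm] <- paste(chars, collapse = "")
      fam <- c(fam, tree$tip.label[t])
    }
  }
  list(sequences = seqs,
       truth = tibble::tibble(name = names(seqs), family = fam))
}

#' Write a simulated family set to disk
#'
#' FASTA sequences plus a tab-separated truth table with header
#' `name<TAB>family` mapping each sequence to its generating family.
#'
#' @param sim Result of [simulate_families()].
#' @param fasta_path,truth_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_family_set <- function(sim, fasta_path, truth_path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$sequences),
                              fasta_path)
  writeLines(c("name\tfamily",
               sprintf("%s\t%s", sim$truth$name, sim$truth$family)),
             truth_path)
  invisible(fasta_path)
}

#' Random valid profile HMMs for testing
#'
#' Dirichlet-sampled match emissions (sharpness alpha = 0.3, giving
#' realistic peaked columns), background inserts, and sticky randomized
#' transitions. Deterministic under the seed; every output satisfies the
#' profile HMM invariants.
#'
#' @param n Number of models.
#' @param L Match states per model.
#' @param seed Integer seed.
#' @param alpha Dirichlet concentration for match emissions.
#' @return List of [profile_hmm()]s named `toy01..`.
#' @export
make_toy_hmms <- function(n, L, seed = 1, alpha = 0.3) {
  stopifnot(n >= 1, L >= 1)
  set.seed(seed)
  rdirichlet_row <- function(a) {
    g <- rgamma(20, shape = a)
    if (sum(g) <= 0) g[sample(20, 1)] <- 1
    g / sum(g)
  }
  lapply(seq_len(n), function(i) {
    match <- t(vapply(seq_len(L), function(k) rdirichlet_row(alpha),
                      numeric(20)))
    tr <- matrix(0, L + 1, 7)
    for (k in seq_len(L + 1)) {
      m3 <- rgamma(3, shape = c(20, 1, 1)); m3 <- m3 / sum(m3)
      i2 <- rgamma(2, shape = c(4, 1)); i2 <- i2 / sum(i2)
      d2 <- rgamma(2, shape = c(4, 1)); d2 <- d2 / sum(d2)
      tr[k, ] <- c(m3, i2, d2)
    }
    tr[L + 1, ] <- c(tr[L + 1, 1] + tr[L + 1, 3], tr[L + 1, 2], 0,
                     tr[L + 1, 4], tr[L + 1, 5],
                     1, 0)  # exit row: no further delete
    profile_hmm(sprintf("toy%02d", i), match = match, transitions = tr)
  })
}
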