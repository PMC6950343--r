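# End-to-end workflow: cluster -> align -> build pHMMs -> all-vs-all ->
# distance matrix -> UPGMA tree, plus classification of new sequences.

#' Global percent identity of two sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) via Biostrings;
#' identity = matches / alignment length (gap columns included).
#'
#' @param a,b Amino-acid sequences (character).
#' @return Identity fraction in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Greedy single-linkage-free clustering at an identity threshold
#'
#' Sequences are processed in decreasing length (ties by name); each joins
#' the first existing cluster whose representative it matches at or above
#' the identity threshold, otherwise it founds a new cluster. This is the
#' built-in redundancy/clustering fallback of the pipeline (heavyweight
#' external clusterers can be run upstream instead and their clusters fed
#' in as FASTA files).
#'
#' @param seqs Named character vector (or `AAStringSet`) of sequences.
#' @param identity Threshold in `(0, 1]` (default 0.70).
#' @return Tibble with columns `name`, `cluster` (integer id),
#'   `representative` (logical), `identity_to_rep`.
#' @export
greedy_cluster <- function(seqs, identity = 0.70) {
  if (inherits(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (length(seqs) < 1) stop("at least one sequence required")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (!is.numeric(identity) || identity <= 0 || identity > 1)
    stop("identity threshold must lie in (0, 1]")
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- integer(0)   # indices (into seqs) of cluster representatives
  assign <- integer(length(seqs))
  ident <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (c in seq_along(reps)) {
      pid <- if (seqs[i] == seqs[reps[c]]) 1 else
        global_identity(seqs[i], seqs[reps[c]])
      if (pid >= identity) {
        assign[i] <- c; ident[i] <- pid; placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
      ident[i] <- 1
    }
  }
  tibble::tibble(name = names(seqs), cluster = assign,
                 representative = seq_along(seqs) %in% reps,
                 identity_to_rep = ident)
}

#' Center-star progressive alignment of a cluster
#'
#' Aligns every member globally to the cluster representative (the center)
#' and merges the pairwise alignments on the center's coordinates,
#' left-justifying insertions. A testing-grade aligner: adequate for the
#' high-identity clusters the pipeline produces, not a replacement for a
#' production MSA program.
#'
#' @param seqs Named character vector; the first element is the center.
#' @return A [msa()].
#' @export
center_star_align <- function(seqs) {
  if (inherits(seqs, "AAStringSet")) seqs <- as.character(seqs)
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (n == 1) return(msa(seqs))
  center <- seqs[1]
  Lc <- nchar(center)
  per <- vector("list", n)  # per member: chars at center pos, insert strings
  per[[1]] <- list(at = strsplit(center, "")[[1]],
                   ins = rep("", Lc + 1))
  for (m in 2:n) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(center), Biostrings::AAString(seqs[m]),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    at <- character(Lc)
    ins <- rep("", Lc + 1)
    p <- 0
    for (k in seq_along(pa)) {
      if (pa[k] == "-") {
        if (sa[k] != "-") ins[p + 1] <- paste0(ins[p + 1], sa[k])
      } else {
        p <- p + 1
        at[p] <- sa[k]
      }
    }
    per[[m]] <- list(at = at, ins = ins)
  }
  maxins <- apply(vapply(per, function(x) nchar(x$ins), numeric(Lc + 1)), 1, max)
  rows <- vapply(per, function(x) {
    parts <- character(0)
    for (p in 0:Lc) {
      parts <- c(parts, sprintf("%-*s", maxins[p + 1], x$ins[p + 1]))
      if (p < Lc) parts <- c(parts, x$at[p + 1])
    }
    gsub(" ", "-", paste(parts, collapse = ""))
  }, character(1))
  msa(rows, names = names(seqs))
}

#' Pipeline configuration
#'
#' Validates and bundles the knobs of [run_pipeline()].
#'
#' @param identity Clustering identity threshold in `(0, 1]` (default 0.70,
#'   the standard protein-family grouping level).
#' @param pseudocount_mode `"substitution"`, `"none"` or `"context"`.
#' @param prefilter `"off"`, `"threshold"` or `"topN"`.
#' @param prefilter_value Score threshold or N.
#' @param score `"forward"` or `"viterbi"`.
#' @param seed Integer seed for every stochastic step.
#' @param context_library Optional [context_library()] for context mode.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(identity = 0.70,
                            pseudocount_mode = c("substitution", "none",
                                                 "context"),
                            prefilter = c("off", "threshold", "topN"),
                            prefilter_value = 0, score = c("forward", "viterbi"),
                            seed = 1, context_library = NULL) {
  if (!is.numeric(identity) || identity <= 0 || identity > 1)
    stop("identity must lie in (0, 1]")
  structure(list(identity = identity,
                 pseudocount_mode = match.arg(pseudocount_mode),
                 prefilter = match.arg(prefilter),
                 prefilter_value = prefilter_value,
                 score = match.arg(score),
                 seed = as.integer(seed),
                 context_library = context_library),
            class = "pipeline_config")
}

#' Run the full pHMM-tree workflow
#'
#' Clusters the input sequences at the identity threshold, aligns each
#' multi-member cluster (center-star), builds one profile HMM per cluster
#' and per singleton, scores all models against each other (optionally
#' prefiltered), converts scores to distances and builds the UPGMA tree.
#' All artifacts are written to `out_dir`: per-cluster alignments, the HMM
#' library (`library.hmm`), the score table (`scores.tsv`), the PHYLIP
#' distance matrix (`distances.phylip`), the Newick tree (`tree.nwk`) and a
#' run manifest with per-stage counts. With fewer than two models the tree
#' stage is skipped with an explanatory message.
#'
#' @param input FASTA path, `AAStringSet`, or named character vector.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `clusters` (tibble), `models`, `scores`,
#'   `distances`, `tree` (or `NULL`), `manifest` (tibble of stage counts).
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(input) && length(input) == 1 && file.exists(input)) {
    x <- Biostrings::readAAStringSet(input)
    seqs <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else if (inherits(input, "AAStringSet")) {
    seqs <- setNames(as.character(input), sub("\\s.*$", "", names(input)))
  } else {
    seqs <- input
  }
  if (length(seqs) == 0) stop("empty input")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  cl <- greedy_cluster(seqs, config$identity)
  sizes <- table(cl$cluster)
  singleton_ids <- as.integer(names(sizes)[sizes == 1])
  multi_ids <- as.integer(names(sizes)[sizes > 1])

  models <- list()
  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (cid in sort(unique(cl$cluster))) {
    memb <- cl$name[cl$cluster == cid]
    memb <- c(memb[cl$representative[cl$cluster == cid]],
              memb[!cl$representative[cl$cluster == cid]])
    a <- center_star_align(seqs[memb])
    nm <- if (cid %in% singleton_ids) memb[1] else sprintf("cluster%03d", cid)
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(setNames(a$seqs, a$names)),
      file.path(aln_dir, paste0(nm, ".fasta")))
    models[[length(models) + 1]] <-
      build_hmm(a, pseudocount_mode = config$pseudocount_mode,
                context_library = config$context_library, name = nm)
  }
  write_hmmer3(models, file.path(out_dir, "library.hmm"))

  tree <- NULL
  scores <- NULL
  distances <- NULL
  if (length(models) >= 2) {
    pf <- if (config$prefilter == "off") NULL else
      list(mode = config$prefilter, value = config$prefilter_value)
    scores <- all_vs_all(models, prefilter = pf, score = config$score)
    write_scores_tsv(scores, file.path(out_dir, "scores.tsv"))
    distances <- score_to_distance(scores)
    write_phylip(distances, file.path(out_dir, "distances.phylip"))
    tree <- upgma(distances)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
  } else {
    message("only one model built: tree construction needs >= 2, skipping")
  }

  manifest <- tibble::tibble(
    stage = c("sequences", "clusters", "singletons", "hmms",
              "pairs_scored", "pairs_prefiltered_out"),
    count = c(length(seqs), length(multi_ids), length(singleton_ids),
              length(models),
              if (is.null(scores)) 0 else sum(!is.na(scores[upper.tri(scores)])),
              if (is.null(scores)) 0 else sum(is.na(scores[upper.tri(scores)]))))
  writeLines(sprintf("%-22s %d", manifest$stage, manifest$count),
             file.path(out_dir, "manifest.txt"))
  invisible(list(clusters = cl, models = models, scores = scores,
                 distances = distances, tree = tree, manifest = manifest))
}

write_scores_tsv <- function(scores, path) {
  nm <- rownames(scores)
  idx <- which(upper.tri(scores, diag = TRUE), arr.ind = TRUE)
  lines <- c("query\ttarget\tscore_bits",
             sprintf("%s\t%s\t%s", nm[idx[, 1]], nm[idx[, 2]],
                     ifelse(is.na(scores[idx]), "NA",
                            sprintf("%.6f", scores[idx]))))
  writeLines(lines, path)
}

#' Classify a query against a profile HMM library
#'
#' Scores the query (a sequence, FASTA path, or prebuilt `profile_hmm`)
#' against every library model with the simple local forward score and
#' reports ranked hits; with a tree supplied, the best hit's smallest
#' enclosing clade (its sister group) is reported too.
#'
#' @param query Character sequence, FASTA path, or `profile_hmm`.
#' @param models Non-empty list of library `profile_hmm`s.
#' @param tree Optional `upgma_tree` or `phylo` over the same model names.
#' @return Tibble of hits sorted by score (`rank`, `target`,
#'   `forward_bits`), with the best hit's clade labels in
#'   `attr(, "best_clade")` when a tree is given.
#' @export
classify_query <- function(query, models, tree = NULL) {
  if (length(models) == 0) stop("empty model library")
  if (inherits(query, "profile_hmm")) {
    qh <- query
  } else {
    if (is.character(query) && length(query) == 1 && file.exists(query)) {
      x <- Biostrings::readAAStringSet(query)
      query <- setNames(as.character(x), sub("\\s.*$", "", names(x)))[1]
    }
    qh <- build_hmm(msa(query), pseudocount_mode = "substitution",
                    name = names(query) %||% "query")
  }
  bits <- vapply(models, function(h)
    pair_forward(qh, h)$forward_bits, numeric(1))
  out <- tibble::tibble(target = vapply(models, function(h) h$name,
                                        character(1)),
                        forward_bits = bits)
  out <- out[order(-out$forward_bits), ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "target", "forward_bits")]
  if (!is.null(tree)) {
    ph <- if (inherits(tree, "phylo")) tree else as.phylo.upgma_tree(tree)
    best <- out$target[1]
    tip <- match(best, ph$tip.label)
    if (!is.na(tip) && !is.null(ph$edge)) {
      parent <- ph$edge[ph$edge[, 2] == tip, 1]
      clade <- ape::extract.clade(ph, parent)
      attr(out, "best_clade") <- clade$tip.label
    }
  }
  out
}
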