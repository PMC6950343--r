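# Score-to-distance transform, UPGMA (fast vs naive), PHYLIP and Newick.

test_that("score-to-distance follows the self-score-normalized formula", {
  set.seed(71)
  n <- 6
  s <- matrix(runif(n * n, -2, 8), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- runif(n, 10, 20)
  dimnames(s) <- list(paste0("m", 1:n), paste0("m", 1:n))
  d <- score_to_distance(s)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:n)
    for (j in 1:n) {
      if (i == j) next
      expect_equal(d[i, j],
                   min(1, max(0, 1 - max(0, s[i, j]) / max(s[i, i], s[j, j]))),
                   tolerance = 1e-12)
    }
  # identical models are at distance zero; non-positive scores at one
  s2 <- matrix(c(5, 5, 5, 5), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(score_to_distance(s2)["a", "b"], 0)
  s3 <- matrix(c(5, -1, -1, 5), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(score_to_distance(s3)["a", "b"], 1)
  s4 <- s; diag(s4)[2] <- -3
  expect_error(score_to_distance(s4), "self score")
})

test_that("prefiltered-out pairs are imputed with the maximum distance", {
  s <- matrix(c(10, 8, NA, 8, 10, 2, NA, 2, 10), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  d <- score_to_distance(s)
  expect_equal(d[1, 3], max(d[upper.tri(d)]))
  expect_identical(d, t(d))
})

test_that("the textbook three-leaf case and tie degeneracies come out right", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d)
  expect_equal(write_newick(t3), "((A:1,B:1):1,C:2);")
  expect_equal(tree_heights(t3), c(1, 2))
  # all-equal distances: every merge at the same height, zero-length internals
  n <- 5
  de <- matrix(1, n, n); diag(de) <- 0
  dimnames(de) <- list(paste0("t", 1:n), paste0("t", 1:n))
  te <- upgma(de)
  expect_true(all(abs(tree_heights(te) - 0.5) < 1e-12))
  expect_lt(ultrametric_spread(te), 1e-12)
  # deterministic tie rule: lexicographically first pair merges first
  expect_equal(te$merges$a[1], -1)
  expect_equal(te$merges$b[1], -2)
})

test_that("O(n^2) UPGMA is identical to the naive O(n^3) reference", {
  set.seed(72)
  for (r in 1:25) {
    n <- sample(2:50, 1)
    d <- random_distance_matrix(n, tie_prone = r %% 3 == 0)
    fast <- upgma(d)
    slow <- upgma_naive(d)
    expect_identical(fast$merges, slow$merges)
    expect_lt(ultrametric_spread(fast), 1e-9)
    expect_true(all(diff(fast$merges$height) >= -1e-12))  # monotone merges
  }
})

test_that("UPGMA agrees with an established implementation on tie-free input", {
  set.seed(73)
  n <- 15
  d <- random_distance_matrix(n) + 0.05
  diag(d) <- 0
  d <- (d + t(d)) / 2
  ph1 <- ape::as.phylo(upgma(d))
  ph2 <- phangorn::upgma(stats::as.dist(d))
  expect_equal(phangorn::RF.dist(ph1, ph2), 0)
  expect_equal(sort(ape::node.depth.edgelength(ph1)[1:n]),
               sort(ape::node.depth.edgelength(ph2)[1:n]), tolerance = 1e-9)
})

test_that("invalid distance matrices are rejected", {
  d <- random_distance_matrix(4)
  d[1, 2] <- d[1, 2] + 0.5           # asymmetric
  expect_error(upgma(d), "symmetric")
  d2 <- random_distance_matrix(4); d2[2, 1] <- d2[1, 2] <- -1
  expect_error(upgma(d2), "non-negative")
  expect_error(upgma(random_distance_matrix(2)[1, 1, drop = FALSE] * NA),
               "")
})

test_that("leaf sets and label round trips are preserved", {
  set.seed(74)
  d <- random_distance_matrix(9)
  tr <- upgma(d)
  ph <- ape::as.phylo(tr)
  expect_setequal(ph$tip.label, rownames(d))
  # newick written with 6 significant digits re-reads to the same path lengths
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  ph2 <- ape::read.tree(f)
  expect_equal(phangorn::RF.dist(ph, ph2), 0)
  expect_equal(sort(ape::node.depth.edgelength(ph2)[1:9]),
               sort(ape::node.depth.edgelength(ph)[1:9]), tolerance = 1e-5)
  # a cherry serializes as (A:h,B:h);
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(write_newick(upgma(d2)), "(A:1.5,B:1.5);")
})

test_that("labels with Newick metacharacters are quoted and survive", {
  d <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3)
  labs <- c("pl(ain", "with space", "ok")
  dimnames(d) <- list(labs, labs)
  s <- write_newick(upgma(d))
  expect_match(s, "'pl\\(ain'", fixed = FALSE)
  ph <- ape::read.tree(text = s)
  # ape keeps the protective quotes verbatim; the label content survives
  expect_setequal(gsub("^'|'$", "", ph$tip.label), labs)
})

test_that("PHYLIP square matrices round-trip in both dialects", {
  set.seed(75)
  d <- random_distance_matrix(7)
  f <- withr::local_tempfile(fileext = ".phylip")
  write_phylip(d, f)
  d2 <- read_phylip(f)
  expect_identical(rownames(d2), rownames(d))
  expect_lt(max(abs(d - d2)), 1e-6)
  # 2x2 case is a 3-line file
  dd <- d[1:2, 1:2]
  f2 <- withr::local_tempfile(fileext = ".phylip")
  write_phylip(dd, f2)
  expect_length(readLines(f2), 3)
  expect_lt(max(abs(read_phylip(f2) - dd)), 1e-6)
  # strict dialect truncates long labels uniquely
  dl <- random_distance_matrix(3)
  labs <- c("longlabelnumber1", "longlabelnumber2", "short")
  dimnames(dl) <- list(labs, labs)
  fs <- withr::local_tempfile(fileext = ".phylip")
  write_phylip(dl, fs, strict = TRUE)
  r <- read_phylip(fs)
  expect_true(all(nchar(rownames(r)) <= 10))
  expect_false(anyDuplicated(rownames(r)) > 0)
  # whitespace labels are sanitized with a warning
  dw <- random_distance_matrix(2)
  dimnames(dw) <- list(c("a b", "c"), c("a b", "c"))
  fw <- withr::local_tempfile(fileext = ".phylip")
  expect_warning(write_phylip(dw, fw), "whitespace")
  expect_identical(rownames(read_phylip(fw))[1], "a_b")
})

test_that("all-vs-all equals independent pairwise calls and checks names", {
  hs <- make_toy_hmms(5, 6, seed = 76)
  M <- all_vs_all(hs)
  expect_identical(M, t(M))
  expect_false(anyNA(M))                         # prefilter off: no missing
  for (i in 1:5)
    for (j in i:5)
      expect_equal(M[i, j],
                   pair_forward(hs[[i]], hs[[j]])$forward_bits,
                   tolerance = 1e-12)
  hs2 <- hs; hs2[[2]]$name <- hs2[[1]]$name
  expect_error(all_vs_all(hs2), "duplicate")
  expect_error(all_vs_all(hs[1]), "at least 2")
  # two models: one off-diagonal value, mirrored
  M2 <- all_vs_all(hs[1:2])
  expect_equal(M2[1, 2], M2[2, 1])
})
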