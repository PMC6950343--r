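# Profile HMM construction: weights, pseudocounts, transitions.

test_that("single sequences give point-mass match states without pseudocounts", {
  h <- build_hmm(msa("ACD"), pseudocount_mode = "none")
  expect_equal(h$L, 3)
  expect_equal(unname(h$match[1, "A"]), 1)
  expect_equal(unname(h$match[2, "C"]), 1)
  expect_equal(unname(h$match[3, "D"]), 1)
  expect_silent(validate_profile_hmm(h))
})

test_that("duplicated sequences collapse to the single-sequence model", {
  for (n in c(2, 5, 9)) {
    hn <- build_hmm(msa(rep("MKVLIT", n)), pseudocount_mode = "substitution")
    h1 <- build_hmm(msa("MKVLIT"), pseudocount_mode = "substitution")
    expect_lt(max(abs(hn$match - h1$match)), 1e-12)
    expect_lt(max(abs(hn$transitions - h1$transitions)), 1e-12)
  }
})

test_that("substitution pseudocounts match a hand-computed admixture", {
  h <- build_hmm(msa("A"), pseudocount_mode = "substitution",
                 params = list(tau = 0.5))
  fobs <- c(1, rep(0, 19))
  g <- substitution_pseudocounts(matrix(fobs, 1, 20))[1, ]
  hand <- 0.5 * fobs + 0.5 * g
  expect_lt(max(abs(h$match[1, ] - hand / sum(hand))), 1e-12)
})

test_that("degenerate alignments raise the documented errors", {
  expect_error(build_hmm(msa(c("--", "--"))), "match columns")
  expect_error(msa(c("", "")), "[Zz]ero-length")
  expect_error(build_hmm(msa("ACD"), pseudocount_mode = "context"),
               "context_library")
})

test_that("non-standard residues map to X with a warning", {
  expect_warning(m <- msa("ACBDZ"), "mapped to X")
  expect_true(all(m$mat[1, c(3, 5)] == "X"))
})

test_that("emission rows move monotonically toward the pseudocount row in tau", {
  a <- msa(c("MKVA", "MKLA", "MRVA"))
  taus <- c(0, 0.2, 0.5, 0.8, 1)
  hs <- lapply(taus, function(tau)
    build_hmm(a, pseudocount_mode = "substitution", params = list(tau = tau)))
  pure <- hs[[length(taus)]]$match
  for (row in 1:4) {
    tv <- vapply(hs, function(h) 0.5 * sum(abs(h$match[row, ] - pure[row, ])),
                 numeric(1))
    expect_true(all(diff(tv) <= 1e-12))
  }
})

test_that("fuzzed alignments always yield valid models", {
  set.seed(31)
  for (r in 1:15) {
    n <- sample(1:6, 1)
    L <- sample(3:12, 1)
    rows <- vapply(seq_len(n), function(i)
      paste(sample(c(AA_letters(), "-"), L, replace = TRUE,
                   prob = c(rep(0.045, 20), 0.1)), collapse = ""),
      character(1))
    m <- tryCatch(msa(rows), error = function(e) NULL)
    if (is.null(m)) next
    h <- tryCatch(build_hmm(m), error = function(e) NULL)  # all-gap columns ok to skip
    if (is.null(h)) next
    expect_silent(validate_profile_hmm(h))
  }
})

test_that("context responsibilities match a brute-force Bayes oracle", {
  set.seed(12)
  # two near-orthogonal window profiles, window length 3
  p1 <- matrix(0.001, 3, 20); p1[, 1:3] <- 0.332; p1 <- p1 / rowSums(p1)
  p2 <- matrix(0.001, 3, 20); p2[, 15:17] <- 0.332; p2 <- p2 / rowSums(p2)
  lib <- context_library(list(p1, p2), priors = c(0.6, 0.4))
  counts <- matrix(rgamma(3 * 20, 0.4), 3, 20)
  out <- context_pseudocounts(counts, lib, admix = 1)
  for (i in 1:3) {
    resp <- brute_context_posterior(counts, lib, i, aa_background())
    expected <- resp[1] * p1[2, ] + resp[2] * p2[2, ]
    expect_lt(max(abs(out[i, ] - expected)), 1e-9)
  }
})

test_that("context admixture limits are the identity and the pure prior", {
  lib1 <- context_library(list(matrix(aa_background(), 1, 20, byrow = TRUE)))
  cts <- matrix(rgamma(5 * 20, 0.5), 5, 20)
  fobs <- t(apply(cts, 1, function(x) x / sum(x)))
  expect_equal(context_pseudocounts(cts, lib1, 0), fobs, tolerance = 1e-12)
  out1 <- context_pseudocounts(cts, lib1, 1)
  expect_lt(max(abs(sweep(out1, 2, aa_background()))), 1e-12)
  expect_error(context_pseudocounts(cts, lib1, -0.1), "admix")
  expect_error(context_pseudocounts(cts, lib1, 1.5), "admix")
})

test_that("a window-1 library reproduces substitution pseudocounts where the
          conditional model is idempotent", {
  # Rank-1 conditional model: every column of P(a|b) equals g0, so pushing
  # frequencies through it once or twice gives the same answer and the
  # context route (one application) must agree with the substitution route.
  g0 <- norm1(runif(20) + 0.1)
  lib <- context_library(list(matrix(g0, 1, 20, byrow = TRUE)))
  cts <- matrix(rgamma(4 * 20, 0.5), 4, 20)
  fobs <- t(apply(cts, 1, function(x) x / sum(x)))
  rank1 <- fobs %*% t(matrix(g0, 20, 20))  # substitution route, P[a,b] = g0[a]
  rank1 <- rank1 / rowSums(rank1)
  ctx <- context_pseudocounts(cts, lib, admix = 1)
  expect_lt(max(abs(ctx - rank1)), 1e-12)
  # and at intermediate admixture both routes still agree
  tau <- 0.3
  mixed <- (1 - tau) * fobs + tau * rank1
  expect_lt(max(abs(context_pseudocounts(cts, lib, tau) - mixed)), 1e-12)
})

test_that("context library text format round-trips", {
  set.seed(5)
  libs <- train_context_library(make_toy_hmms(3, 10, seed = 2), K = 4, w = 3,
                                seed = 9)
  f <- withr::local_tempfile(fileext = ".lib")
  write_context_library(libs, f)
  r <- read_context_library(f)
  expect_equal(r$K, libs$K)
  expect_equal(r$w, libs$w)
  expect_equal(r$priors, libs$priors, tolerance = 1e-6)
  for (k in seq_len(r$K))
    expect_lt(max(abs(r$profiles[[k]] - libs$profiles[[k]])), 1e-6)
})

test_that("effective sequence number behaves sensibly in both modes", {
  one <- build_hmm(msa("MKVLIT"), params = list(neff_method = "entropy"))
  expect_equal(one$metadata$neff, 1, tolerance = 1e-9)
  div <- build_hmm(msa(c("MKVLIT", "ARQEND", "GHWYCS")),
                   params = list(neff_method = "entropy"))
  expect_gt(div$metadata$neff, 1.5)
  uniq <- build_hmm(msa(c("MKVLIT", "MKVLIT", "ARQEND")),
                    params = list(neff_method = "unique"))
  expect_equal(uniq$metadata$neff, 2)
})
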