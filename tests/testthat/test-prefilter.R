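# Column-state alphabet training, discretization, Smith-Waterman scoring
# and candidate-pair selection.

test_that("K = 1 training returns the normalized mean profile", {
  set.seed(2)
  cols <- t(vapply(1:15, function(i) norm1(rgamma(20, 0.5)), numeric(20)))
  al <- train_alphabet(cols, K = 1, seed = 3)
  expect_equal(al$K, 1)
  expect_lt(max(abs(al$state_profiles[1, ] - norm1(colMeans(cols)))), 1e-9)
})

test_that("two well-separated clusters are recovered exactly (brute 2-means)", {
  set.seed(8)
  base1 <- norm1(c(rep(5, 5), rep(0.01, 15)))
  base2 <- norm1(c(rep(0.01, 15), rep(5, 5)))
  jitter_profile <- function(b) norm1(b * exp(rnorm(20, 0, 0.05)))
  cols <- rbind(t(vapply(1:6, function(i) jitter_profile(base1), numeric(20))),
                t(vapply(1:6, function(i) jitter_profile(base2), numeric(20))))
  al <- train_alphabet(cols, K = 2, seed = 4)
  oracle <- brute_kmeans2(cols)
  got <- lapply(seq_len(2), function(k) al$state_profiles[k, ])
  # match clusters up to ordering
  d <- function(a, b) max(abs(a - b))
  perm <- min(max(d(got[[1]], oracle[[1]]), d(got[[2]], oracle[[2]])),
              max(d(got[[1]], oracle[[2]]), d(got[[2]], oracle[[1]])))
  expect_lt(perm, 1e-6)
})

test_that("too few columns for K states is rejected with advice", {
  cols <- matrix(1 / 20, 5, 20)
  expect_error(train_alphabet(cols, K = 10), "reduce K")
})

test_that("substitution matrix closed forms and symmetry hold", {
  pm <- matrix(0, 3, 20)
  pm[1, 1] <- 1; pm[2, 1] <- 1; pm[3, 5] <- 1
  S <- state_substitution_matrix(pm, rep(1 / 20, 20), scale = 1)
  expect_equal(S[1, 2], 4L)                     # round(log2 20) same point mass
  expect_equal(S[1, 3], -16L)                   # orthogonal -> floor
  Sb <- state_substitution_matrix(rbind(aa_background(), aa_background()),
                                  scale = 1)
  expect_equal(Sb[1, 2], 0L)                    # background vs background
  set.seed(14)
  prof <- t(vapply(1:8, function(i) norm1(rgamma(20, 0.4)), numeric(20)))
  S8 <- state_substitution_matrix(prof, scale = 2)
  # independent double-loop recomputation
  bg <- aa_background()
  for (a in 1:8)
    for (b in 1:8) {
      lo <- log2(sum(prof[a, ] * prof[b, ] / bg))
      expect_equal(S8[a, b], as.integer(round(2 * max(lo, -16))))
    }
  expect_identical(S8, t(S8))
})

test_that("discretization is the exhaustive co-emission argmax", {
  set.seed(21)
  toy <- make_toy_hmms(3, 12, seed = 6)
  cols <- do.call(rbind, lapply(toy, function(h) h$match))
  al <- train_alphabet(cols, K = 9, seed = 2)
  for (h in toy) {
    s <- discretize(h, al)
    expect_length(s, h$L)
    for (i in seq_len(h$L)) {
      sc <- vapply(seq_len(al$K), function(k)
        coemission_column_score(h$match[i, ], al$state_profiles[k, ],
                                al$background), numeric(1))
      expect_equal(as.integer(s[i]), which.max(sc))  # first max = lowest index
    }
  }
  # a column equal to a state profile picks that state (self is the argmax)
  hself <- profile_hmm("self", al$state_profiles[4, , drop = FALSE])
  expect_equal(as.integer(discretize(hself, al)[1]), 4L)
})

test_that("Smith-Waterman matches closed forms and the brute-force oracle", {
  set.seed(33)
  prof <- t(vapply(1:6, function(i) norm1(rgamma(20, 0.4)), numeric(20)))
  al <- column_alphabet(prof)
  # identical sequences over a diagonal-dominant matrix: perfect diagonal path
  pm6 <- matrix(0, 6, 20); pm6[cbind(1:6, 1:6)] <- 1
  ald <- column_alphabet(pm6)
  s <- c(1L, 3L, 5L, 2L)
  expect_equal(smith_waterman(s, s, ald), sum(diag(ald$subst)[s]))
  # empty sequence scores zero
  expect_equal(smith_waterman(integer(0), s, al), 0L)
  # disjoint floored letters align nowhere
  pmA <- matrix(0, 2, 20); pmA[1, 1] <- 1; pmA[2, 2] <- 1
  pmB <- matrix(0, 2, 20); pmB[1, 10] <- 1; pmB[2, 11] <- 1
  alp <- column_alphabet(rbind(pmA, pmB))
  expect_equal(smith_waterman(c(1L, 2L), c(3L, 4L), alp), 0L)
  # brute-force enumeration on short random pairs
  for (r in 1:12) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    s1 <- sample(6, n1, replace = TRUE)
    s2 <- sample(6, n2, replace = TRUE)
    expect_equal(smith_waterman(s1, s2, al, 6, 1),
                 max(0, brute_sw(s1, s2, al$subst, 6, 1)))
  }
  # one longer case
  s1 <- sample(6, 6, replace = TRUE); s2 <- sample(6, 6, replace = TRUE)
  expect_equal(smith_waterman(s1, s2, al, 6, 1),
               max(0, brute_sw(s1, s2, al$subst, 6, 1)))
})

test_that("pair selection retains self pairs and is symmetric", {
  toy <- make_toy_hmms(6, 15, seed = 13)
  cols <- do.call(rbind, lapply(toy, function(h) h$match))
  al <- train_alphabet(cols, K = 10, seed = 1)
  seqs <- lapply(toy, discretize, alphabet = al)
  pf_all <- prefilter_pairs(seqs, mode = "threshold", value = 0, alphabet = al)
  expect_true(all(pf_all$keep))                     # SW >= 0: everything kept
  pf_top <- prefilter_pairs(seqs, mode = "topN", value = length(toy) - 1,
                            alphabet = al)
  expect_true(all(pf_top$keep))                     # topN = n-1 keeps all
  pf <- prefilter_pairs(seqs, mode = "topN", value = 1, alphabet = al)
  expect_true(all(pf$keep[pf$query == pf$target]))  # self pairs survive
  expect_error(prefilter_pairs(seqs, mode = "threshold", value = "x",
                               alphabet = al), "value")
})

test_that("discretization quality is monotone in alphabet size", {
  toy <- make_toy_hmms(10, 30, seed = 77)
  cols <- do.call(rbind, lapply(toy, function(h) h$match))
  avg_co <- vapply(c(4, 8, 16, 32, 64), function(K) {
    a <- train_alphabet(cols, K = K, seed = 42)
    mean(vapply(toy, function(h) {
      s <- discretize(h, a)
      mean(vapply(seq_along(s), function(i)
        coemission_column_score(h$match[i, ], a$state_profiles[s[i], ],
                                a$background), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(avg_co) >= -1e-9))
})

test_that("alphabet files round-trip through the context-library format", {
  toy <- make_toy_hmms(4, 10, seed = 19)
  cols <- do.call(rbind, lapply(toy, function(h) h$match))
  al <- train_alphabet(cols, K = 7, seed = 5)
  f <- withr::local_tempfile(fileext = ".alphabet")
  write_alphabet(al, f)
  r <- read_alphabet(f)
  expect_equal(r$K, 7)
  expect_lt(max(abs(r$state_profiles - al$state_profiles)), 1e-6)
  expect_identical(r$subst, al$subst)
  # a window-3 library is not an alphabet
  lib3 <- train_context_library(toy, K = 3, w = 3, seed = 1)
  f3 <- withr::local_tempfile(fileext = ".lib")
  write_context_library(lib3, f3)
  expect_error(read_alphabet(f3), "window")
})
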