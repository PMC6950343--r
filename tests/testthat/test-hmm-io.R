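# HMMER3 profile format: decoding, encoding, dialects, error handling.

test_that("star token decodes to exact zero and headers set the node count", {
  hs <- make_toy_hmms(1, 3, seed = 4)
  h <- hs[[1]]
  h$match[2, ] <- c(rep(1 / 19, 19), 0)  # a genuine zero emission
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(h, f)
  txt <- readLines(f)
  expect_true(any(grepl("\\*", txt[grepl("^      2", txt)])))
  r <- read_hmmer3(f)[[1]]
  expect_identical(unname(r$match[2, 20]), 0)      # "*" -> exactly 0.0
  expect_equal(r$L, 3)                     # LENG contract
  expect_equal(nrow(r$transitions), 4)     # L + 1 transition rows
  expect_equal(r$name, h$name)
})

test_that("read-write-read is the identity on probability content", {
  hs <- make_toy_hmms(4, 7, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".hmm")
  f2 <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(hs, f1)
  r1 <- read_hmmer3(f1)
  write_hmmer3(r1, f2)
  r2 <- read_hmmer3(f2)
  expect_length(r1, 4)
  for (k in seq_along(r1)) {
    expect_lt(max(abs(r1[[k]]$match - r2[[k]]$match)), 1e-9)
    expect_lt(max(abs(r1[[k]]$insert - r2[[k]]$insert)), 1e-9)
    expect_lt(max(abs(r1[[k]]$transitions - r2[[k]]$transitions)), 1e-9)
  }
})

test_that("parsing renormalizes rows by less than 1e-6 per entry", {
  hs <- make_toy_hmms(2, 6, seed = 3)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(hs, f)
  for (h in read_hmmer3(f)) {
    raw_m <- h$match            # already renormalized on read
    renorm <- raw_m / rowSums(raw_m)
    expect_lt(max(abs(raw_m - renorm)), 1e-6)
    expect_lt(max(abs(rowSums(h$match) - 1)), 1e-9)
  }
})

test_that("uniform match rows encode as -ln(1/20) and empty lists are fine", {
  h <- profile_hmm("unif", matrix(1 / 20, 2, 20))
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(h, f)
  match_lines <- grep("^      [12] ", readLines(f), value = TRUE)
  fields <- strsplit(trimws(match_lines[1]), "\\s+")[[1]][2:21]
  expect_true(all(fields == "2.99573"))    # -ln(0.05) to 5 decimals
  f0 <- withr::local_tempfile(fileext = ".hmm")
  expect_silent(write_hmmer3(list(), f0))
  expect_identical(readLines(f0), character(0))
})

test_that("dialects 3/b-3/f parse; 3/a, HMMER2 and non-amino are rejected", {
  hs <- make_toy_hmms(1, 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(hs, f)
  base <- readLines(f)
  for (v in c("b", "c", "d", "e", "f")) {
    fd <- withr::local_tempfile(fileext = ".hmm")
    writeLines(c(sprintf("HMMER3/%s [test]", v), base[-1]), fd)
    expect_equal(read_hmmer3(fd)[[1]]$metadata$version, paste0("3/", v))
  }
  fa <- withr::local_tempfile(fileext = ".hmm")
  writeLines(c("HMMER3/a [test]", base[-1]), fa)
  expect_error(read_hmmer3(fa), "3/a")
  f2 <- withr::local_tempfile(fileext = ".hmm")
  writeLines(c("HMMER2.0 [2.3.2]", base[-1]), f2)
  expect_error(read_hmmer3(f2), "HMMER3")
  fd <- withr::local_tempfile(fileext = ".hmm")
  writeLines(sub("^ALPH  amino", "ALPH  DNA", base), fd)
  expect_error(read_hmmer3(fd), "alphabet")
})

test_that("LENG / node-count mismatches name the offending node", {
  hs <- make_toy_hmms(1, 3, seed = 6)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(hs, f)
  txt <- readLines(f)
  short <- txt[!grepl("^      3 ", txt)]
  short <- short[-(which(grepl("^      2 ", short)) + (3:4))]  # drop node 3 block
  fs <- withr::local_tempfile(fileext = ".hmm")
  writeLines(short, fs)
  expect_error(read_hmmer3(fs), "node")
})

test_that("writer validates models before emitting any bytes", {
  h <- make_toy_hmms(1, 2, seed = 7)[[1]]
  h$match[1, ] <- h$match[1, ] * 0.9  # broken normalization
  f <- withr::local_tempfile(fileext = ".hmm")
  expect_error(write_hmmer3(h, f), "sum to 1")
  expect_false(file.exists(f) && file.size(f) > 0)
})

test_that("COMPO is stored, usable as background, and switchable off", {
  h <- make_toy_hmms(1, 4, seed = 8)[[1]]
  h$metadata$compo <- norm1(runif(20) + 0.2)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(h, f)
  r_on <- read_hmmer3(f, use_compo = TRUE)[[1]]
  r_off <- read_hmmer3(f, use_compo = FALSE)[[1]]
  expect_lt(max(abs(r_on$background - h$metadata$compo)), 1e-4)
  expect_equal(r_off$background, unname(aa_background()), tolerance = 1e-12)
})

test_that("written files are accepted by the HMMER toolchain", {
  hs <- make_toy_hmms(2, 5, seed = 9)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3(hs, f)
  out <- suppressWarnings(system2("hmmstat", f, stdout = TRUE, stderr = TRUE))
  expect_true(any(grepl("toy01", out)))
  expect_true(any(grepl("toy02", out)))
})
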