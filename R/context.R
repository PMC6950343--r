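# Context libraries: K window profiles with priors, used for
# context-specific pseudocounts (window w > 1) and, with w = 1, as a
# column-state alphabet source.

#' Construct a context library
#'
#' @param profiles List of K matrices, each `w x 20`, every row summing to 1
#'   (window position distributions over amino acids).
#' @param priors K prior weights, normalized to sum to 1.
#' @return Object of class `context_library` with fields `K`, `w`,
#'   `priors`, `profiles`.
#' @export
context_library <- function(profiles, priors = NULL) {
  K <- length(profiles)
  if (K < 1) stop("context library needs at least one profile")
  profiles <- lapply(profiles, as.matrix)
  w <- nrow(profiles[[1]])
  if (w < 1 || w %% 2 == 0) stop("window length must be odd and >= 1")
  for (p in profiles) {
    if (nrow(p) != w || ncol(p) != 20)
      stop("every context profile must be w x 20")
    if (any(abs(rowSums(p) - 1) > 1e-6))
      stop("every context window column must sum to 1")
  }
  priors <- priors %||% rep(1 / K, K)
  if (length(priors) != K || any(priors < 0))
    stop("priors must be K non-negative weights")
  structure(list(K = K, w = w, priors = norm1(priors),
                 profiles = lapply(profiles, function(p) {
                   colnames(p) <- AA; p
                 })),
            class = "context_library")
}

#' @export
print.context_library <- function(x, ...) {
  cat(sprintf("Context library: K = %d profiles, window w = %d\n", x$K, x$w))
  invisible(x)
}

#' Read a context library from its text format
#'
#' Format: a header line `K w`, then K blocks each consisting of one prior
#' line followed by `w` lines of 20 whitespace-separated probabilities.
#' Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return A [context_library()].
#' @export
read_context_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hd <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  K <- hd[1]; w <- hd[2]
  if (is.na(K) || is.na(w)) stop("malformed context library header")
  i <- 2
  priors <- numeric(K)
  profiles <- vector("list", K)
  for (k in seq_len(K)) {
    priors[k] <- as.numeric(trimws(lines[i])); i <- i + 1
    rows <- t(vapply(lines[i:(i + w - 1)], function(ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]][1:20]), numeric(20)))
    rownames(rows) <- NULL
    profiles[[k]] <- rows
    i <- i + w
  }
  context_library(profiles, priors)
}

#' Write a context library in its text format
#'
#' @param lib A [context_library()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_context_library <- function(lib, path) {
  stopifnot(inherits(lib, "context_library"))
  out <- c(sprintf("%d %d", lib$K, lib$w))
  for (k in seq_len(lib$K)) {
    out <- c(out, sprintf("%.8g", lib$priors[k]),
             apply(lib$profiles[[k]], 1, function(r)
               paste(sprintf("%.8g", r), collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Train a small context library by k-means over profile windows
#'
#' Slides windows of length `w` over the match-emission rows of the supplied
#' profiles (or plain probability matrices), flattens them, and clusters in
#' square-root coordinates. Each context is the mean of its assigned windows
#' (columns renormalized); priors are the cluster occupancy fractions.
#'
#' @param profiles List of `profile_hmm`s or of L x 20 probability matrices.
#' @param K Number of contexts.
#' @param w Odd window length.
#' @param seed Integer seed making the clustering deterministic.
#' @return A [context_library()].
#' @export
train_context_library <- function(profiles, K, w = 1, seed = 1) {
  mats <- lapply(profiles, function(p)
    if (inherits(p, "profile_hmm")) p$match else as.matrix(p))
  h <- (w - 1) / 2
  bg <- aa_background()
  wins <- list()
  for (m in mats) {
    L <- nrow(m)
    padded <- rbind(matrix(rep(bg, each = h), nrow = h, ncol = 20), m,
                    matrix(rep(bg, each = h), nrow = h, ncol = 20))
    for (i in seq_len(L))
      wins[[length(wins) + 1]] <- padded[i:(i + w - 1), , drop = FALSE]
  }
  if (length(wins) < K)
    stop(sprintf("only %d windows available for K = %d contexts; reduce K",
                 length(wins), K))
  X <- t(vapply(wins, function(x) sqrt(as.numeric(x)), numeric(w * 20)))
  km <- safe_kmeans(X, K, seed)
  profiles_out <- vector("list", K)
  priors <- numeric(K)
  for (k in seq_len(K)) {
    members <- wins[km$cluster == k]
    priors[k] <- length(members) / length(wins)
    avg <- Reduce(`+`, members) / length(members)
    profiles_out[[k]] <- avg / rowSums(avg)
  }
  context_library(profiles_out, priors)
}
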