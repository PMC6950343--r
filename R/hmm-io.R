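# HMMER3 text profile format, read and write.
#
# Layout recap (dialect 3/f; 3/b-3/e differ only in header fields):
#   HMMER3/f [version]
#   NAME  ...
#   LENG  <L>
#   ALPH  amino
#   ...
#   HMM          A        C   ...   Y
#               m->m     m->i  ...  d->d
#     COMPO   <20 neg-log values>          (optional)
#             <20 insert-0 emissions>
#             <7 BEGIN transitions>
#         1   <20 match emissions>  <annotation tokens>
#             <20 insert emissions>
#             <7 transitions>
#     ...
#   //
# All probability fields are negative natural logs; "*" encodes probability 0.

.decode_field <- function(tok) {
  p <- ifelse(tok == "*", 0, exp(-suppressWarnings(as.numeric(tok))))
  if (anyNA(p)) stop("malformed numeric field in HMMER3 file: ",
                     paste(tok[is.na(p)], collapse = " "))
  p
}

.encode_field <- function(p) {
  ifelse(p <= 0, sprintf("%8s", "*"), sprintf("%8.5f", -log(p)))
}

#' Read profile HMMs from a HMMER3 text file
#'
#' Parses one or more concatenated models from HMMER3 text (dialects `3/b`
#' through `3/f`; `3/a` and binary files are rejected). Negative natural-log
#' fields are converted to probabilities and the `*` token decodes to exactly
#' 0. Emission rows and transition groups are renormalized on read: the file
#' stores 5-decimal logs, so raw sums deviate from 1 by up to ~1e-5 and
#' renormalization changes entries by less than 1e-6. The `COMPO` average
#' composition, when present, is stored in metadata and used as the model's
#' background unless `use_compo = FALSE`.
#'
#' Optional per-node annotation columns (MAP/CONS/RF/MM/CS) are preserved in
#' `metadata$annotation` and ignored by all computation.
#'
#' @param path Path to a HMMER3 text file (possibly multi-model).
#' @param use_compo Use the file's COMPO line as the background when present
#'   (default `TRUE`); otherwise the standard background [aa_background()] is
#'   attached.
#' @return List of [profile_hmm()] objects.
#' @export
read_hmmer3 <- function(path, use_compo = TRUE) {
  lines <- readLines(path, warn = FALSE)
  models <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1
    if (i > n) break
    head_line <- lines[i]
    m <- regmatches(head_line, regexec("^HMMER([0-9])/([a-z])", head_line))[[1]]
    if (length(m) == 0)
      stop("not a HMMER3 text file (header line: ", substr(head_line, 1, 40), ")")
    if (m[2] != "3" || !(m[3] %in% c("b", "c", "d", "e", "f")))
      stop(sprintf("unsupported HMMER format version '%s/%s' (dialects 3/b-3/f supported)",
                   m[2], m[3]))
    version <- paste0(m[2], "/", m[3])
    i <- i + 1
    header <- list()
    while (i <= n && !grepl("^HMM\\s", lines[i])) {
      kv <- regmatches(lines[i], regexec("^(\\S+)\\s+(.*)$", lines[i]))[[1]]
      if (length(kv) == 3) header[[kv[2]]] <- trimws(kv[3])
      i <- i + 1
    }
    if (i > n) stop("corrupt HMMER3 file: no HMM line for model starting at '",
                    head_line, "'")
    alph <- tolower(header$ALPH %||% "")
    if (alph != "amino")
      stop("unsupported alphabet '", header$ALPH %||% "?",
           "': only amino-acid profiles are supported")
    L <- as.integer(header$LENG %||% NA)
    if (is.na(L) || L < 1) stop("missing or invalid LENG header field")
    aa_order <- strsplit(trimws(sub("^HMM\\s+", "", lines[i])), "\\s+")[[1]]
    if (!identical(aa_order, AA))
      stop("unexpected residue column order in HMM line")
    i <- i + 2  # skip the m->m ... d->d header line
    compo <- NULL
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (identical(toks[1], "COMPO")) {
      compo <- norm1(.decode_field(toks[2:21]))
      i <- i + 1
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    }
    insert0 <- norm1(.decode_field(toks[1:20]))
    i <- i + 1
    transitions <- matrix(0, L + 1, 7, dimnames = list(NULL, TRANS_COLS))
    transitions[1, ] <- .decode_field(strsplit(trimws(lines[i]), "\\s+")[[1]][1:7])
    i <- i + 1
    match <- matrix(0, L, 20)
    insert <- matrix(0, L, 20)
    annotation <- vector("list", L)
    for (k in seq_len(L)) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (identical(toks[1], "//"))
        stop(sprintf("corrupt HMMER3 file: %d node(s) found but LENG is %d (node %d missing)",
                     k - 1, L, k))
      node <- suppressWarnings(as.integer(toks[1]))
      if (is.na(node) || node != k)
        stop(sprintf("corrupt HMMER3 file: expected node %d, found '%s'", k, toks[1]))
      match[k, ] <- .decode_field(toks[2:21])
      if (length(toks) > 21) annotation[[k]] <- toks[22:length(toks)]
      insert[k, ] <- .decode_field(strsplit(trimws(lines[i + 1]), "\\s+")[[1]][1:20])
      transitions[k + 1, ] <-
        .decode_field(strsplit(trimws(lines[i + 2]), "\\s+")[[1]][1:7])
      i <- i + 3
    }
    while (i <= n && !grepl("^//", lines[i])) {
      if (grepl("^\\s*[0-9]+\\s", lines[i]))
        stop(sprintf("corrupt HMMER3 file: extra node beyond LENG %d at node %s",
                     L, strsplit(trimws(lines[i]), "\\s+")[[1]][1]))
      i <- i + 1
    }
    i <- i + 1  # past //
    # Renormalize rows (files carry 5-decimal log precision).
    match <- t(apply(match, 1, norm1))
    insert <- t(apply(insert, 1, norm1))
    for (grp in list(1:3, 4:5, 6:7)) {
      s <- rowSums(transitions[, grp, drop = FALSE])
      def <- s > 1e-12
      transitions[def, grp] <- transitions[def, grp, drop = FALSE] / s[def]
    }
    meta <- list(version = version, header = header, insert0 = insert0,
                 annotation = annotation)
    if (!is.null(compo)) meta$compo <- compo
    if (!is.null(header$EFFN))
      meta$neff <- suppressWarnings(as.numeric(header$EFFN))
    bg <- if (use_compo && !is.null(compo)) compo else aa_background()
    models[[length(models) + 1]] <- profile_hmm(
      name = header$NAME %||% sprintf("model%d", length(models) + 1),
      match = match, insert = insert, transitions = transitions,
      background = bg, metadata = meta)
  }
  models
}

#' Write profile HMMs as HMMER3 text
#'
#' Emits the `HMMER3/f` dialect: probability fields as 5-decimal negative
#' natural logs, zero probabilities as `*`, one model per block terminated by
#' `//`, multiple models concatenated. Models are validated before any output
#' is produced. Together with [read_hmmer3()] the 5-decimal log grid is a
#' fixed point: read-write-read reproduces probabilities to well below 1e-9.
#'
#' @param models A `profile_hmm` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly. An empty model list writes an empty file.
#' @export
write_hmmer3 <- function(models, path) {
  if (inherits(models, "profile_hmm")) models <- list(models)
  lapply(models, validate_profile_hmm, tol = 1e-5)
  out <- character(0)
  for (h in models) {
    meta <- h$metadata
    lines <- c(
      "HMMER3/f [prcx]",
      sprintf("NAME  %s", h$name),
      sprintf("LENG  %d", h$L),
      "ALPH  amino")
    if (!is.null(meta$neff)) lines <- c(lines, sprintf("EFFN  %.6f", meta$neff))
    lines <- c(lines, "MAP   yes")
    lines <- c(lines,
      paste0("HMM  ", paste(sprintf("%8s", AA), collapse = " ")),
      paste0("     ", paste(sprintf("%8s", c("m->m", "m->i", "m->d", "i->m",
                                             "i->i", "d->m", "d->d")),
                            collapse = " ")))
    compo <- meta$compo %||% h$background
    lines <- c(lines,
      paste0("  COMPO ", paste(.encode_field(compo), collapse = " ")))
    insert0 <- meta$insert0 %||% h$background
    lines <- c(lines,
      paste0("        ", paste(.encode_field(insert0), collapse = " ")),
      paste0("        ", paste(.encode_field(h$transitions[1, ]), collapse = " ")))
    for (k in seq_len(h$L)) {
      ann <- c(as.character(k), "-", "-", "-", "-")
      lines <- c(lines,
        paste0(sprintf("%7d ", k),
               paste(.encode_field(h$match[k, ]), collapse = " "),
               " ", paste(ann, collapse = " ")),
        paste0("        ", paste(.encode_field(h$insert[k, ]), collapse = " ")),
        paste0("        ", paste(.encode_field(h$transitions[k + 1, ]),
                                 collapse = " ")))
    }
    out <- c(out, lines, "//")
  }
  writeLines(out, path)
  invisible(path)
}
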