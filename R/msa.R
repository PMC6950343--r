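#' Construct a (possibly trivial) multiple sequence alignment
#'
#' Holds equal-length aligned amino-acid sequences. Permitted characters are
#' the 20 canonical residues, `X` and the gap `-`; `.` is converted to `-`
#' and any other character is mapped to `X` with a warning. A single
#' unaligned sequence is a valid one-row alignment.
#'
#' @param seqs Character vector of aligned sequences (rows).
#' @param names Sequence names; defaults to `names(seqs)` or `seq1..seqn`.
#' @return Object of class `prcx_msa` with fields `names`, `seqs` and the
#'   residue matrix `mat` (rows = sequences).
#' @export
msa <- function(seqs, names = NULL) {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 1) stop("alignment must contain at least one sequence")
  if (any(nchar(seqs) == 0)) stop("zero-length sequences are not allowed")
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned sequences must all have the same length")
  names <- names %||% base::names(seqs) %||% paste0("seq", seq_along(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  mat <- do.call(rbind, strsplit(seqs, ""))
  ok <- mat %in% c(AA, "X", "-")
  if (!all(ok)) {
    warning(sprintf("%d non-standard residue(s) mapped to X", sum(!ok)))
    mat[!ok] <- "X"
  }
  rownames(mat) <- names
  structure(list(names = names, seqs = apply(mat, 1, paste, collapse = ""),
                 mat = mat),
            class = "prcx_msa")
}

#' Read a FASTA file as an alignment
#'
#' Reads single-sequence or aligned multi-FASTA via Biostrings. All records
#' must have equal length (an alignment); a file with a single record is
#' treated as a trivial one-row alignment.
#'
#' @param path FASTA file path.
#' @return A [msa()] object.
#' @export
read_fasta_msa <- function(path) {
  x <- Biostrings::readBStringSet(path)
  msa(as.character(x), names = sub("\\s.*$", "", names(x)))
}

#' @export
print.prcx_msa <- function(x, ...) {
  cat(sprintf("Alignment: %d sequence(s) x %d column(s)\n",
              length(x$names), ncol(x$mat)))
  invisible(x)
}

#' Per-column gap fraction of an alignment
#' @param m A `prcx_msa`.
#' @return Numeric vector, one value per alignment column.
#' @export
gap_fraction <- function(m) {
  colMeans(m$mat == "-")
}
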