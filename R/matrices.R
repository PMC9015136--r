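#' Read an amino-acid substitution matrix
#'
#' Parses NCBI/EMBOSS-style whitespace-delimited square matrix text: an
#' optional block of `#` comment lines, a header row of residue codes,
#' then one row per residue beginning with its code. The matrix must be
#' square over the header alphabet and symmetric; asymmetry is reported
#' with the offending residue pair. This is the format BLOSUM/PAM and the
#' IDP-derived families (EDSSMat, Disorder, DUNMat) are distributed in,
#' so matrices obtained from their original sources drop in directly.
#'
#' @param path Path to the matrix file.
#' @param name Name to attach; defaults to the file name.
#' @return A numeric matrix of class `substitution_matrix` with residue
#'   dimnames and a `name` attribute.
#' @export
read_substitution_matrix <- function(path, name = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) abort(sprintf("Not a matrix file: %s", path))
  header <- strsplit(lines[1], "\\s+")[[1]]
  k <- length(header)
  rows <- strsplit(lines[-1], "\\s+")
  if (length(rows) != k) {
    abort(sprintf("Header lists %d residues but file has %d data rows.", k, length(rows)))
  }
  if (any(lengths(rows) != k + 1L)) {
    i <- which(lengths(rows) != k + 1L)[1]
    abort(sprintf("Row %d has %d fields; expected residue code plus %d scores.",
                  i, lengths(rows)[i], k))
  }
  row_codes <- vapply(rows, `[[`, "", 1L)
  if (!identical(row_codes, header)) {
    abort("Row labels do not match the header alphabet (order included).")
  }
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(k))
  )
  if (anyNA(vals)) abort(sprintf("Non-numeric score in %s.", path))
  m <- t(vals)
  dimnames(m) <- list(header, header)
  validate_substitution_matrix(m, name %||% sub("\\.[^.]*$", "", basename(path)))
}

validate_substitution_matrix <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("Substitution matrix must be square.")
  asym <- which(m != t(m), arr.ind = TRUE)
  asym <- asym[asym[, 1] < asym[, 2], , drop = FALSE]
  if (nrow(asym) > 0) {
    i <- asym[1, 1]; j <- asym[1, 2]
    abort(sprintf(
      "Matrix is asymmetric: score(%s,%s) = %g but score(%s,%s) = %g.",
      rownames(m)[i], colnames(m)[j], m[i, j],
      rownames(m)[j], colnames(m)[i], m[j, i]
    ))
  }
  structure(m, name = name, class = c("substitution_matrix", class(m)))
}

#' Write a substitution matrix in NCBI-style text format
#'
#' @param m A `substitution_matrix` (or plain symmetric named matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substitution_matrix <- function(m, path) {
  m <- validate_substitution_matrix(unclass_matrix(m), attr(m, "name") %||% "matrix")
  codes <- rownames(m)
  wid <- max(3L, max(nchar(format(m, trim = TRUE))) + 1L)
  fmt <- function(x) formatC(x, width = wid)
  lines <- c(
    paste0("# ", attr(m, "name")),
    paste0("  ", paste(formatC(codes, width = wid), collapse = "")),
    vapply(seq_along(codes), function(i) {
      paste0(formatC(codes[i], width = 2L, flag = "-"),
             paste(fmt(format(m[i, ], trim = TRUE)), collapse = ""))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

unclass_matrix <- function(m) {
  class(m) <- setdiff(class(m), "substitution_matrix")
  m
}

#' Score a pair of aligned (gapped) sequences
#'
#' Sums substitution scores over aligned residue pairs and applies
#' affine gap penalties: each maximal run of gaps in either sequence
#' costs `gap_open + (run_length - 1) * gap_extend`. Columns where both
#' sequences carry a gap are ignored. Lets a matrix be exercised without
#' an external aligner; alignment search itself is out of scope.
#'
#' @param a,b Gapped sequences of equal length; gap character `-`.
#' @param matrix A `substitution_matrix`.
#' @param gap_open Penalty for opening a gap run (typically negative).
#' @param gap_extend Penalty per additional gap position (typically
#'   negative).
#' @return Total alignment score (scalar).
#' @examples
#' toy <- validate_substitution_matrix(
#'   matrix(c(4, -1, -1, 5), 2, dimnames = list(c("A", "R"), c("A", "R"))), "toy")
#' score_aligned_pair("A-A", "AAA", toy, gap_open = -5, gap_extend = -1)
#' @export
score_aligned_pair <- function(a, b, matrix, gap_open = -10, gap_extend = -1) {
  if (nchar(a) != nchar(b)) {
    abort(sprintf("Aligned sequences differ in length (%d vs %d).", nchar(a), nchar(b)))
  }
  ca <- seq_chars(toupper(a))
  cb <- seq_chars(toupper(b))
  both_gap <- ca == "-" & cb == "-"
  ca <- ca[!both_gap]; cb <- cb[!both_gap]
  if (length(ca) == 0L) return(0)
  gap <- ca == "-" | cb == "-"
  res <- c(ca[!gap], cb[!gap])
  bad <- setdiff(unique(res), rownames(matrix))
  if (length(bad) > 0) {
    abort(sprintf("Residue(s) not in matrix alphabet: %s.", paste(bad, collapse = ", ")))
  }
  sub_score <- if (any(!gap)) sum(matrix[cbind(ca[!gap], cb[!gap])]) else 0
  gap_score <- 0
  if (any(gap)) {
    runs <- rle(gap)
    lens <- runs$lengths[runs$values]
    gap_score <- sum(gap_open + (lens - 1) * gap_extend)
  }
  sub_score + gap_score
}
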