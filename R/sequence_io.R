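#' @keywords internal
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# letters with an IUPAC meaning but no single standard residue; replaced by
# the mask sentinel "X" under the "mask" policy
AA_AMBIGUOUS <- c("B", "J", "O", "U", "X", "Z")

AA_MASK <- "X"

#' Parse and validate a protein sequence
#'
#' Normalises free text into a validated one-letter amino-acid sequence:
#' whitespace and digits are stripped (so numbered sequence blocks paste
#' cleanly) and letters are upper-cased. Characters outside the 20
#' standard residue codes are handled by the unknown-residue policy:
#' `"strict"` (default) errors, naming the character and its 1-based
#' position in the normalised sequence; `"mask"` replaces the ambiguity
#' codes (B, J, O, U, X, Z) with the sentinel `X`, with a warning. Masked
#' positions are excluded from every average and window downstream, so a
#' masked sequence never silently biases a classification.
#'
#' @param raw Free text containing the sequence.
#' @param id Optional identifier; defaults to `"seq"`.
#' @param unknown Unknown-residue policy, `"strict"` or `"mask"`.
#' @param allow_sentinel Accept an existing mask sentinel `X` as valid
#'   (used when revalidating already-parsed sequences).
#' @return A one-row tibble with columns `id`, `seq`, `length`.
#' @examples
#' parse_sequence("mdvfmkGLS")
#' parse_sequence("MD VF\n10 MK")
#' @export
parse_sequence <- function(raw, id = "seq", unknown = c("strict", "mask"),
                           allow_sentinel = FALSE) {
  unknown <- arg_match(unknown)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    abort("`raw` must be a single character string.")
  }
  seq <- toupper(gsub("[[:space:][:digit:]]", "", raw))
  if (!nzchar(seq)) {
    abort("Sequence is empty after removing whitespace and digits.")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  legal <- if (allow_sentinel) c(AA_STANDARD, AA_MASK) else AA_STANDARD
  bad <- which(!chars %in% legal)
  if (length(bad) > 0) {
    if (unknown == "strict") {
      abort(sprintf(
        "Invalid residue '%s' at position %d (strict policy; use unknown = \"mask\" for ambiguity codes).",
        chars[bad[1]], bad[1]
      ))
    }
    maskable <- chars[bad] %in% AA_AMBIGUOUS
    if (any(!maskable)) {
      i <- bad[!maskable][1]
      abort(sprintf("Invalid character '%s' at position %d.", chars[i], i))
    }
    warn(sprintf(
      "Masked %d non-standard residue(s) (%s) with '%s'; masked positions are excluded from averages.",
      length(bad), paste(unique(chars[bad]), collapse = ", "), AA_MASK
    ))
    chars[bad] <- AA_MASK
    seq <- paste(chars, collapse = "")
  }
  tibble(id = as.character(id), seq = seq, length = nchar(seq))
}

#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly multi-record, possibly line-wrapped) FASTA file. The
#' record `id` is the first whitespace-delimited token of the header; the
#' full header is kept as `description`. Bodies are normalised through
#' [parse_sequence()].
#'
#' @param path Path to a FASTA file.
#' @param unknown Unknown-residue policy, see [parse_sequence()].
#' @return A tibble with one row per record: `id`, `description`, `seq`,
#'   `length`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">toy example", "MDVF", "MK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, unknown = c("strict", "mask")) {
  unknown <- arg_match(unknown)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0) {
    abort(sprintf("Not a FASTA file (no '>' headers): %s", path))
  }
  ends <- c(headers[-1] - 1L, length(lines))
  purrr::map2_dfr(headers, ends, function(h, e) {
    desc <- sub("^>\\s*", "", lines[h])
    id <- strsplit(desc, "\\s+")[[1]][1]
    if (e < h + 1L) {
      abort(sprintf("FASTA record '%s' has an empty body.", id))
    }
    body <- paste(lines[(h + 1L):e], collapse = "")
    res <- parse_sequence(body, id = id, unknown = unknown)
    res$description <- desc
    res[, c("id", "description", "seq", "length")]
  })
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with `id` and `seq` columns (a `description` column,
#'   if present, is used as the header), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  x <- as_protein_tbl(x)
  hdr <- if ("description" %in% names(x) && !all(is.na(x$description))) {
    ifelse(is.na(x$description), x$id, x$description)
  } else {
    x$id
  }
  out <- purrr::map2(hdr, x$seq, function(h, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(out), path)
  invisible(path)
}

#' Fetch a protein sequence from UniProt
#'
#' Downloads the FASTA record for a UniProt accession. Network access is
#' off by default so that all core analyses work fully offline; pass
#' `network = TRUE` to allow the request.
#'
#' @param accession UniProt accession (e.g. `"P37840"`).
#' @param network Must be `TRUE` to permit the HTTP request.
#' @param unknown Unknown-residue policy, see [parse_sequence()].
#' @return A one-row tibble as from [read_fasta()].
#' @export
fetch_uniprot <- function(accession, network = FALSE,
                          unknown = c("strict", "mask")) {
  unknown <- arg_match(unknown)
  if (!grepl("^[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2}$|^[OPQ][0-9][A-Z0-9]{3}[0-9]$",
             accession)) {
    abort(sprintf("'%s' is not a valid UniProt accession.", accession))
  }
  if (!isTRUE(network)) {
    abort("Network access is disabled; call with network = TRUE to fetch from UniProt.")
  }
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", accession)
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  status <- tryCatch(
    utils::download.file(url, tmp, quiet = TRUE, mode = "wb"),
    error = function(e) abort(sprintf("UniProt retrieval failed for %s: %s",
                                      accession, conditionMessage(e)))
  )
  if (!identical(status, 0L) && !identical(status, 0)) {
    abort(sprintf("UniProt retrieval failed for %s (status %s).", accession, status))
  }
  read_fasta(tmp, unknown = unknown)
}

#' Coerce sequence input to the canonical tibble form
#'
#' Accepts a character vector of sequences (optionally named), a one-row
#' result of [parse_sequence()], or any data frame with `id` and `seq`
#' columns, and returns a validated tibble with `id`, `seq`, `length`.
#'
#' @param x Sequence input.
#' @param unknown Unknown-residue policy, see [parse_sequence()].
#' @return A tibble with columns `id`, `seq`, `length` (plus
#'   `description` when present in the input).
#' @export
as_protein_tbl <- function(x, unknown = c("strict", "mask")) {
  unknown <- arg_match(unknown)
  if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x))) {
      abort("Data-frame input must have `id` and `seq` columns.")
    }
    # tibbles are the canonical parsed form, so the mask sentinel is legal
    # here even under the strict policy for raw strings
    parsed <- purrr::map2_dfr(x$seq, x$id, parse_sequence, unknown = unknown,
                              allow_sentinel = TRUE)
    if ("description" %in% names(x)) parsed$description <- x$description
    return(parsed)
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) {
      ids <- if (length(x) == 1L) "seq" else paste0("seq", seq_along(x))
    }
    return(purrr::map2_dfr(x, ids, parse_sequence, unknown = unknown))
  }
  abort("Sequence input must be a character vector or a data frame with `id` and `seq`.")
}

# split a sequence string into its residue vector
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]
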