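#' Lay out per-residue values as a sequence map
#'
#' Arranges one value per residue (discrete labels or continuous numbers)
#' on a row-major grid — left to right, top to bottom, the last row
#' possibly partial — so a whole protein can be read like a block of
#' text. Cell `position` (1-based) relates to the grid by
#' `position = (row - 1) * n_columns + column`. Optional annotations mark
#' position ranges (point mutations, domains, conserved residues).
#'
#' @param x A single sequence (string or one-row `id`/`seq` tibble).
#' @param values Vector of per-residue values, same length as the
#'   sequence. Defaults to the residues themselves.
#' @param n_columns Number of grid columns. Default `min(length, 30)`.
#' @param annotations Optional tibble/data frame with columns `start`,
#'   `end`, `text` (1-based inclusive ranges), or a path to a
#'   `start<TAB>end<TAB>text` file.
#' @return An object of class `sequence_map`: a tibble with columns
#'   `position`, `row`, `column`, `residue`, `value`, carrying
#'   `n_columns`, `id` and `annotations` attributes. [autoplot()] renders
#'   the grid.
#' @examples
#' sequence_map("MDVFMKGLSK", n_columns = 5)
#' @export
sequence_map <- function(x, values = NULL, n_columns = NULL, annotations = NULL) {
  tbl <- as_protein_tbl(x)
  if (nrow(tbl) != 1L) abort("`sequence_map()` lays out a single sequence.")
  n <- tbl$length
  chars <- seq_chars(tbl$seq)
  if (is.null(values)) values <- chars
  if (length(values) != n) {
    abort(sprintf("`values` has length %d but the sequence has %d residues.",
                  length(values), n))
  }
  if (is.null(n_columns)) n_columns <- min(n, 30L)
  if (!is.numeric(n_columns) || length(n_columns) != 1L || n_columns < 1 ||
      n_columns != as.integer(n_columns)) {
    abort("`n_columns` must be a positive integer.")
  }
  n_columns <- as.integer(n_columns)
  ann <- resolve_annotations(annotations, n)

  pos <- seq_len(n)
  out <- tibble(
    position = pos,
    row = (pos - 1L) %/% n_columns + 1L,
    column = (pos - 1L) %% n_columns + 1L,
    residue = chars,
    value = values
  )
  structure(out, class = c("sequence_map", class(out)),
            n_columns = n_columns, id = tbl$id, annotations = ann)
}

resolve_annotations <- function(annotations, n) {
  if (is.null(annotations)) return(NULL)
  if (is.character(annotations) && length(annotations) == 1L) {
    if (!file.exists(annotations)) abort(sprintf("File not found: %s", annotations))
    lines <- trimws(readLines(annotations, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t")
    if (any(lengths(parts) != 3L)) {
      abort("Annotation files need three tab-separated fields: start, end, text.")
    }
    annotations <- tibble(
      start = as.integer(vapply(parts, `[[`, "", 1L)),
      end = as.integer(vapply(parts, `[[`, "", 2L)),
      text = vapply(parts, `[[`, "", 3L)
    )
  }
  if (!is.data.frame(annotations) ||
      !all(c("start", "end", "text") %in% names(annotations))) {
    abort("`annotations` needs `start`, `end` and `text` columns.")
  }
  annotations <- as_tibble(annotations)
  bad <- annotations$start < 1 | annotations$end > n |
    annotations$start > annotations$end
  if (any(bad)) {
    abort(sprintf("Annotation range [%s, %s] is outside 1..%d.",
                  annotations$start[which(bad)[1]],
                  annotations$end[which(bad)[1]], n))
  }
  annotations
}

#' Flatten a sequence map back to its inputs
#'
#' Reads cells in (row, column) order and returns the residue string and
#' value vector; the layout is lossless, so this inverts
#' [sequence_map()].
#'
#' @param map A `sequence_map`.
#' @return A list with elements `seq` (string) and `values` (vector).
#' @export
map_flatten <- function(map) {
  if (!inherits(map, "sequence_map")) abort("`map` must be a sequence_map.")
  ord <- order(map$row, map$column)
  list(seq = paste(map$residue[ord], collapse = ""), values = map$value[ord])
}

#' @export
print.sequence_map <- function(x, ...) {
  cat(sprintf("Sequence map of '%s' (%d residues, %d columns)\n",
              attr(x, "id"), nrow(x), attr(x, "n_columns")))
  NextMethod()
}
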