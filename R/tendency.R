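TENDENCY_CLASSES <- c("disorder-promoting", "order-promoting", "disorder-neutral")

#' Structural-tendency scheme
#'
#' Partition of the 20 standard residues into disorder-promoting,
#' order-promoting and disorder-neutral classes. The default follows the
#' classic enrichment analysis of disordered versus ordered proteins:
#' disorder-promoting P, E, S, Q, K, A, G; order-promoting M, N, V, H, L,
#' F, Y, I, W, C; disorder-neutral D, T, R. Alternative published
#' definitions can be supplied as a tibble with the same columns or
#' loaded from a `residue<TAB>class` file via [read_tendency_scheme()];
#' any scheme must assign every standard residue to exactly one class.
#'
#' @return A tibble with columns `residue` and `class`.
#' @examples
#' tendency_scheme()
#' @export
tendency_scheme <- function() {
  tibble(
    residue = c(
      "P", "E", "S", "Q", "K", "A", "G",
      "M", "N", "V", "H", "L", "F", "Y", "I", "W", "C",
      "D", "T", "R"
    ),
    class = rep(TENDENCY_CLASSES, times = c(7L, 10L, 3L))
  )
}

validate_scheme <- function(scheme) {
  if (!is.data.frame(scheme) || !all(c("residue", "class") %in% names(scheme))) {
    abort("A tendency scheme needs `residue` and `class` columns.")
  }
  scheme$residue <- toupper(scheme$residue)
  if (anyDuplicated(scheme$residue)) {
    dup <- scheme$residue[duplicated(scheme$residue)][1]
    abort(sprintf("Residue '%s' appears in more than one class; classes must be disjoint.", dup))
  }
  missing <- setdiff(AA_STANDARD, scheme$residue)
  extra <- setdiff(scheme$residue, AA_STANDARD)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(sprintf(
      "Scheme must cover exactly the 20 standard residues (missing: %s; extra: %s).",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")
    ))
  }
  bad <- setdiff(unique(scheme$class), TENDENCY_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown class label(s): %s. Use %s.",
                  paste(bad, collapse = ", "), paste(TENDENCY_CLASSES, collapse = ", ")))
  }
  scheme
}

#' Read a tendency scheme from a TSV file
#'
#' One `residue<TAB>class` pair per line (`#` comments allowed); class is
#' one of `disorder-promoting`, `order-promoting`, `disorder-neutral`.
#'
#' @param path Path to the file.
#' @return A validated scheme tibble.
#' @export
read_tendency_scheme <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t ]+")
  if (any(lengths(parts) != 2L)) abort(sprintf("Malformed scheme file %s.", path))
  validate_scheme(tibble(
    residue = vapply(parts, `[[`, "", 1L),
    class = vapply(parts, `[[`, "", 2L)
  ))
}

#' Classify residues by structural tendency
#'
#' @param residues Character vector of one-letter residue codes.
#' @param scheme A scheme tibble; `NULL` uses [tendency_scheme()].
#' @return Character vector of class labels; the mask sentinel `X`
#'   returns `NA`.
#' @examples
#' classify_residue(c("P", "W", "R"))
#' @export
classify_residue <- function(residues, scheme = NULL) {
  scheme <- validate_scheme(scheme %||% tendency_scheme())
  residues <- toupper(residues)
  bad <- setdiff(unique(residues), c(AA_STANDARD, AA_MASK))
  if (length(bad) > 0) {
    abort(sprintf("Unknown residue code(s): %s.", paste(bad, collapse = ", ")))
  }
  lk <- setNames(scheme$class, scheme$residue)
  out <- unname(lk[residues])
  out[residues == AA_MASK] <- NA_character_
  out
}

#' Per-position structural-tendency profile
#'
#' @inheritParams classify_residue
#' @param x Sequence input (string, named vector, or `id`/`seq` tibble).
#' @return A tibble with columns `id`, `position`, `residue`, `class`.
#' @examples
#' tendency_profile("PWDE")
#' @export
tendency_profile <- function(x, scheme = NULL) {
  tbl <- as_protein_tbl(x)
  scheme <- validate_scheme(scheme %||% tendency_scheme())
  purrr::pmap_dfr(tbl, function(id, seq, length, ...) {
    chars <- seq_chars(seq)
    tibble(
      id = id,
      position = seq_len(length),
      residue = chars,
      class = classify_residue(chars, scheme)
    )
  })
}

#' Residue and tendency-class composition of a sequence
#'
#' Counts and fractions per residue and per tendency class, optionally
#' with enrichment against a user-supplied reference composition:
#' `enrichment = (fraction - reference) / reference`. No reference is
#' shipped as authoritative — pass a named numeric vector over the 20
#' standard residues (positive, summing to 1), or
#' `reference = "uniform"` for an explicit 1/20-each baseline.
#'
#' @inheritParams tendency_profile
#' @param reference Optional reference composition: named numeric vector
#'   or `"uniform"`.
#' @return An object of class `composition_summary`: a list with tibbles
#'   `residues` (`id`, `residue`, `class`, `count`, `fraction`, and
#'   `enrichment` when a reference is given) and `classes` (`id`,
#'   `class`, `count`, `fraction`). [tidy()] returns `residues`.
#' @examples
#' composition_summary("PPEE")
#' @export
composition_summary <- function(x, scheme = NULL, reference = NULL) {
  tbl <- as_protein_tbl(x)
  scheme <- validate_scheme(scheme %||% tendency_scheme())
  ref <- resolve_reference(reference)

  prof <- tendency_profile(tbl, scheme) |> filter(!is.na(.data$class))
  residues <- prof |>
    dplyr::count(.data$id, .data$residue, name = "count") |>
    tidyr::complete(id = unique(prof$id),
                    residue = AA_STANDARD, fill = list(count = 0L)) |>
    left_join(scheme, by = "residue") |>
    group_by(.data$id) |>
    mutate(fraction = .data$count / sum(.data$count)) |>
    ungroup() |>
    select("id", "residue", "class", "count", "fraction") |>
    arrange(match(.data$id, tbl$id), match(.data$residue, AA_STANDARD))
  if (!is.null(ref)) {
    residues <- mutate(residues,
                       enrichment = (.data$fraction - ref[.data$residue]) / ref[.data$residue])
  }
  classes <- residues |>
    group_by(.data$id, .data$class) |>
    summarise(count = sum(.data$count), fraction = sum(.data$fraction),
              .groups = "drop") |>
    tidyr::complete(id = unique(residues$id), class = TENDENCY_CLASSES,
                    fill = list(count = 0L, fraction = 0)) |>
    arrange(match(.data$id, tbl$id), match(.data$class, TENDENCY_CLASSES))

  structure(list(residues = residues, classes = classes),
            class = "composition_summary")
}

resolve_reference <- function(reference) {
  if (is.null(reference)) return(NULL)
  if (identical(reference, "uniform")) {
    return(setNames(rep(1 / 20, 20), AA_STANDARD))
  }
  if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
    reference <- read_kv_file(reference)
  }
  if (!is.numeric(reference) || is.null(names(reference))) {
    abort("`reference` must be 'uniform', a file path, or a named numeric vector.")
  }
  names(reference) <- toupper(names(reference))
  missing <- setdiff(AA_STANDARD, names(reference))
  if (length(missing) > 0) {
    abort(sprintf("Reference composition missing residue(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  reference <- reference[AA_STANDARD]
  if (any(reference <= 0)) abort("Reference fractions must all be positive.")
  if (abs(sum(reference) - 1) > 1e-6) {
    abort("Reference fractions must sum to 1.")
  }
  reference
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Residue composition by structural tendency\n")
  print(x$classes, ...)
  invisible(x)
}

#' @rdname composition_summary
#' @param x A `composition_summary`.
#' @param ... Unused.
#' @method tidy composition_summary
#' @export
tidy.composition_summary <- function(x, ...) x$residues

#' @rdname composition_summary
#' @method glance composition_summary
#' @export
glance.composition_summary <- function(x, ...) {
  x$classes |>
    select(!"count") |>
    tidyr::pivot_wider(names_from = "class", values_from = "fraction")
}
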