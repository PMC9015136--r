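# Kyte & Doolittle hydropathy index (raw, range -4.5 .. 4.5)
KD_RAW <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Scaled Kyte-Doolittle hydropathy scale
#'
#' The Kyte-Doolittle hydropathy index rescaled linearly onto \[0, 1\] so
#' that Arg (the most hydrophilic residue, raw -4.5) is exactly 0.0 and
#' Ile (the most hydrophobic, raw +4.5) is exactly 1.0:
#' `scaled = (raw + 4.5) / 9`. Alternative scales load from TSV files via
#' [read_hydropathy_scale()] and may be passed wherever a scale is
#' accepted.
#'
#' @return A tibble with columns `residue` and `value` (in \[0, 1\]),
#'   carrying a `name` attribute.
#' @examples
#' hydropathy_scale()
#' @export
hydropathy_scale <- function() {
  out <- tibble(residue = names(KD_RAW), value = (unname(KD_RAW) + 4.5) / 9)
  attr(out, "name") <- "Kyte-Doolittle (scaled)"
  out
}

#' Read a hydropathy scale from a TSV file
#'
#' One `residue<TAB>value` pair per line, `#` comments allowed; all 20
#' standard residues must be present and all values must lie in \[0, 1\].
#'
#' @param path Path to the file.
#' @param name Name to attach; defaults to the file name.
#' @return A scale tibble as from [hydropathy_scale()].
#' @export
read_hydropathy_scale <- function(path, name = NULL) {
  kv <- read_kv_file(path)
  missing <- setdiff(AA_STANDARD, names(kv))
  if (length(missing) > 0) {
    abort(sprintf("Scale is missing residue(s): %s.", paste(missing, collapse = ", ")))
  }
  if (any(kv < 0 | kv > 1)) abort("Scaled hydropathy values must lie in [0, 1].")
  out <- tibble(residue = names(kv), value = unname(kv))
  attr(out, "name") <- name %||% sub("\\.[^.]*$", "", basename(path))
  out
}

resolve_scale <- function(scale) {
  if (is.null(scale)) return(hydropathy_scale())
  if (!is.data.frame(scale) || !all(c("residue", "value") %in% names(scale))) {
    abort("A hydropathy scale needs `residue` and `value` columns.")
  }
  scale
}

#' Scaled hydropathy of single residues
#'
#' @param residues Character vector of one-letter residue codes.
#' @param scale A scale tibble; `NULL` (default) uses the scaled
#'   Kyte-Doolittle scale.
#' @return Numeric vector of values in \[0, 1\]; the mask sentinel `X`
#'   returns `NA`.
#' @examples
#' scaled_hydropathy(c("R", "I", "E"))
#' @export
scaled_hydropathy <- function(residues, scale = NULL) {
  scale <- resolve_scale(scale)
  residues <- toupper(residues)
  vals <- setNames(scale$value, scale$residue)
  bad <- setdiff(unique(residues), c(names(vals), AA_MASK))
  if (length(bad) > 0) {
    abort(sprintf("Unknown residue code(s): %s.", paste(bad, collapse = ", ")))
  }
  out <- unname(vals[residues])
  out[residues == AA_MASK] <- NA_real_
  out
}

#' Mean scaled hydropathy of sequences
#'
#' Arithmetic mean of the per-residue scaled hydropathy values (masked
#' positions excluded). On the default scale this is the x-coordinate of
#' the charge-hydropathy plot.
#'
#' @inheritParams scaled_hydropathy
#' @param x Sequence input (string, named vector, or `id`/`seq` tibble).
#' @return A tibble with columns `id`, `length`, `mean_hydropathy`.
#' @examples
#' mean_scaled_hydropathy("RI")
#' @export
mean_scaled_hydropathy <- function(x, scale = NULL) {
  tbl <- as_protein_tbl(x)
  scale <- resolve_scale(scale)
  purrr::pmap_dfr(tbl, function(id, seq, length, ...) {
    h <- scaled_hydropathy(seq_chars(seq), scale)
    tibble(id = id, length = length, mean_hydropathy = mean(h, na.rm = TRUE))
  })
}

#' Local (sliding-window) hydropathy profile
#'
#' Mean scaled hydropathy over an odd-width sliding window reported at
#' the center position; same full-window semantics as [local_charge()].
#'
#' @inheritParams mean_scaled_hydropathy
#' @param window Odd window width, at most the sequence length. Default 9.
#' @return A tibble with columns `id`, `position`, `residue`, `window`,
#'   `hydropathy`.
#' @examples
#' local_hydropathy("RRRRIIIII", window = 3)
#' @export
local_hydropathy <- function(x, window = 9, scale = NULL) {
  tbl <- as_protein_tbl(x)
  scale <- resolve_scale(scale)
  per <- purrr::pmap_dfr(tbl, function(id, seq, length, ...) {
    chars <- seq_chars(seq)
    tibble(
      id = id,
      position = seq_len(length),
      residue = chars,
      hydropathy = scaled_hydropathy(chars, scale)
    )
  })
  windowed_profile(per, "hydropathy", window)
}
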