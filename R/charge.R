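#' Fractional charge of single residues
#'
#' Henderson-Hasselbalch fractional charge of each residue at a given pH.
#' Acidic groups carry `-1 / (1 + 10^(pKa - pH))`, basic groups
#' `+1 / (1 + 10^(pH - pKa))`; non-ionizable residues are exactly 0. At
#' `pH == pKa` a group is half-ionized (charge -0.5 or +0.5). The mask
#' sentinel `X` returns `NA`.
#'
#' @param residues Character vector of one-letter residue codes (or the
#'   terminal group names `"NTERM"`/`"CTERM"`).
#' @param ph pH, in (0, 14). Default 7.0.
#' @param pka A pKa set tibble ([pka_set()]) or the name of a built-in set.
#' @return Numeric vector of fractional charges in \[-1, 1\].
#' @examples
#' residue_charge(c("G", "E", "K"), ph = 7)
#' @export
residue_charge <- function(residues, ph = 7.0, pka = pka_set()) {
  pka <- resolve_pka(pka)
  if (!is.numeric(ph) || length(ph) != 1L || ph <= 0 || ph >= 14) {
    abort("`ph` must be a single value in (0, 14).")
  }
  residues <- toupper(residues)
  known <- c(AA_STANDARD, AA_MASK, "NTERM", "CTERM")
  bad <- setdiff(unique(residues), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown residue code(s): %s.", paste(bad, collapse = ", ")))
  }
  pkas <- setNames(pka$pka, pka$group)
  pols <- setNames(pka$polarity, pka$group)
  out <- numeric(length(residues))
  out[residues == AA_MASK] <- NA_real_
  ion <- residues %in% names(pkas)
  if (any(ion)) {
    r <- residues[ion]
    q <- ifelse(
      pols[r] == "acid",
      -1 / (1 + 10^(pkas[r] - ph)),
      +1 / (1 + 10^(ph - pkas[r]))
    )
    out[ion] <- unname(q)
  }
  out
}

resolve_pka <- function(pka) {
  if (is.character(pka) && length(pka) == 1L) return(pka_set(pka))
  validate_pka_set(pka)
}

resolve_id_col <- function(values, tbl) {
  rep(tbl$id, tbl$length)
}

#' Per-residue charges of a sequence
#'
#' @inheritParams residue_charge
#' @param x Sequence input: a character string/vector or a tibble with
#'   `id` and `seq` columns (see [as_protein_tbl()]).
#' @return A tibble with columns `id`, `position` (1-based), `residue`,
#'   `charge`.
#' @export
sequence_charge <- function(x, ph = 7.0, pka = pka_set()) {
  tbl <- as_protein_tbl(x)
  pka <- resolve_pka(pka)
  purrr::pmap_dfr(tbl, function(id, seq, length, ...) {
    chars <- seq_chars(seq)
    tibble(
      id = id,
      position = seq_len(length),
      residue = chars,
      charge = residue_charge(chars, ph = ph, pka = pka)
    )
  })
}

#' Net charge and mean net charge per residue
#'
#' Sums Henderson-Hasselbalch fractional charges over the sequence, by
#' default including the free N- and C-terminal groups. The mean net
#' charge divides by the number of residues (termini are extra groups,
#' not extra residues). Masked (`X`) positions contribute nothing and are
#' excluded from the residue count used for the mean.
#'
#' @inheritParams sequence_charge
#' @param include_termini Add the terminal group charges? Default `TRUE`.
#' @return A tibble with one row per sequence: `id`, `length`,
#'   `net_charge`, `mean_net_charge`, `ph`, `pka_set`.
#' @examples
#' net_charge("EEEE", include_termini = FALSE)
#' @export
net_charge <- function(x, ph = 7.0, pka = pka_set(), include_termini = TRUE) {
  tbl <- as_protein_tbl(x)
  pka <- resolve_pka(pka)
  per <- sequence_charge(tbl, ph = ph, pka = pka)
  term <- if (include_termini) {
    sum(residue_charge(c("NTERM", "CTERM"), ph = ph, pka = pka))
  } else {
    0
  }
  per |>
    group_by(.data$id) |>
    summarise(
      length = dplyr::n(),
      n_known = sum(!is.na(.data$charge)),
      net_charge = sum(.data$charge, na.rm = TRUE) + term,
      .groups = "drop"
    ) |>
    mutate(
      mean_net_charge = .data$net_charge / .data$n_known,
      ph = ph,
      pka_set = attr(pka, "name") %||% "custom"
    ) |>
    select(!"n_known") |>
    arrange(match(.data$id, tbl$id))
}

#' Local (sliding-window) charge profile
#'
#' Mean fractional charge over an odd-width sliding window, reported at
#' the window's center position. Only full windows are reported, so the
#' first and last `(window - 1) / 2` positions carry no value; terminal
#' group charges are never included (a window's ends are not free
#' termini).
#'
#' @inheritParams sequence_charge
#' @param window Odd window width, at most the sequence length. Default 9.
#' @return A tibble with columns `id`, `position` (window center),
#'   `residue` (at the center), `charge` (window mean), and a `window`
#'   attribute-free `window` column.
#' @examples
#' local_charge("EEEEKKKKK", window = 3)
#' @export
local_charge <- function(x, window = 9, ph = 7.0, pka = pka_set()) {
  per <- sequence_charge(x, ph = ph, pka = pka)
  windowed_profile(per, "charge", window)
}

# shared sliding-window mean over a per-residue tibble (id, position,
# residue, <col>); masked NA positions are averaged out of their windows
windowed_profile <- function(per, col, window) {
  check_window(window)
  half <- (window - 1L) / 2L
  per |>
    group_by(.data$id) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (window > n) {
        abort(sprintf(
          "Window (%d) exceeds sequence length (%d) for '%s'; use a whole-sequence summary instead.",
          window, n, key$id
        ))
      }
      centers <- seq.int(half + 1L, n - half)
      vals <- rolling_mean(d[[col]], window)
      out <- tibble(
        position = centers,
        residue = d$residue[centers],
        window = as.integer(window)
      )
      out[[col]] <- vals
      out
    }) |>
    ungroup()
}

# mean over each full window, NA values excluded from their window's mean
# (all-NA window -> NA)
rolling_mean <- function(v, window) {
  n <- length(v)
  known <- !is.na(v)
  cs <- cumsum(c(0, ifelse(known, v, 0)))
  ck <- cumsum(c(0, as.numeric(known)))
  starts <- seq_len(n - window + 1L)
  tot <- cs[starts + window] - cs[starts]
  cnt <- ck[starts + window] - ck[starts]
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != as.integer(window)) {
    abort("`window` must be a positive integer.")
  }
  if (window %% 2 == 0) {
    abort(sprintf("`window` must be odd (got %d).", as.integer(window)))
  }
  invisible(as.integer(window))
}
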