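CH_SLOPE <- 2.785
CH_INTERCEPT <- 1.151
CH_INSOLUBLE <- 0.7

#' Charge-hydropathy (Uversky) classification
#'
#' Classifies a protein by its position in the charge-hydropathy plane.
#' With `h` the mean scaled hydropathy and `q` the mean net charge per
#' residue, the boundary between extended (disordered) and collapsed
#' (compact) proteins is the pair of lines `q = +-(2.785 h - 1.151)`:
#' points with `|q| > 2.785 h - 1.151` are called
#' `"extended/disordered"`, otherwise `"collapsed/compact"`. Sequences
#' with `h >= 0.7` are called `"insoluble"` regardless of charge (the
#' insolubility rule overrides the boundary). Points exactly on the
#' boundary are collapsed (strict inequality for extended).
#'
#' @param mean_hydropathy Mean scaled hydropathy, in \[0, 1\]. Vectorised.
#' @param mean_net_charge Mean net charge per residue. Vectorised.
#' @return Character vector with values in `"extended/disordered"`,
#'   `"collapsed/compact"`, `"insoluble"`.
#' @examples
#' classify_charge_hydropathy(c(0.0, 0.5, 0.8), c(0.0, 0.10, 0.0))
#' @export
classify_charge_hydropathy <- function(mean_hydropathy, mean_net_charge) {
  if (any(mean_hydropathy < 0 | mean_hydropathy > 1, na.rm = TRUE)) {
    abort("`mean_hydropathy` must lie in [0, 1].")
  }
  boundary <- CH_SLOPE * mean_hydropathy - CH_INTERCEPT
  dplyr::case_when(
    mean_hydropathy >= CH_INSOLUBLE ~ "insoluble",
    abs(mean_net_charge) > boundary ~ "extended/disordered",
    .default = "collapsed/compact"
  )
}

#' Charge-hydropathy point and label for whole sequences
#'
#' Computes the two whole-sequence coordinates — mean scaled hydropathy
#' ([mean_scaled_hydropathy()]) and mean net charge per residue
#' ([net_charge()]) — and applies [classify_charge_hydropathy()].
#'
#' @inheritParams net_charge
#' @param scale Hydropathy scale tibble, `NULL` for scaled Kyte-Doolittle.
#' @return A tibble with one row per sequence: `id`, `length`,
#'   `mean_hydropathy`, `mean_net_charge`, `label`, `ph`.
#' @examples
#' charge_hydropathy(c(aSynLike = "MDVFMKGLSKAKEGVVAAAE"))
#' @export
charge_hydropathy <- function(x, ph = 7.0, pka = pka_set(), scale = NULL,
                              include_termini = TRUE) {
  tbl <- as_protein_tbl(x)
  h <- mean_scaled_hydropathy(tbl, scale)
  q <- net_charge(tbl, ph = ph, pka = pka, include_termini = include_termini)
  h |>
    left_join(select(q, "id", "mean_net_charge"), by = "id") |>
    mutate(
      label = classify_charge_hydropathy(.data$mean_hydropathy, .data$mean_net_charge),
      ph = ph
    )
}

#' FoldIndex disorder prediction
#'
#' FoldIndex folds the charge-hydropathy boundary into a per-window
#' score: for each odd-width window (51 residues by default) the score is
#' `2.785 * h_w - |q_w| - 1.151`, where `h_w` is the window's mean scaled
#' hydropathy and `q_w` its mean net charge per residue (terminal groups
#' excluded — a window's ends are not free termini). A negative score
#' predicts the window's center residue disordered; a positive score
#' predicts it ordered (an exact 0, a measure-zero boundary, is called
#' ordered). Scores range over roughly \[-1.151, 1.634\].
#'
#' Only positions with a full window are reported. A sequence shorter
#' than the window is scored as a single whole-sequence window reported
#' at its central position, with `whole_sequence = TRUE` in the summary.
#' Maximal runs of identical calls are returned as regions with 1-based
#' inclusive coordinates.
#'
#' @inheritParams charge_hydropathy
#' @param window Odd window width. Default 51.
#' @return An object of class `foldindex_result`: a list with
#'   \describe{
#'     \item{scores}{tibble `id`, `position`, `residue`, `hydropathy`,
#'       `charge`, `score`, `call` (`"disordered"`/`"ordered"`)}
#'     \item{regions}{tibble `id`, `start`, `end`, `call` (1-based
#'       inclusive, spanning the reported positions)}
#'     \item{params}{list: `window`, `ph`, `pka_set`, `scale`}
#'     \item{sequences}{tibble `id`, `length`, `whole_sequence`}
#'   }
#'   [tidy()] returns `scores`, [glance()] a one-row-per-sequence
#'   summary, [autoplot()] the score profile.
#' @examples
#' fi <- foldindex(strrep("I", 60))
#' glance(fi)
#' @export
foldindex <- function(x, window = 51, ph = 7.0, pka = pka_set(), scale = NULL) {
  check_window(window)
  tbl <- as_protein_tbl(x)
  pka <- resolve_pka(pka)
  scale <- resolve_scale(scale)

  one <- function(id, seq, length, ...) {
    chars <- seq_chars(seq)
    h <- scaled_hydropathy(chars, scale)
    q <- residue_charge(chars, ph = ph, pka = pka)
    whole <- window > length
    w <- if (whole) length else as.integer(window)
    half <- (w - 1L) %/% 2L
    centers <- if (whole) as.integer(ceiling(length / 2)) else seq.int(half + 1L, length - half)
    hw <- rolling_mean(h, w)
    qw <- rolling_mean(q, w)
    scores <- tibble(
      id = id,
      position = centers,
      residue = chars[centers],
      hydropathy = hw,
      charge = qw,
      score = CH_SLOPE * hw - abs(qw) - CH_INTERCEPT,
      call = ifelse(CH_SLOPE * hw - abs(qw) - CH_INTERCEPT < 0, "disordered", "ordered")
    )
    list(scores = scores,
         meta = tibble(id = id, length = length, whole_sequence = whole))
  }

  parts <- purrr::pmap(tbl, one)
  scores <- purrr::map_dfr(parts, "scores")
  meta <- purrr::map_dfr(parts, "meta")

  structure(
    list(
      scores = scores,
      regions = call_regions(scores),
      params = list(
        window = as.integer(window), ph = ph,
        pka_set = attr(pka, "name") %||% "custom",
        scale = attr(scale, "name") %||% "custom"
      ),
      sequences = meta
    ),
    class = "foldindex_result"
  )
}

# maximal runs of identical calls over the reported positions
call_regions <- function(scores) {
  scores |>
    group_by(.data$id) |>
    dplyr::group_modify(function(d, key) {
      r <- rle(d$call)
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1L) + 1L)
      tibble(
        start = d$position[starts],
        end = d$position[ends],
        call = r$values
      )
    }) |>
    ungroup()
}

#' @export
print.foldindex_result <- function(x, ...) {
  cat(sprintf(
    "FoldIndex prediction (window %d, pH %.1f, pKa set %s)\n",
    x$params$window, x$params$ph, x$params$pka_set
  ))
  g <- glance(x)
  print(g, ...)
  invisible(x)
}

#' @rdname foldindex
#' @param x A `foldindex_result`.
#' @param ... Unused.
#' @method tidy foldindex_result
#' @export
tidy.foldindex_result <- function(x, ...) x$scores

#' @rdname foldindex
#' @method glance foldindex_result
#' @export
glance.foldindex_result <- function(x, ...) {
  x$scores |>
    group_by(.data$id) |>
    summarise(
      n_windows = dplyr::n(),
      mean_score = mean(.data$score),
      min_score = min(.data$score),
      max_score = max(.data$score),
      frac_disordered = mean(.data$call == "disordered"),
      .groups = "drop"
    ) |>
    left_join(x$sequences, by = "id") |>
    select("id", "length", "whole_sequence", dplyr::everything())
}
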