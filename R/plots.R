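# figure defaults: disorder green, order purple, neutral pink
TENDENCY_COLOURS <- c(
  "disorder-promoting" = "#2E7D32",
  "order-promoting" = "#6A1B9A",
  "disorder-neutral" = "#D81B60"
)

#' Charge-hydropathy plot
#'
#' Scatter of mean net charge per residue against mean scaled hydropathy
#' with the two boundary lines `q = +-(2.785 h - 1.151)` and the
#' insolubility line `h = 0.7`.
#'
#' @param ch A tibble from [charge_hydropathy()] (or [tidy()] of a
#'   [disorder_profile()]).
#' @return A ggplot object.
#' @export
plot_charge_hydropathy <- function(ch) {
  hgrid <- seq(CH_INTERCEPT / CH_SLOPE, 1, length.out = 100)
  bound <- tibble(h = rep(hgrid, 2),
                  q = c(CH_SLOPE * hgrid - CH_INTERCEPT,
                        -(CH_SLOPE * hgrid - CH_INTERCEPT)),
                  side = rep(c("+", "-"), each = 100))
  ggplot2::ggplot(ch, ggplot2::aes(x = .data$mean_hydropathy,
                                   y = .data$mean_net_charge)) +
    ggplot2::geom_line(data = bound,
                       ggplot2::aes(x = .data$h, y = .data$q, group = .data$side),
                       linetype = 2, colour = "grey40", inherit.aes = FALSE) +
    ggplot2::geom_vline(xintercept = CH_INSOLUBLE, linetype = 3, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "Mean scaled hydropathy", y = "Mean net charge per residue",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Local profile line plot
#'
#' @param profile A tibble from [local_charge()] or [local_hydropathy()].
#' @param value Name of the value column (`"charge"` or `"hydropathy"`);
#'   guessed when omitted.
#' @return A ggplot object.
#' @export
plot_local_profile <- function(profile, value = NULL) {
  value <- value %||% intersect(c("charge", "hydropathy", "score"), names(profile))[1]
  if (is.na(value)) abort("No profile value column found.")
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data[[value]],
                                        colour = .data$id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Position", y = paste("Windowed", value), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Structural tendency bar plot
#'
#' @param profile A tibble from [tendency_profile()].
#' @return A ggplot object.
#' @export
plot_tendency <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = 1,
                                        fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~id, ncol = 1) +
    ggplot2::scale_fill_manual(values = TENDENCY_COLOURS, na.value = "grey70") +
    ggplot2::labs(x = "Position", y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @describeIn foldindex Score profile with the zero line; windows below
#'   zero are predicted disordered.
#' @param object A `foldindex_result` (for `autoplot`).
#' @method autoplot foldindex_result
#' @export
autoplot.foldindex_result <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_area(ggplot2::aes(fill = .data$call), alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~id, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(disordered = "#C62828",
                                          ordered = "#1565C0")) +
    ggplot2::labs(x = "Position", y = "FoldIndex score", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn sequence_map Grid rendering; discrete values map to fill
#'   colours, continuous values to a gradient; annotations are drawn as
#'   underlines.
#' @param object A `sequence_map` (for `autoplot`).
#' @param ... Unused.
#' @method autoplot sequence_map
#' @export
autoplot.sequence_map <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$column, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue), size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = attr(object, "id")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (is.character(object$value) &&
      all(unique(stats::na.omit(object$value)) %in% names(TENDENCY_COLOURS))) {
    p <- p + ggplot2::scale_fill_manual(values = TENDENCY_COLOURS, na.value = "grey70")
  }
  ann <- attr(object, "annotations")
  if (!is.null(ann) && nrow(ann) > 0) {
    nc <- attr(object, "n_columns")
    marks <- purrr::pmap_dfr(ann, function(start, end, text) {
      pos <- start:end
      tibble(column = (pos - 1L) %% nc + 1L,
             row = (pos - 1L) %/% nc + 1L, text = text)
    })
    p <- p + ggplot2::geom_point(
      data = marks, shape = 95, size = 4, inherit.aes = FALSE,
      mapping = ggplot2::aes(x = .data$column, y = .data$row + 0.45)
    )
  }
  p
}

#' @describeIn composition_summary Residue-fraction bar plot coloured by
#'   tendency class (enrichment bars when a reference was supplied).
#' @param object A `composition_summary` (for `autoplot`).
#' @method autoplot composition_summary
#' @export
autoplot.composition_summary <- function(object, ...) {
  d <- object$residues
  yvar <- if ("enrichment" %in% names(d)) "enrichment" else "fraction"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data[[yvar]],
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~id, ncol = 1) +
    ggplot2::scale_fill_manual(values = TENDENCY_COLOURS) +
    ggplot2::labs(x = NULL, y = yvar, fill = NULL) +
    ggplot2::theme_minimal()
}
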