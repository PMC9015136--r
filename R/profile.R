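#' Full disorder profile of one or more sequences
#'
#' Runs every native analysis in one call — charge-hydropathy
#' classification, local charge and local hydropathy profiles,
#' structural-tendency profile and composition, and FoldIndex — with a
#' single shared parameter set, and collects the results. Each component
#' is bit-identical to calling the corresponding function directly with
#' the same parameters.
#'
#' @inheritParams charge_hydropathy
#' @param window Sliding-window width for the local charge/hydropathy
#'   profiles. Default 9.
#' @param foldindex_window Window for FoldIndex. Default 51.
#' @param scheme Tendency scheme tibble; `NULL` for the default.
#' @param reference Optional reference composition for enrichment; see
#'   [composition_summary()].
#' @return An object of class `disorder_profile`: a list with elements
#'   `sequences`, `charge_hydropathy`, `local_charge`,
#'   `local_hydropathy`, `tendency`, `composition`, `foldindex`,
#'   `params`. [glance()] gives a one-row-per-sequence overview;
#'   [tidy()] the charge-hydropathy table.
#' @examples
#' p <- disorder_profile(generate_fixture("acidic", 80, seed = 1))
#' glance(p)
#' @export
disorder_profile <- function(x, ph = 7.0, window = 9, foldindex_window = 51,
                             pka = pka_set(), scale = NULL, scheme = NULL,
                             reference = NULL, include_termini = TRUE) {
  tbl <- as_protein_tbl(x)
  pka <- resolve_pka(pka)
  scale <- resolve_scale(scale)
  scheme <- validate_scheme(scheme %||% tendency_scheme())
  check_window(window)
  check_window(foldindex_window)

  structure(
    list(
      sequences = tbl,
      charge_hydropathy = charge_hydropathy(tbl, ph = ph, pka = pka,
                                            scale = scale,
                                            include_termini = include_termini),
      local_charge = local_charge(tbl, window = window, ph = ph, pka = pka),
      local_hydropathy = local_hydropathy(tbl, window = window, scale = scale),
      tendency = tendency_profile(tbl, scheme = scheme),
      composition = composition_summary(tbl, scheme = scheme, reference = reference),
      foldindex = foldindex(tbl, window = foldindex_window, ph = ph,
                            pka = pka, scale = scale),
      params = list(
        ph = ph,
        window = as.integer(window),
        foldindex_window = as.integer(foldindex_window),
        pka_set = attr(pka, "name") %||% "custom",
        scale = attr(scale, "name") %||% "custom",
        include_termini = include_termini
      )
    ),
    class = "disorder_profile"
  )
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat(sprintf(
    "Disorder profile of %d sequence(s) (pH %.1f, window %d, FoldIndex window %d, pKa set %s)\n",
    nrow(x$sequences), x$params$ph, x$params$window,
    x$params$foldindex_window, x$params$pka_set
  ))
  print(glance(x), ...)
  invisible(x)
}

#' @rdname disorder_profile
#' @param x A `disorder_profile`.
#' @param ... Unused.
#' @method tidy disorder_profile
#' @export
tidy.disorder_profile <- function(x, ...) x$charge_hydropathy

#' @rdname disorder_profile
#' @method glance disorder_profile
#' @export
glance.disorder_profile <- function(x, ...) {
  x$charge_hydropathy |>
    select("id", "length", "mean_hydropathy", "mean_net_charge", "label") |>
    left_join(select(glance(x$foldindex), "id", "mean_score", "frac_disordered"),
              by = "id") |>
    left_join(
      x$composition$classes |>
        filter(.data$class == "disorder-promoting") |>
        select("id", frac_disorder_promoting = "fraction"),
      by = "id"
    )
}

#' Write a disorder profile to disk
#'
#' Writes per-sequence TSV tables (`charge.tsv`, `hydropathy.tsv`,
#' `tendency.tsv`, `foldindex.tsv`, `foldindex_regions.tsv`,
#' `composition.tsv`, `charge_hydropathy.tsv`) and/or a single
#' `profile.json` holding every component plus the run parameters. All
#' coordinates are 1-based inclusive.
#'
#' @param profile A `disorder_profile`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"`, `"json"`, or both.
#' @return `dir`, invisibly.
#' @export
write_profile <- function(profile, dir, format = c("tsv", "json")) {
  if (!inherits(profile, "disorder_profile")) {
    abort("`profile` must be a disorder_profile.")
  }
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if ("tsv" %in% format) {
    tsv <- function(d, f) utils::write.table(
      d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE
    )
    tsv(profile$charge_hydropathy, "charge_hydropathy.tsv")
    tsv(profile$local_charge, "charge.tsv")
    tsv(profile$local_hydropathy, "hydropathy.tsv")
    tsv(profile$tendency, "tendency.tsv")
    tsv(profile$composition$residues, "composition.tsv")
    tsv(profile$foldindex$scores, "foldindex.tsv")
    tsv(profile$foldindex$regions, "foldindex_regions.tsv")
  }
  if ("json" %in% format) {
    jsonlite::write_json(profile_to_list(profile),
                         file.path(dir, "profile.json"),
                         digits = NA, na = "null")
  }
  invisible(dir)
}

profile_to_list <- function(profile) {
  list(
    params = profile$params,
    sequences = profile$sequences,
    charge_hydropathy = profile$charge_hydropathy,
    local_charge = profile$local_charge,
    local_hydropathy = profile$local_hydropathy,
    tendency = profile$tendency,
    composition = list(residues = profile$composition$residues,
                       classes = profile$composition$classes),
    foldindex = list(scores = profile$foldindex$scores,
                     regions = profile$foldindex$regions,
                     params = profile$foldindex$params,
                     sequences = profile$foldindex$sequences)
  )
}

#' Reload a profile written as JSON
#'
#' Reconstructs a `disorder_profile` from a `profile.json` produced by
#' [write_profile()]; the reloaded tables equal the in-memory originals.
#'
#' @param path Path to the JSON file.
#' @return A `disorder_profile`.
#' @export
read_profile_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tb <- function(d) as_tibble(d)
  structure(
    list(
      sequences = tb(raw$sequences),
      charge_hydropathy = tb(raw$charge_hydropathy),
      local_charge = tb(raw$local_charge),
      local_hydropathy = tb(raw$local_hydropathy),
      tendency = tb(raw$tendency),
      composition = structure(
        list(residues = tb(raw$composition$residues),
             classes = tb(raw$composition$classes)),
        class = "composition_summary"
      ),
      foldindex = structure(
        list(scores = tb(raw$foldindex$scores),
             regions = tb(raw$foldindex$regions),
             params = raw$foldindex$params,
             sequences = tb(raw$foldindex$sequences)),
        class = "foldindex_result"
      ),
      params = raw$params
    ),
    class = "disorder_profile"
  )
}
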