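#' Built-in pKa sets
#'
#' Acid-dissociation constants for the ionizable residues (D, E, C, Y, H,
#' K, R) and the free termini, used by the Henderson-Hasselbalch charge
#' calculations. Polarity is fixed by chemistry: D, E, C, Y and the
#' C-terminus are acids (charge in \[-1, 0\]); H, K, R and the N-terminus
#' are bases (charge in \[0, +1\]).
#'
#' Two sets are built in: `"IPC_protein"` (the default throughout the
#' package; pKa values optimised for whole proteins, Kozlowski 2016) and
#' `"EMBOSS"` (the defaults of the EMBOSS `iep` tool). Further sets load
#' from TSV files via [read_pka_set()].
#'
#' @param name Name of a built-in set; see `pka_set_names()`.
#' @return A tibble with columns `group` (residue code, `"NTERM"` or
#'   `"CTERM"`), `pka`, and `polarity` (`"acid"` or `"base"`), carrying a
#'   `name` attribute.
#' @examples
#' pka_set("IPC_protein")
#' pka_set_names()
#' @export
pka_set <- function(name = "IPC_protein") {
  sets <- builtin_pka_sets()
  if (!name %in% names(sets)) {
    abort(sprintf("Unknown pKa set '%s'. Available: %s.",
                  name, paste(names(sets), collapse = ", ")))
  }
  sets[[name]]
}

#' @rdname pka_set
#' @export
pka_set_names <- function() names(builtin_pka_sets())

PKA_POLARITY <- c(
  D = "acid", E = "acid", C = "acid", Y = "acid", CTERM = "acid",
  H = "base", K = "base", R = "base", NTERM = "base"
)

make_pka_set <- function(name, values) {
  groups <- names(values)
  stopifnot(setequal(groups, names(PKA_POLARITY)))
  out <- tibble(
    group = groups,
    pka = unname(values),
    polarity = unname(PKA_POLARITY[groups])
  )
  attr(out, "name") <- name
  validate_pka_set(out)
}

builtin_pka_sets <- function() {
  list(
    # pKa set optimised against experimental protein pI values
    IPC_protein = make_pka_set("IPC_protein", c(
      D = 3.872, E = 4.412, C = 7.555, Y = 10.85,
      H = 5.637, K = 9.052, R = 11.84,
      NTERM = 9.094, CTERM = 2.869
    )),
    EMBOSS = make_pka_set("EMBOSS", c(
      D = 3.9, E = 4.1, C = 8.5, Y = 10.1,
      H = 6.5, K = 10.8, R = 12.5,
      NTERM = 8.6, CTERM = 3.6
    ))
  )
}

validate_pka_set <- function(x) {
  if (!is.data.frame(x) || !all(c("group", "pka", "polarity") %in% names(x))) {
    abort("A pKa set needs `group`, `pka` and `polarity` columns.")
  }
  missing <- setdiff(names(PKA_POLARITY), x$group)
  if (length(missing) > 0) {
    abort(sprintf("pKa set is missing group(s): %s.", paste(missing, collapse = ", ")))
  }
  if (any(x$pka <= 0 | x$pka >= 14)) {
    abort("All pKa values must lie in (0, 14).")
  }
  wrong <- x$group[x$polarity != PKA_POLARITY[x$group]]
  if (length(wrong) > 0) {
    abort(sprintf("Polarity of %s contradicts chemistry (acids: D,E,C,Y,CTERM; bases: H,K,R,NTERM).",
                  paste(wrong, collapse = ", ")))
  }
  x
}

#' Read a pKa set from a TSV file
#'
#' The file holds one `group<TAB>pKa` pair per line, where group is an
#' ionizable residue code or `NTERM`/`CTERM`; `#` lines are comments. All
#' nine ionizable groups must be present. Polarities are assigned by
#' chemistry, not by the file.
#'
#' @param path Path to the file.
#' @param name Name to attach to the set; defaults to the file name.
#' @return A pKa set tibble as from [pka_set()].
#' @export
read_pka_set <- function(path, name = NULL) {
  kv <- read_kv_file(path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  make_pka_set(name, kv)
}

# shared loader for group<TAB>value files (pKa sets, hydropathy scales,
# reference compositions)
read_kv_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    abort(sprintf("Malformed line %d in %s (expected 'key<TAB>value').", bad[1], path))
  }
  keys <- toupper(vapply(parts, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(vals)) abort(sprintf("Non-numeric value in %s.", path))
  if (anyDuplicated(keys)) abort(sprintf("Duplicate key in %s.", path))
  setNames(vals, keys)
}
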