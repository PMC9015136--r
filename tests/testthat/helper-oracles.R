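# Independent oracles used across tests. These deliberately avoid the
# package's own windowing/scoring code paths.

# Henderson-Hasselbalch fractional charge, written out directly
hh_charge <- function(residue, ph, pka_tbl) {
  row <- pka_tbl[pka_tbl$group == residue, ]
  if (nrow(row) == 0) return(0)
  if (row$polarity == "acid") -1 / (1 + 10^(row$pka - ph)) else 1 / (1 + 10^(ph - row$pka))
}

# per-residue value vectors via the oracle
oracle_charges <- function(seq, ph = 7, pka_tbl = pka_set()) {
  vapply(strsplit(seq, "")[[1]], hh_charge, 0, ph = ph, pka_tbl = pka_tbl,
         USE.NAMES = FALSE)
}

KD_TABLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

oracle_hydropathy <- function(seq) {
  unname((KD_TABLE[strsplit(seq, "")[[1]]] + 4.5) / 9)
}

# brute-force full-window means at center positions
brute_windows <- function(values, window) {
  n <- length(values)
  half <- (window - 1) / 2
  centers <- seq.int(half + 1, n - half)
  vapply(centers, function(c) mean(values[(c - half):(c + half)]), 0)
}

random_sequence <- function(n, seed) {
  withr::with_seed(seed, paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      n, replace = TRUE), collapse = ""))
}

# write a matrix in NCBI-style text (independent of the package's writer)
write_ncbi_matrix <- function(m, path) {
  codes <- rownames(m)
  lines <- c(
    "# test fixture",
    paste(" ", paste(sprintf("%3s", codes), collapse = "")),
    vapply(seq_along(codes), function(i) {
      paste0(codes[i], paste(sprintf("%4d", m[i, ]), collapse = ""))
    }, "")
  )
  writeLines(lines, path)
  path
}
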