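test_that("residue_charge follows Henderson-Hasselbalch", {
  expect_identical(residue_charge("G", 7), 0)
  ipc <- pka_set("IPC_protein")

  # half-ionization exactly at pH == pKa
  pka_e <- ipc$pka[ipc$group == "E"]
  expect_identical(residue_charge("E", pka_e), -0.5)
  pka_k <- ipc$pka[ipc$group == "K"]
  expect_identical(residue_charge("K", pka_k), 0.5)

  # direct formula at pH 7 for every ionizable group
  for (g in c("D", "E", "C", "Y", "H", "K", "R")) {
    expect_equal(residue_charge(g, 7), hh_charge(g, 7, ipc))
  }

  # a base with pKa 3 units above pH is almost fully charged
  custom <- pka_set()
  custom$pka[custom$group == "K"] <- 10
  expect_equal(residue_charge("K", 7, custom), 1 / (1 + 10^(7 - 10)),
               tolerance = 1e-12)

  expect_error(residue_charge("Z", 7), "Unknown residue")
  expect_error(residue_charge("E", 15), "in \\(0, 14\\)")
})

test_that("signed charges deprotonate monotonically as pH rises", {
  # raising pH deprotonates every group: acids go 0 -> -1, bases +1 -> 0,
  # so the signed charge of both is non-increasing in pH
  grid <- 1:13
  for (g in c("D", "E", "C", "Y", "CTERM")) {
    q <- vapply(grid, function(p) residue_charge(g, p), 0)
    expect_true(all(diff(q) <= 0))
    expect_true(all(q <= 0 & q >= -1))
  }
  for (g in c("H", "K", "R", "NTERM")) {
    q <- vapply(grid, function(p) residue_charge(g, p), 0)
    expect_true(all(diff(q) <= 0))
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("net_charge sums per-residue charges, with optional termini", {
  expect_equal(net_charge("GGGG", include_termini = FALSE)$net_charge, 0)

  ipc <- pka_set()
  e4 <- net_charge("EEEE", include_termini = FALSE)
  expect_equal(e4$net_charge, 4 * hh_charge("E", 7, ipc), tolerance = 1e-12)
  expect_equal(e4$mean_net_charge, e4$net_charge / 4)

  with_term <- net_charge("EEEE", include_termini = TRUE)
  expect_equal(with_term$net_charge,
               e4$net_charge + hh_charge("NTERM", 7, ipc) + hh_charge("CTERM", 7, ipc),
               tolerance = 1e-12)
})

test_that("mean net charge of a homopolymer is length-invariant (termini off)", {
  for (n in c(5, 20, 113)) {
    expect_equal(net_charge(strrep("E", n), include_termini = FALSE)$mean_net_charge,
                 hh_charge("E", 7, pka_set()), tolerance = 1e-12)
  }
})

test_that("local_charge reports full windows only, at center positions", {
  p <- local_charge(strrep("G", 9), window = 9)
  expect_equal(p$position, 5L)
  expect_equal(p$charge, 0)

  p11 <- local_charge(random_sequence(11, 1), window = 9)
  expect_equal(p11$position, c(5L, 6L, 7L))

  p3 <- local_charge("EEEEKKKKK", window = 3)
  at5 <- p3$charge[p3$position == 5]
  expect_equal(at5, mean(oracle_charges("EKK")), tolerance = 1e-12)

  expect_error(local_charge("EEEEKKKKK", window = 4), "odd")
  expect_error(local_charge("EEK", window = 5), "exceeds sequence length")
})

test_that("local_charge matches a brute-force window loop", {
  for (seed in 1:20) {
    n <- sample(9:120, 1)
    w <- sample(seq(3, min(n, 21), by = 2), 1)
    s <- random_sequence(n, seed)
    got <- local_charge(s, window = w)
    expect_equal(got$charge, brute_windows(oracle_charges(s), w), tolerance = 1e-12)
  }
})

test_that("masked positions are excluded from sums and window means", {
  p <- suppressWarnings(as_protein_tbl("EXE", unknown = "mask"))
  nc <- net_charge(p, include_termini = FALSE)
  expect_equal(nc$net_charge, 2 * hh_charge("E", 7, pka_set()), tolerance = 1e-12)
  # mean over known residues only
  expect_equal(nc$mean_net_charge, hh_charge("E", 7, pka_set()), tolerance = 1e-12)
  lw <- local_charge(p, window = 3)
  expect_equal(lw$charge, hh_charge("E", 7, pka_set()), tolerance = 1e-12)
})

test_that("pKa sets validate chemistry and load from files", {
  expect_true(all(c("IPC_protein", "EMBOSS") %in% pka_set_names()))
  expect_error(pka_set("nosuch"), "Unknown pKa set")

  f <- system.file("extdata", "pka_example.tsv", package = "disprof")
  ps <- read_pka_set(f, name = "example")
  expect_equal(sort(ps$group), sort(pka_set("EMBOSS")$group))
  expect_equal(ps$pka[ps$group == "K"], 10.8)

  bad <- pka_set()
  bad$pka[1] <- 15
  expect_error(residue_charge("E", 7, bad), "\\(0, 14\\)")
})
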