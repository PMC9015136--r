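test_that("charge-hydropathy classification implements the boundary rules", {
  expect_equal(classify_charge_hydropathy(0, 0), "extended/disordered")
  expect_equal(classify_charge_hydropathy(0.8, 0), "insoluble")
  # boundary at h = 0.5 is 2.785*0.5 - 1.151 = 0.2415; 0.10 falls inside
  expect_equal(classify_charge_hydropathy(0.5, 0.10), "collapsed/compact")
  # exact boundary equality is collapsed (strict inequality for extended)
  expect_equal(classify_charge_hydropathy(0.5, 2.785 * 0.5 - 1.151),
               "collapsed/compact")
  # insolubility overrides even an extreme charge
  expect_equal(classify_charge_hydropathy(0.7, 0.9), "insoluble")
  expect_error(classify_charge_hydropathy(1.2, 0), "\\[0, 1\\]")
})

test_that("classification is symmetric in the sign of the charge", {
  withr::with_seed(42, {
    h <- runif(300)
    q <- runif(300, -1, 1)
  })
  expect_identical(classify_charge_hydropathy(h, q),
                   classify_charge_hydropathy(h, -q))
})

test_that("charge_hydropathy composes the two whole-sequence coordinates", {
  polyI <- c(polyI = strrep("I", 50))
  chI <- charge_hydropathy(polyI)
  expect_equal(chI$mean_hydropathy, 1)
  expect_equal(chI$label, "insoluble")

  polyG <- strrep("G", 50)
  chG <- charge_hydropathy(polyG, include_termini = FALSE)
  expect_equal(chG$mean_hydropathy, (-0.4 + 4.5) / 9, tolerance = 1e-12)
  expect_equal(chG$mean_net_charge, 0)
  # boundary at scaled(G) is 2.785*0.4556 - 1.151 = 0.1178 > 0 => collapsed
  expect_equal(chG$label, "collapsed/compact")

  # coordinates equal the module functions they are built from
  s <- generate_fixture("mixed", 120, seed = 7)
  ch <- charge_hydropathy(s)
  expect_equal(ch$mean_hydropathy, mean_scaled_hydropathy(s)$mean_hydropathy)
  expect_equal(ch$mean_net_charge, net_charge(s)$mean_net_charge)
})

test_that("FoldIndex scores follow 2.785*h - |q| - 1.151", {
  # poly-Ile: h = 1, q ~ 0, so every window scores 2.785 - 1.151 exactly
  fi <- foldindex(strrep("I", 120))
  expect_equal(fi$scores$score, rep(2.785 - 1.151, nrow(fi$scores)),
               tolerance = 1e-12)
  expect_true(all(fi$scores$call == "ordered"))

  # poly-Glu at pH 7: strongly charged and hydrophilic => disordered
  qe <- abs(hh_charge("E", 7, pka_set()))
  expected <- 2.785 * (1 / 9) - qe - 1.151
  fe <- foldindex(strrep("E", 120))
  expect_equal(fe$scores$score, rep(expected, nrow(fe$scores)),
               tolerance = 1e-9)
  expect_true(all(fe$scores$call == "disordered"))

  expect_error(foldindex("EEK", window = 4), "odd")
})

test_that("FoldIndex agrees with local charge and hydropathy profiles", {
  s <- generate_fixture("mixed", 200, seed = 11)
  fi <- foldindex(s, window = 51)
  h <- local_hydropathy(s, window = 51)
  q <- local_charge(s, window = 51)
  expect_equal(fi$scores$position, h$position)
  expect_equal(fi$scores$score, 2.785 * h$hydropathy - abs(q$charge) - 1.151,
               tolerance = 1e-12)
})

test_that("calls match score signs, zero counted as ordered", {
  s <- generate_fixture("mixed", 300, seed = 13)
  fi <- foldindex(s)
  expect_identical(fi$scores$call,
                   ifelse(fi$scores$score < 0, "disordered", "ordered"))
})

test_that("sequences shorter than the window fall back to one whole-sequence window", {
  s <- random_sequence(30, 17)
  fi <- foldindex(s, window = 51)
  expect_equal(nrow(fi$scores), 1L)
  expect_equal(fi$scores$position, 15L)
  expect_true(fi$sequences$whole_sequence)
  expect_equal(fi$scores$score,
               2.785 * mean(oracle_hydropathy(s)) -
                 abs(mean(oracle_charges(s))) - 1.151,
               tolerance = 1e-12)
})

test_that("regions are maximal same-call runs partitioning the positions", {
  tbl <- dplyr::bind_rows(
    generate_fixture("mixed", 400, seed = 19),
    generate_fixture("disorder-rich", 260, seed = 20)
  )
  fi <- foldindex(tbl)
  for (one_id in tbl$id) {
    sc <- dplyr::filter(fi$scores, id == one_id)
    rg <- dplyr::filter(fi$regions, id == one_id)
    # concatenating the regions reproduces the per-position calls
    rebuilt <- unlist(purrr::pmap(rg, function(start, end, call, ...) {
      rep(call, end - start + 1)
    }))
    expect_identical(rebuilt, sc$call)
    expect_equal(rg$start[1], min(sc$position))
    expect_equal(rg$end[nrow(rg)], max(sc$position))
    if (nrow(rg) > 1) {
      expect_true(all(rg$start[-1] == rg$end[-nrow(rg)] + 1))
      expect_true(all(rg$call[-1] != rg$call[-nrow(rg)]))
    }
  }
})

test_that("replacing hydrophobic residues with Glu never raises a window score", {
  # residues whose hydropathy excess over Glu outweighs Glu's full charge
  hydrophobic <- c("I", "V", "L", "F", "C", "M", "A")
  for (seed in 31:40) {
    s <- generate_fixture("mixed", 150, seed = seed)$seq
    chars <- strsplit(s, "")[[1]]
    chars[chars %in% hydrophobic] <- "E"
    mutated <- paste(chars, collapse = "")
    before <- foldindex(s, window = 21)$scores$score
    after <- foldindex(mutated, window = 21)$scores$score
    expect_true(all(after <= before + 1e-12))
  }
})
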