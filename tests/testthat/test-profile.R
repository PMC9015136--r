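test_that("fixture generation is deterministic and class-biased", {
  a <- generate_fixture("disorder-rich", 100, seed = 1)
  b <- generate_fixture("disorder-rich", 100, seed = 1)
  expect_identical(a$seq, b$seq)
  expect_false(identical(a$seq, generate_fixture("disorder-rich", 100, seed = 2)$seq))
  expect_error(generate_fixture("spicy", 10), "must be one of")
  expect_error(generate_fixture("mixed", 0), "positive integer")

  # composition bias shows up in class fractions
  cs <- composition_summary(generate_fixture("disorder-rich", 2000, seed = 3))
  frac <- cs$classes$fraction[cs$classes$class == "disorder-promoting"]
  expect_gt(frac, 0.7)
})

test_that("acidic fixtures are net negative, basic fixtures net positive", {
  for (seed in 1:5) {
    expect_lt(net_charge(generate_fixture("acidic", 200, seed = seed))$net_charge, 0)
    expect_gt(net_charge(generate_fixture("basic", 200, seed = seed))$net_charge, 0)
  }
})

test_that("order-rich fixtures score higher on FoldIndex than disorder-rich", {
  fo <- foldindex(generate_fixture("order-rich", 500, seed = 4))
  fd <- foldindex(generate_fixture("disorder-rich", 500, seed = 4))
  expect_gt(mean(fo$scores$score), mean(fd$scores$score))
})

test_that("the profile aggregator reproduces each module bit-for-bit", {
  tbl <- dplyr::bind_rows(
    generate_fixture("acidic", 140, seed = 8),
    generate_fixture("order-rich", 90, seed = 9)
  )
  p <- disorder_profile(tbl, ph = 7, window = 9, foldindex_window = 51)

  expect_identical(p$charge_hydropathy, charge_hydropathy(tbl))
  expect_identical(p$local_charge, local_charge(tbl, window = 9))
  expect_identical(p$local_hydropathy, local_hydropathy(tbl, window = 9))
  expect_identical(p$tendency, tendency_profile(tbl))
  expect_identical(p$composition$residues, composition_summary(tbl)$residues)
  expect_identical(p$foldindex$scores, foldindex(tbl, window = 51)$scores)

  g <- glance(p)
  expect_equal(nrow(g), 2L)
  expect_true(all(c("label", "mean_score", "frac_disorder_promoting") %in% names(g)))

  expect_error(disorder_profile(tbl, window = 8), "odd")
})

test_that("profiles survive a JSON round trip", {
  tbl <- generate_fixture("mixed", 120, seed = 10)
  p <- disorder_profile(tbl)
  dir <- withr::local_tempdir()
  write_profile(p, dir, format = "json")
  back <- read_profile_json(file.path(dir, "profile.json"))

  expect_equal(as.data.frame(back$charge_hydropathy),
               as.data.frame(p$charge_hydropathy))
  expect_equal(as.data.frame(back$local_charge), as.data.frame(p$local_charge))
  expect_equal(as.data.frame(back$local_hydropathy),
               as.data.frame(p$local_hydropathy))
  expect_equal(as.data.frame(back$tendency), as.data.frame(p$tendency))
  expect_equal(as.data.frame(back$foldindex$scores),
               as.data.frame(p$foldindex$scores))
  expect_equal(as.data.frame(back$foldindex$regions),
               as.data.frame(p$foldindex$regions))
  expect_equal(back$params$ph, p$params$ph)
})

test_that("TSV outputs cover every component", {
  dir <- withr::local_tempdir()
  write_profile(disorder_profile(generate_fixture("mixed", 80, seed = 12)),
                dir, format = "tsv")
  expect_true(all(file.exists(file.path(dir, c(
    "charge_hydropathy.tsv", "charge.tsv", "hydropathy.tsv",
    "tendency.tsv", "composition.tsv", "foldindex.tsv", "foldindex_regions.tsv"
  )))))
})

test_that("plot builders return ggplot objects without evaluation errors", {
  tbl <- generate_fixture("mixed", 90, seed = 14)
  p <- disorder_profile(tbl)
  expect_s3_class(plot_charge_hydropathy(p$charge_hydropathy), "ggplot")
  expect_s3_class(plot_local_profile(p$local_charge), "ggplot")
  expect_s3_class(plot_tendency(p$tendency), "ggplot")
  expect_s3_class(autoplot(p$foldindex), "ggplot")
  expect_s3_class(autoplot(p$composition), "ggplot")
  m <- sequence_map(tbl, values = p$tendency$class, n_columns = 15)
  expect_s3_class(autoplot(m), "ggplot")
})
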