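test_that("noiseless intensity ratios equal count ratios exactly", {
  cnt <- data.frame(species = c("correct", "M", "C"),
                    positions = c("", "5", "5+7"),
                    count = c(1e8, 1e4, 8e2))
  cfg <- sim_config(noise_cv = 0, n_replicates = 2)
  tab <- emit_intensity_table(cnt, cfg, condition = list(aga = "Str"))
  ef <- compute_ef(tab, "M", parent = "correct")
  expect_equal(ef$ef, 1e-4)
  expect_equal(ef$parent_source, "measured")
  expect_false(ef$upper_limit)
  expect_equal(compute_ef(tab, "C")$ef, 8e-6)
})

test_that("intensities below the detection floor become missing", {
  cnt <- data.frame(species = c("correct", "M"), count = c(1e6, 0))
  cfg <- sim_config(noise_cv = 0, detection_floor = 1, n_replicates = 1)
  tab <- emit_intensity_table(cnt, cfg)
  expect_true(is.na(tab$intensity[tab$species == "M"]))
  # missing missense is an upper limit at the floor, never zero
  ef <- compute_ef(tab, "M", parent = "correct")
  expect_true(ef$upper_limit)
  expect_equal(ef$ef, 1 / 1e6)
  # a species absent from the table yields a missing result
  expect_true(is.na(compute_ef(tab, "nonexistent")$ef))
})

test_that("a missing parent falls back to the median of correct peptides", {
  tab <- data.frame(
    species = c("corr1", "corr2", "corr3", "M"),
    replicate = 1L,
    intensity = c(1e6, 2e6, 4e6, 100)
  )
  ef <- compute_ef(tab, "M", parent = "corr9",
                   correct_species = c("corr1", "corr2", "corr3"))
  expect_equal(ef$ef, 100 / 2e6)
  expect_equal(ef$parent_source, "median-fallback")
})

test_that("replicate error frequencies aggregate by the median", {
  tab <- data.frame(
    species = rep(c("correct", "M"), 3),
    replicate = rep(1:3, each = 2),
    intensity = c(1e6, 100, 1e6, 120, 1e6, 500)
  )
  expect_equal(compute_ef(tab, "M", parent = "correct")$ef, 1.2e-4)
})

test_that("per-species ionization multipliers bias LFQ ratios as expected", {
  cnt <- data.frame(species = c("correct", "M"), count = c(1e6, 1e3))
  cfg <- sim_config(noise_cv = 0, n_replicates = 1)
  tab <- emit_intensity_table(cnt, cfg, ionization = c(M = 0.5))
  expect_equal(compute_ef(tab, "M", parent = "correct")$ef, 5e-4)
})

test_that("intensity tables round-trip through the TSV format", {
  cnt <- data.frame(species = c("correct", "M"), positions = c("", "5"),
                    count = c(1e6, 1e3))
  cfg <- sim_config(noise_cv = 0.1, seed = 5, n_replicates = 3)
  tab <- emit_intensity_table(cnt, cfg, condition = list(aga = "Apr", concentration = 4))
  path <- tempfile(fileext = ".tsv")
  write_intensity_table(tab, path)
  back <- read_intensity_table(path)
  expect_equal(attr(back, "detection_floor"), attr(tab, "detection_floor"))
  expect_equal(back$intensity, tab$intensity, tolerance = 1e-12)
  expect_equal(back$species, tab$species)
  expect_equal(back$aga, tab$aga)
})

test_that("the induction filter keeps induced species and drops background", {
  expect_true(induction_filter(c(300, 310, 295), c(100, 100, 100)))
  expect_false(induction_filter(c(150, 160, 150), c(100, 100, 100)))
  expect_false(induction_filter(c(300, 150, 300), c(100, 100, 100)))
  # simulated chemical background: constant intensity across conditions
  set.seed(9)
  kept <- vapply(1:200, function(i) {
    base <- exp(rnorm(3, log(1e5), 0.2))
    treat <- exp(rnorm(3, log(1e5), 0.2))
    induction_filter(treat, base)
  }, logical(1))
  expect_gte(mean(!kept), 0.95)
})
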