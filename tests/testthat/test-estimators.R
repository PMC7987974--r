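test_that("stochastic expectation is the product of single frequencies", {
  expect_equal(stochastic_expectation(c(1e-4, 1e-3))$value, 1e-7)
  expect_equal(stochastic_expectation(c(1e-4, 1e-4, 1e-3))$value, 1e-11)
  expect_true(stochastic_expectation(c(1e-4, 1e-3), upper_limit = c(FALSE, TRUE))$upper_limit)
  expect_false(stochastic_expectation(c(1e-4, 1e-3))$upper_limit)
})

test_that("amplification and the cluster-statistic identities hold", {
  expect_equal(amplification(8e-6, 1e-4, 1e-3), 80)
  expect_warning(a0 <- amplification(1e-6, 0, 1e-3), "upper-limit")
  expect_equal(a0, Inf)
  set.seed(21)
  for (i in 1:50) {
    ef1 <- 10^runif(1, -5, -3); ef2 <- 10^runif(1, -5, -3)
    efn <- runif(1, 0.01, 0.5)
    efc <- ef1 * efn
    cs <- cluster_stat("X+Y", ef1, ef2, efc, d = 1)
    expect_equal(cs$amplification, cs$ef_cluster / (cs$ef_first * cs$ef_second),
                 tolerance = 1e-12)
    expect_equal(cs$efnext, cs$ef_cluster / cs$ef_first, tolerance = 1e-12)
    expect_equal(cs$amplification, cs$efnext / cs$ef_second, tolerance = 1e-12)
    expect_equal(cs$ef_first * cs$efnext, cs$ef_cluster, tolerance = 1e-12)
  }
})

test_that("the through-origin slope recovers proportional data exactly", {
  series <- data.frame(ef_first = c(1e-4, 2e-4, 4e-4),
                       ef_cluster = c(8e-6, 1.6e-5, 3.2e-5))
  sl <- efnext_slope(series)
  expect_equal(sl$efnext, 0.08, tolerance = 1e-12)
  expect_equal(sl$se, 0, tolerance = 1e-9)
  expect_equal(efnext_slope(data.frame(ef_first = c(1, 2, 3), ef_cluster = 0))$efnext, 0)
  expect_error(efnext_slope(series[1:2, ]), "at least 3")
})

test_that("ratio estimators compute point and third-step values", {
  expect_equal(efnext_ratio(8e-6, 1e-4)$efnext, 0.08)
  expect_equal(efnext_ratio(2e-7, 8e-7)$efnext, 0.25)  # triple over leading double
  expect_true(efnext_ratio(8e-6, 1e-4, first_upper_limit = TRUE)$lower_limit)
  expect_error(efnext_ratio(1e-6, 0), "positive")
})

test_that("the LFQ estimator enforces the physico-chemical exclusions", {
  expect_equal(efnext_lfq(400, 8000)$efnext, 0.05)
  res <- efnext_lfq(400, 8000, following_from = "Y", following_to = "H")
  expect_false(res$valid)
  expect_match(res$reason, "charge-state")
  expect_true(is.na(res$efnext))
  # D -> E does not change the charge class
  expect_true(efnext_lfq(400, 8000, following_from = "D", following_to = "E")$valid)
  expect_error(efnext_lfq(400, 8000, cleavage_altered = TRUE), "cleavage")
})

test_that("slope, ratio and LFQ estimators coincide on noiseless data", {
  prot <- example_protein()
  subs <- rbind(substitution_spec(prot, 242, "D"),
                substitution_spec(prot, 244, "D"))
  params <- cluster_params("Apr", c(242, 244))
  cfg <- sim_config(noise_cv = 0, n_replicates = 1, epsilon0 = 0)
  labels <- stats::setNames(subs$label, subs$position)
  tabs <- lapply(c(1, 2, 4, 8), function(conc) {
    cnt <- sample_counts(prot, params, cfg, concentration = conc,
                         labels = labels, mode = "expected")
    emit_intensity_table(cnt, cfg, condition = list(concentration = conc))
  })
  ratio <- efnext_from_tables(tabs, "E242D", "E242D+E244D", estimator = "ratio")
  slope <- efnext_from_tables(tabs, "E242D", "E242D+E244D", estimator = "slope")
  # per-condition ratios are constant, and LFQ equals the frequency ratio
  # constant up to the tiny rebinding dependence on concentration
  expect_equal(ratio$by_condition$efnext,
               rep(ratio$efnext, 4), tolerance = 1e-3)
  expect_equal(slope$efnext, ratio$efnext, tolerance = 1e-3)
  tab1 <- tabs[[4]]
  lfq <- efnext_lfq(tab1$intensity[tab1$species == "E242D+E244D"],
                    tab1$intensity[tab1$species == "E242D"],
                    following_from = "E", following_to = "D")
  expect_equal(lfq$efnext, ratio$by_condition$efnext[4], tolerance = 1e-12)
})
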