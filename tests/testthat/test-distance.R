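test_that("distance profiles normalize to the reference drug", {
  # a drug identical to the reference gives a flat profile at 1
  df <- data.frame(aga = rep(c("Str", "X"), each = 3),
                   d = rep(0:2, 2), efnext = rep(c(0.05, 0.05, 0.05), 2))
  prof <- build_distance_profile(df, reference = "Str")
  expect_equal(prof$efnext_norm, rep(1, 6))
  # halving per unit distance against a flat reference
  df2 <- data.frame(aga = c(rep("Str", 3), rep("Y", 3)), d = rep(0:2, 2),
                    efnext = c(0.05, 0.05, 0.05, 0.4, 0.2, 0.1))
  prof2 <- build_distance_profile(df2, reference = "Str")
  y <- prof2[prof2$aga == "Y", ]
  expect_equal(y$efnext_norm, 8 * c(1, 0.5, 0.25))
  # per-drug scaling anchors each curve at 1 at its smallest distance
  prof3 <- build_distance_profile(df2, reference = "Str", scaling = "per_aga")
  expect_equal(prof3$efnext_norm[prof3$aga == "Y"], c(1, 0.5, 0.25))
})

test_that("points without a reference measurement are dropped with a warning", {
  df <- data.frame(aga = c("Str", "Str", "Y", "Y", "Y"),
                   d = c(0, 1, 0, 1, 5), efnext = c(0.05, 0.05, 0.4, 0.2, 0.01))
  expect_warning(prof <- build_distance_profile(df, reference = "Str"),
                 "without a Str reference")
  expect_false(any(prof$d == 5))
})

test_that("exact exponential profiles are fitted exactly", {
  prof <- data.frame(aga = "Z", d = 0:2, efnext_norm = c(1, 0.5, 0.25))
  fit <- fit_retention(prof, n_boot = 50, seed = 1)
  expect_equal(fit$q, 0.5, tolerance = 1e-6)
  expect_equal(fit$c, 1, tolerance = 1e-6)
  flat <- data.frame(aga = "Z", d = 0:3, efnext_norm = rep(1, 4))
  ffit <- fit_retention(flat, n_boot = 50, seed = 2)
  expect_equal(ffit$q, 1)
  expect_true(ffit$degenerate)
  expect_equal(ffit$ci[2], 1)
  expect_error(fit_retention(prof[1:2, ]), "3 distinct")
})

test_that("retention is recovered within the bootstrap CI across q values", {
  set.seed(17)
  for (q in c(0.3, 0.5, 0.7, 1.0)) {
    d <- 0:6
    y <- 2 * q^d * exp(rnorm(7, 0, 0.04))
    prof <- data.frame(aga = "Z", d = d, efnext_norm = y, sd = 0.05 * y)
    fit <- fit_retention(prof, n_boot = 200, seed = round(100 * q))
    expect_true(fit$ci[1] <= q && q <= fit$ci[2],
                label = sprintf("q = %g in [%.3f, %.3f]", q, fit$ci[1], fit$ci[2]))
    expect_true(fit$q >= 0 && fit$q <= 1)
  }
})

test_that("drug groups are classified by potency and adjacent next-error", {
  expect_equal(classify_aga(1.3e-3, 0.05), "I")    # streptomycin-like
  expect_equal(classify_aga(8e-5, 0.4), "II")      # sisomycin-like
  expect_equal(classify_aga(0, 0), "unclassified")
  expect_equal(classify_aga(NA, 0.4), "unclassified")
})

test_that("preset simulations land in the expected drug groups", {
  prot <- example_protein()
  cfg <- sim_config(seed = 77)
  one <- function(drug) {
    params <- cluster_params(drug, c(241, 242),
                             efnext = aga_presets(drug)$anchors$efnext[1],
                             d_anchor = aga_presets(drug)$anchors$d[1])
    cnt <- sample_counts(prot, params, cfg, concentration = 8,
                         labels = c("241" = "E241D", "242" = "E242D"))
    tab <- emit_intensity_table(cnt, cfg, seed = 78)
    ef1 <- compute_ef(tab, "E241D")$ef
    efn <- efnext_from_tables(tab, "E241D", "E241D+E242D")$efnext
    classify_aga(ef1, efn)
  }
  expect_equal(one("Str"), "I")
  expect_equal(one("Apr"), "II")
})
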