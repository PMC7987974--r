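test_that("aggregation enrichment normalizes to the correct-peptide cohort", {
  corr_in <- matrix(c(1, 1, 1, 1, 1, 1), nrow = 3)   # 3 peptides x 2 reps
  corr_sol <- matrix(c(2, 2, 2, 2, 2, 2), nrow = 3)  # cohort ratio 0.5
  res <- aggregation_enrichment(c(4, 4), c(2, 2), corr_in, corr_sol)
  expect_equal(res$enrichment, 4)                    # 2.0 / 0.5
  # a correct peptide against its own cohort sits at 1
  res1 <- aggregation_enrichment(c(1, 1), c(2, 2), corr_in, corr_sol)
  expect_equal(res1$enrichment, 1)
  # zero soluble intensity flags an upper limit
  res2 <- aggregation_enrichment(c(4, 4), c(0, 2), corr_in, corr_sol)
  expect_true(res2$upper_limit)
})

test_that("programmed aggregation propensities are recovered from a split", {
  cnt <- data.frame(species = c("correct", "M"), count = c(1e7, 1e5))
  sp <- fraction_split(cnt, c(M = 0.8, correct = 0.2), seed = 4)
  reps <- 3
  set.seed(5)
  noise <- function(x) x * exp(rnorm(reps, 0, 0.05))
  insol_m <- noise(sp$insoluble$count[2]); sol_m <- noise(sp$soluble$count[2])
  corr_in <- matrix(noise(sp$insoluble$count[1]), nrow = 1)
  corr_sol <- matrix(noise(sp$soluble$count[1]), nrow = 1)
  res <- aggregation_enrichment(insol_m, sol_m, corr_in, corr_sol)
  truth <- (0.8 / 0.2) / (0.2 / 0.8)  # odds ratio of the propensities
  expect_equal(res$enrichment, truth, tolerance = 0.15)
  expect_lt(res$p_value, 0.05)
})

test_that("thermostability curves anchor at the reference temperature", {
  raw <- c("41" = 0.2, "45" = 0.15, "49" = 0.1)
  parent <- c("41" = 1, "45" = 1, "49" = 1)
  curve <- thermostability_normalize(raw, parent)
  expect_equal(curve$value, c(1, 0.75, 0.5))
  expect_equal(curve$value[curve$temperature == 41], 1)
  # identical decay of missense and parent: flat curve at 1
  flat <- thermostability_normalize(c("41" = 5, "45" = 2, "49" = 0.5),
                                    c("41" = 10, "45" = 4, "49" = 1))
  expect_equal(flat$value, rep(1, 3))
  # a destabilized species decays monotonically
  temps <- seq(41, 61, by = 4)
  parent2 <- stats::setNames(exp(-0.05 * (temps - 41)), temps)
  miss2 <- stats::setNames(exp(-0.20 * (temps - 41)), temps)
  dec <- thermostability_normalize(miss2, parent2)
  expect_true(all(diff(dec$value) < 0))
  expect_error(thermostability_normalize(raw[2:3], parent[2:3], anchor = 41),
               "anchor")
})

test_that("presence filtering keeps proteins quantified in >= 60% of runs", {
  m <- matrix(1, nrow = 3, ncol = 10,
              dimnames = list(c("p5", "p6", "p10"), NULL))
  m[1, 1:5] <- NA  # 5/10 -> dropped
  m[2, 1:4] <- NA  # 6/10 -> kept
  out <- presence_filter(m)
  expect_equal(rownames(out), c("p6", "p10"))
  full <- matrix(1, 4, 3)
  expect_equal(presence_filter(full), full)
})

test_that("imputation draws from the downshifted, narrowed normal law", {
  set.seed(100)
  n <- 10000
  mat <- matrix(rnorm(2 * n, mean = 25, sd = 2), ncol = 2)
  miss <- sample(n, n / 2)
  truth <- mat[miss, 1]
  mat[miss, 1] <- NA
  out <- impute_missing(mat, seed = 200)
  imputed <- out[miss, 1]
  obs <- mat[-miss, 1][!is.na(mat[-miss, 1])]
  mu <- mean(mat[, 1], na.rm = TRUE); s <- sd(mat[, 1], na.rm = TRUE)
  # location test against mu - 1.8 sd and spread against 0.3 sd
  expect_lt(abs(mean(imputed) - (mu - 1.8 * s)), 3 * 0.3 * s / sqrt(length(imputed)))
  expect_equal(sd(imputed), 0.3 * s, tolerance = 0.05)
  # observed values are untouched; imputed values sit in the left tail
  expect_identical(out[, 2], mat[, 2])
  expect_identical(out[-miss, 1], mat[-miss, 1])
  # with the default width/downshift the imputed law sits at mu - 1.8 sd,
  # so P(imputed < 5th observed percentile) = pnorm((1.8 - 1.645) / 0.3)
  expect_equal(mean(imputed < quantile(mat[, 1], 0.05, na.rm = TRUE)),
               pnorm((1.8 - 1.645) / 0.3), tolerance = 0.05)
  # a fully observed matrix is returned unchanged
  m2 <- matrix(rnorm(20, 25, 2), ncol = 2)
  expect_identical(impute_missing(m2, seed = 1), m2)
  # too few observed values in a sample is an error
  bad <- matrix(c(1, NA, NA, 1, 2, 3), ncol = 2)
  expect_error(impute_missing(bad, seed = 1), "fewer than 2")
})

test_that("interval scaling maps profiles onto [0, 1]", {
  expect_equal(as.numeric(scale_to_interval(c(2, 4, 6))), c(0, 0.5, 1))
  degen <- scale_to_interval(c(5, 5, 5))
  expect_equal(as.numeric(degen), c(0, 0, 0))
  expect_true(attr(degen, "degenerate"))
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1))
    y <- scale_to_interval(x)
    expect_equal(range(y), c(0, 1))
    expect_false(attr(y, "degenerate"))
  }
})
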