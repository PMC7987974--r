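test_that("without drug or baseline errors the correct pattern is certain", {
  prot <- test_protein(10)
  par <- test_params(beta = 0, q = 0.5, misread = c("3" = 0.5, "7" = 0.2))
  expect_equal(pattern_probability(integer(0), prot, par, concentration = 1), 1)
  expect_equal(pattern_probability(c(3, 7), prot, par, concentration = 1), 0)
})

test_that("forward DP equals exhaustive path enumeration on short proteins", {
  prot <- test_protein(6)
  cases <- list(
    list(beta = 0.2, q = 0.6, mis = c("2" = 0.5, "4" = 0.3, "6" = 0.7), eps = 0.01),
    list(beta = 0.05, q = 0.9, mis = c("1" = 0.4, "5" = 0.25), eps = 0),
    list(beta = 0.5, q = 0.1, mis = c("3" = 1.0, "4" = 0.9), eps = 0.1)
  )
  for (cs in cases) {
    par <- test_params(cs$beta, cs$q, cs$mis)
    designated <- as.integer(names(cs$mis))
    pats <- all_patterns(par)
    for (p in pats) {
      dp <- pattern_probability(p, prot, par, concentration = 1, epsilon0 = cs$eps)
      oracle <- oracle_pattern_probability(p, L = 6, beta = cs$beta, q = cs$q,
                                           misread = cs$mis, eps0 = cs$eps)
      expect_equal(dp, oracle, tolerance = 1e-12,
                   label = sprintf("pattern %s", paste(p, collapse = "+")))
    }
    total <- sum(vapply(pats, pattern_probability, numeric(1), protein = prot,
                        params = par, concentration = 1, epsilon0 = cs$eps))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("full retention gives distance-independent two-error probabilities", {
  # q = 1 and zero weight on intervening codons: the flat-profile limit
  prot <- test_protein(30)
  probs <- vapply(0:5, function(d) {
    par <- test_params(1e-4, q = 1,
                       misread = stats::setNames(c(0.5, 0.3), c(5, 6 + d)))
    pattern_probability(c(5, 6 + d), prot, par, concentration = 1)
  }, numeric(1))
  expect_true(all(abs(probs / probs[1] - 1) < 1e-9))
})

test_that("partial retention decays two-error probabilities monotonically", {
  prot <- test_protein(30)
  probs <- vapply(0:5, function(d) {
    par <- test_params(1e-4, q = 0.6,
                       misread = stats::setNames(c(0.5, 0.3), c(5, 6 + d)))
    pattern_probability(c(5, 6 + d), prot, par, concentration = 1)
  }, numeric(1))
  expect_true(all(diff(probs) < 0))
})

test_that("the measured next-error ratio matches its closed form exactly", {
  # E_f^next = c/(1-c) with c = P(bound->bound over d+1 steps) * mw2:
  # the single-first-error species requires correct decoding at the second
  # position, hence the 1 - c factor
  prot <- test_protein(40)
  for (q in c(0.5, 0.9)) {
    for (d in c(0, 2, 5)) {
      mis <- stats::setNames(c(0.5, 0.3), c(10, 11 + d))
      par <- test_params(2e-5, q, mis)
      p_both <- pattern_probability(c(10, 11 + d), prot, par, concentration = 1)
      p_first <- pattern_probability(10, prot, par, concentration = 1)
      cc <- bound_propagator(par, d + 1, concentration = 1) * 0.3
      expect_equal(p_both / p_first, unname(cc / (1 - cc)), tolerance = 1e-12)
    }
  }
})

test_that("invalid patterns are rejected", {
  prot <- test_protein(10)
  par <- test_params(0.1, 0.5, c("3" = 0.5))
  expect_error(pattern_probability(4, prot, par), "without a misreading weight")
  expect_error(pattern_probability(c(3, 3), prot, par), "strictly increasing")
  expect_error(pattern_probability(99, prot, par), "outside the protein")
})
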