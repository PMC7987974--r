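#' Simulation configuration
#'
#' Collects the nuisance parameters of the synthetic-data generator.
#'
#' @param n_ribosomes Effective number of ribosome traversals N per
#'   condition (the copy number behind the intensity signal).
#' @param seed RNG seed; `NULL` leaves the RNG stream untouched.
#' @param epsilon0 Baseline per-codon probability of the designated
#'   misreading outcome without drug (drug-independent background errors).
#' @param ram_rate Additional independent per-codon error probability
#'   emulating a hyper-accurate-site mutant ribosome (error-prone S4
#'   truncation): elevated, independent errors with no drug involvement.
#' @param noise_cv Log-normal coefficient of variation of emitted
#'   intensities (technical replicate scatter of integrated peak areas).
#' @param detection_floor Intensities below this value are reported missing.
#' @param scale Global intensity per traversal count.
#' @param n_replicates Technical replicates emitted per condition.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_ribosomes = 1e8, seed = NULL, epsilon0 = 1e-6,
                       ram_rate = 0, noise_cv = 0.05, detection_floor = 1,
                       scale = 1, n_replicates = 3L) {
  stopifnot(n_ribosomes > 0)
  stopifnot_scalar_prob(epsilon0, "epsilon0")
  stopifnot_scalar_prob(ram_rate, "ram_rate")
  stopifnot(noise_cv >= 0, detection_floor >= 0, scale > 0, n_replicates >= 1L)
  structure(list(n_ribosomes = n_ribosomes, seed = seed, epsilon0 = epsilon0,
                 ram_rate = ram_rate, noise_cv = noise_cv,
                 detection_floor = detection_floor, scale = scale,
                 n_replicates = as.integer(n_replicates)),
            class = "sim_config")
}

## state order: [unbound, bound]; transition = translocation then binding
state_transition <- function(beta, q) {
  matrix(c(1 - beta, beta,
           (1 - q) * (1 - beta), q + (1 - q) * beta),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("U", "B"), c("U", "B")))
}

#' Probability of remaining effective drug occupancy over several codons
#'
#' Returns the `[bound -> bound]` element of the k-step state transition,
#' i.e. the probability that a ribosome bound at one decoding event is
#' still (or again, via rebinding) bound k translocations later.
#'
#' @param params `aga_params`.
#' @param steps Number of translocation events.
#' @param concentration Nominal concentration (for the rebinding term).
#' @return Probability.
#' @export
bound_propagator <- function(params, steps, concentration = 0) {
  Tm <- state_transition(beta_at(params, concentration), params$q)
  P <- diag(2)
  for (i in seq_len(steps)) P <- P %*% Tm
  unname(P[2, 2])
}

pattern_label <- function(positions, labels = NULL) {
  if (length(positions) == 0L) return("correct")
  if (!is.null(labels)) return(paste(labels[as.character(positions)], collapse = "+"))
  paste(positions, collapse = "+")
}

#' Exact probability of one substitution pattern per ribosome traversal
#'
#' Forward dynamic programming over the two-state (drug-bound / unbound)
#' Markov chain of an elongating ribosome. At every codon a free drug binds
#' with probability `beta`; a bound ribosome misincorporates the designated
#' substitution at position i with probability `misread[i]` and decodes
#' correctly otherwise; an unbound ribosome misincorporates it with the
#' baseline probability `epsilon0`; after each codon the drug is retained
#' with probability `q`. The returned value is the exact probability that a
#' single traversal emits exactly the given pattern of errors over the
#' designated positions (all other designated positions decoded correctly),
#' so probabilities over all subsets of designated positions sum to 1.
#'
#' @param pattern Integer vector of error positions (a subset of
#'   `names(params$misread)`); `integer(0)` is the all-correct pattern.
#' @param protein `protein_record` (bounds checking).
#' @param params `aga_params`.
#' @param concentration Nominal drug concentration; per-codon binding
#'   probability is `beta_at(params, concentration)`.
#' @param epsilon0 Baseline per-codon error probability in the unbound state.
#' @return Probability.
#' @export
#' @examples
#' prot <- example_protein()
#' par <- cluster_params("Apr", c(242, 244))
#' pattern_probability(c(242, 244), prot, par, concentration = 8)
pattern_probability <- function(pattern, protein, params, concentration = 0,
                                epsilon0 = 0) {
  stopifnot(inherits(protein, "protein_record"), inherits(params, "aga_params"))
  stopifnot_scalar_prob(epsilon0, "epsilon0")
  pattern <- sort(as.integer(pattern))
  designated <- as.integer(names(params$misread))
  if (length(pattern)) {
    if (any(pattern > nchar(protein$sequence) | pattern < 1L))
      stop("pattern positions outside the protein", call. = FALSE)
    if (!all(pattern %in% designated))
      stop("pattern contains positions without a misreading weight", call. = FALSE)
    if (any(duplicated(pattern)))
      stop("pattern positions must be strictly increasing", call. = FALSE)
  }
  beta <- beta_at(params, concentration)
  q <- params$q
  if (!length(designated)) return(1)
  L <- max(designated)
  f <- c(U = 1, B = 0)
  for (i in seq_len(L)) {
    ## binding opportunity at this codon
    f <- c(U = f[["U"]] * (1 - beta), B = f[["B"]] + f[["U"]] * beta)
    if (i %in% designated) {
      mw <- params$misread[[as.character(i)]]
      if (i %in% pattern) {
        f <- c(U = f[["U"]] * epsilon0, B = f[["B"]] * mw)
      } else {
        f <- c(U = f[["U"]] * (1 - epsilon0), B = f[["B"]] * (1 - mw))
      }
    }
    ## translocation: retention with probability q
    f <- c(U = f[["U"]] + f[["B"]] * (1 - q), B = f[["B"]] * q)
  }
  unname(f[["U"]] + f[["B"]])
}

#' All subsets of the designated error positions
#'
#' @param params `aga_params`.
#' @return List of integer vectors (patterns), the first being `integer(0)`.
#' @export
all_patterns <- function(params) {
  designated <- as.integer(names(params$misread))
  n <- length(designated)
  if (n > 16L) stop("too many designated positions to enumerate", call. = FALSE)
  out <- list(integer(0))
  for (k in seq_len(n)) {
    combs <- utils::combn(seq_len(n), k)
    out <- c(out, lapply(seq_len(ncol(combs)), function(j) designated[combs[, j]]))
  }
  out
}

#' Draw per-pattern traversal counts
#'
#' Fast Poisson-rate emulation of N ribosome traversals: each requested
#' pattern's count is drawn from a Poisson law with mean
#' `N * pattern_probability(...)`. An explicit per-ribosome Monte Carlo mode
#' (`mode = "montecarlo"`) simulates every traversal's binding/retention
#' chain and is used to cross-validate the rate mode at small N.
#'
#' In ram mode (`config$ram_rate > 0`) the baseline error probability is
#' `epsilon0 + ram_rate`: elevated errors that remain independent across
#' codons, which is what distinguishes the error-prone ribosome mutant from
#' drug retention.
#'
#' @param protein `protein_record`.
#' @param params `aga_params`.
#' @param config `sim_config`.
#' @param concentration Nominal drug concentration.
#' @param patterns List of integer vectors; default all subsets of the
#'   designated positions.
#' @param labels Optional named character vector position -> substitution
#'   label used to name species (e.g. `c("242" = "E242D")`).
#' @param mode `"poisson"` (default), `"montecarlo"`, or `"expected"`
#'   (deterministic counts `N * p`, for noiseless closed-form checks).
#' @return data.frame with columns `species`, `positions`, `probability`,
#'   `count`.
#' @export
sample_counts <- function(protein, params, config, concentration = 0,
                          patterns = NULL, labels = NULL,
                          mode = c("poisson", "montecarlo", "expected")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  patterns <- patterns %||% all_patterns(params)
  eps <- min(1, config$epsilon0 + config$ram_rate)
  probs <- vapply(patterns, pattern_probability, numeric(1),
                  protein = protein, params = params,
                  concentration = concentration, epsilon0 = eps)
  N <- config$n_ribosomes
  counts <- if (mode == "expected") {
    N * probs
  } else if (mode == "poisson") {
    with_seed(config$seed, {
      lam <- N * probs
      ifelse(lam > 1e9,
             round(stats::rnorm(length(lam), lam, sqrt(lam))),
             stats::rpois(length(lam), lam))
    })
  } else {
    mc <- with_seed(config$seed,
                    simulate_ribosomes(protein, params, config, concentration,
                                       epsilon0 = eps))
    key <- vapply(patterns, function(p) {
      if (length(p)) paste(p, collapse = "+") else "(none)"
    }, character(1))
    cc <- unname(mc[key])
    cc[is.na(cc)] <- 0
    cc
  }
  data.frame(
    species = vapply(patterns, pattern_label, character(1), labels = labels),
    positions = vapply(patterns, paste, character(1), collapse = "+"),
    probability = probs,
    count = as.numeric(counts),
    stringsAsFactors = FALSE
  )
}

#' Explicit per-ribosome Monte Carlo traversal simulation
#'
#' Simulates each of `config$n_ribosomes` traversals through the
#' bind/misread/translocate chain and tabulates the emitted error patterns.
#' Intended for cross-validating the Poisson-rate mode at small N.
#'
#' @inheritParams sample_counts
#' @param epsilon0 Baseline unbound-state error probability.
#' @return Named integer vector: pattern signature (`"242+244"`, `""` for
#'   all-correct) -> traversal count.
#' @export
simulate_ribosomes <- function(protein, params, config, concentration = 0,
                               epsilon0 = config$epsilon0) {
  n <- as.integer(config$n_ribosomes)
  if (n > 1e6) stop("Monte Carlo mode is meant for small N (<= 1e6)", call. = FALSE)
  beta <- beta_at(params, concentration)
  q <- params$q
  designated <- as.integer(names(params$misread))
  L <- if (length(designated)) max(designated) else 0L
  bound <- rep(FALSE, n)
  errs <- matrix(FALSE, n, length(designated))
  for (i in seq_len(L)) {
    bound <- bound | (stats::runif(n) < beta)
    j <- match(i, designated)
    if (!is.na(j)) {
      mw <- params$misread[[as.character(i)]]
      u <- stats::runif(n)
      errs[, j] <- ifelse(bound, u < mw, u < epsilon0)
    }
    bound <- bound & (stats::runif(n) < q)
  }
  sig <- apply(errs, 1L, function(e) {
    if (any(e)) paste(designated[e], collapse = "+") else "(none)"
  })
  tab <- table(sig)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Emit an MS-like intensity table from traversal counts
#'
#' Converts per-species counts into replicate intensities: each intensity is
#' `count * scale * exp(noise)` with log-normal noise of coefficient of
#' variation `config$noise_cv` (median preserved, so noiseless ratios equal
#' count ratios). Values below `config$detection_floor` are reported missing.
#' The ionization factor is 1 for every species -- label-free quantification
#' assumes identical ionization and fragmentation of parent and missense
#' peptides -- but a per-species multiplier can be supplied to stress-test
#' the estimators against that assumption.
#'
#' @param counts data.frame from [sample_counts()].
#' @param config `sim_config`.
#' @param condition Named list of metadata columns added to every row (e.g.
#'   `list(aga = "Apr", concentration = 4)`).
#' @param ionization Optional named numeric vector species -> multiplier.
#' @param seed Optional seed for the noise draws.
#' @return data.frame of class `intensity_table` in long form: columns
#'   `species`, `positions`, any condition columns, `replicate`, `intensity`.
#' @export
emit_intensity_table <- function(counts, config, condition = list(),
                                 ionization = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            all(c("species", "count") %in% names(counts)))
  nrep <- config$n_replicates
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  ion <- rep(1, nrow(counts))
  if (!is.null(ionization)) {
    m <- match(counts$species, names(ionization))
    ion[!is.na(m)] <- ionization[m[!is.na(m)]]
  }
  base <- counts$count * config$scale * ion
  rows <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrep), function(r) {
      noise <- if (sdlog > 0) exp(stats::rnorm(nrow(counts), 0, sdlog)) else 1
      intensity <- base * noise
      intensity[intensity < config$detection_floor] <- NA_real_
      df <- data.frame(species = counts$species,
                       positions = counts$positions %||% "",
                       stringsAsFactors = FALSE)
      for (nm in names(condition)) df[[nm]] <- condition[[nm]]
      df$replicate <- r
      df$intensity <- intensity
      df
    }))
  })
  structure(rows, class = c("intensity_table", "data.frame"),
            detection_floor = config$detection_floor)
}

#' Simulate a drug titration
#'
#' One intensity table per nominal concentration. The per-codon binding
#' probability scales linearly with concentration
#' (`beta = beta_scale * concentration`), so single-error frequencies rise
#' with dose while the conditional next-error frequency -- a property of the
#' bound state -- stays constant.
#'
#' @param protein `protein_record`.
#' @param params `aga_params`.
#' @param concentrations Numeric vector of nominal concentrations.
#' @param config `sim_config`; per-concentration seeds are derived from
#'   `config$seed` when it is set.
#' @param labels Optional position -> substitution label vector.
#' @return Named list of `intensity_table` objects (one per concentration),
#'   each carrying `aga`, `concentration` and `replicate` metadata.
#' @export
simulate_titration <- function(protein, params, concentrations, config,
                               labels = NULL) {
  stopifnot(length(concentrations) >= 1L)
  out <- lapply(seq_along(concentrations), function(k) {
    cfg <- config
    if (!is.null(config$seed)) cfg$seed <- config$seed + k
    cnt <- sample_counts(protein, params, cfg, concentration = concentrations[k],
                         labels = labels)
    emit_intensity_table(cnt, cfg,
                         condition = list(aga = params$name,
                                          concentration = concentrations[k]),
                         seed = if (is.null(cfg$seed)) NULL else cfg$seed + 1000L)
  })
  names(out) <- as.character(concentrations)
  out
}

#' Partition traversal counts into soluble and insoluble fractions
#'
#' Each species' count is split binomially according to its aggregation
#' propensity (probability of partitioning into the insoluble fraction).
#'
#' @param counts data.frame from [sample_counts()].
#' @param destabilization_map Named numeric vector species -> propensity in
#'   `[0, 1]`; species without an entry use `default_propensity`.
#' @param default_propensity Propensity for unlisted species.
#' @param seed Optional RNG seed.
#' @return List with elements `soluble` and `insoluble`, each a counts
#'   data.frame with the same rows.
#' @export
fraction_split <- function(counts, destabilization_map = numeric(),
                           default_propensity = 0, seed = NULL) {
  stopifnot(all(c("species", "count") %in% names(counts)))
  prop <- rep(default_propensity, nrow(counts))
  m <- match(counts$species, names(destabilization_map))
  prop[!is.na(m)] <- destabilization_map[m[!is.na(m)]]
  if (any(prop < 0 | prop > 1)) stop("propensities must lie in [0, 1]", call. = FALSE)
  insol_counts <- with_seed(seed, {
    vapply(seq_len(nrow(counts)), function(i) {
      n <- counts$count[i]
      if (n > .Machine$integer.max) {
        round(stats::rnorm(1, n * prop[i], sqrt(n * prop[i] * (1 - prop[i]))))
      } else {
        stats::rbinom(1, as.integer(n), prop[i])
      }
    }, numeric(1))
  })
  soluble <- insoluble <- counts
  insoluble$count <- insol_counts
  soluble$count <- counts$count - insol_counts
  list(soluble = soluble, insoluble = insoluble)
}
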