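#' Simulate a cluster experiment across a titration
#'
#' High-level wrapper tying the generator together for one error cluster:
#' builds the substitution specs, derives the drug parameters from a preset
#' (anchored at the cluster's geometry when the preset states an observable
#' at that distance), draws traversal counts per concentration and emits
#' replicate intensity tables.
#'
#' @param aga Preset name (see [aga_presets()]) or an `aga_params` object.
#' @param substitutions data.frame of substitution specs on `protein`
#'   (rows from [substitution_spec()]), N- to C-terminal.
#' @param protein `protein_record`; defaults to [example_protein()].
#' @param concentrations Titration points (micromolar).
#' @param config `sim_config`.
#' @param baseline Also simulate an untreated (concentration 0) control
#'   table, used for background correction of the estimators.
#' @param ... Passed to [cluster_params()] (e.g. `efnext`, `d_anchor`).
#' @return List with elements `tables` (per-concentration intensity
#'   tables), `baseline` (untreated control table or `NULL`), `params`,
#'   `substitutions`, `species` (named character vector with entries
#'   `first`, `second`, ..., `cluster`).
#' @export
#' @examples
#' prot <- example_protein()
#' subs <- rbind(substitution_spec(prot, 242, "D"),
#'               substitution_spec(prot, 244, "D"))
#' sim <- simulate_cluster_titration("Apr", subs, prot,
#'                                   config = sim_config(n_ribosomes = 1e6, seed = 1))
simulate_cluster_titration <- function(aga, substitutions,
                                       protein = example_protein(),
                                       concentrations = c(0.5, 1, 2, 4, 8),
                                       config = sim_config(), baseline = TRUE,
                                       ...) {
  stopifnot(nrow(substitutions) >= 1L)
  positions <- substitutions$position
  stopifnot(!is.unsorted(positions, strictly = TRUE))
  params <- cluster_params(aga, positions, ...)
  labels <- substitutions$label
  names(labels) <- as.character(positions)
  tables <- simulate_titration(protein, params, concentrations, config,
                               labels = labels)
  base_tab <- NULL
  if (isTRUE(baseline)) {
    cfg0 <- config
    if (!is.null(config$seed)) cfg0$seed <- config$seed + 555L
    cnt0 <- sample_counts(protein, params, cfg0, concentration = 0,
                          labels = labels)
    base_tab <- emit_intensity_table(
      cnt0, cfg0, condition = list(aga = params$name, concentration = 0),
      seed = if (is.null(cfg0$seed)) NULL else cfg0$seed + 1L)
  }
  species <- c(labels, cluster = paste(labels, collapse = "+"))
  names(species)[seq_along(positions)] <-
    c("first", "second", "third", "fourth")[seq_along(positions)]
  list(tables = tables, baseline = base_tab, params = params,
       substitutions = substitutions, species = species)
}

#' Estimate the next-error frequency from simulated (or imported) tables
#'
#' Applies [compute_ef()] per condition to the first-error and cluster
#' species and combines them with the requested estimator: `"ratio"`
#' computes the cluster/first-error frequency ratio per condition and
#' reports the median across conditions; `"slope"` fits the through-origin
#' regression of cluster frequency on first-error frequency across
#' conditions ([efnext_slope()]).
#'
#' When an untreated control table is supplied, each species' error
#' frequency is background-corrected by subtracting its frequency in the
#' control before forming ratios (clipped at zero). Drug-independent
#' baseline errors contribute to the single-error species at every dose and
#' would otherwise dilute the conditional statistic at low doses; measuring
#' against untreated controls is the standard guard against this.
#'
#' @param tables List of `intensity_table` objects (e.g. one per titration
#'   point).
#' @param first,cluster Species names of the single-first-error and cluster
#'   peptides.
#' @param parent Species name of the correct peptide.
#' @param estimator `"ratio"` or `"slope"`.
#' @param baseline Optional untreated-control `intensity_table` for
#'   background correction.
#' @return List with `efnext`, `estimator`, and `by_condition` (data.frame
#'   of per-condition `ef_first`, `ef_cluster`, `efnext`); the slope
#'   estimator also reports `se`.
#' @export
efnext_from_tables <- function(tables, first, cluster, parent = "correct",
                               estimator = c("ratio", "slope"),
                               baseline = NULL) {
  estimator <- match.arg(estimator)
  if (inherits(tables, "intensity_table")) tables <- list(tables)
  bg1 <- bgc <- 0
  if (!is.null(baseline)) {
    b1 <- compute_ef(baseline, first, parent = parent)
    bc <- compute_ef(baseline, cluster, parent = parent)
    if (is.finite(b1$ef) && !isTRUE(b1$upper_limit)) bg1 <- b1$ef
    if (is.finite(bc$ef) && !isTRUE(bc$upper_limit)) bgc <- bc$ef
  }
  rows <- do.call(rbind, lapply(tables, function(tab) {
    ef1 <- max(compute_ef(tab, first, parent = parent)$ef - bg1, 0)
    efc <- max(compute_ef(tab, cluster, parent = parent)$ef - bgc, 0)
    data.frame(ef_first = ef1, ef_cluster = efc, efnext = efc / ef1)
  }))
  rownames(rows) <- NULL
  if (estimator == "ratio") {
    list(efnext = stats::median(rows$efnext, na.rm = TRUE),
         estimator = "ratio", by_condition = rows)
  } else {
    sl <- efnext_slope(rows)
    list(efnext = sl$efnext, se = sl$se, estimator = "slope",
         by_condition = rows)
  }
}

#' Simulate the distance dependence of consecutive errors
#'
#' For every inter-error distance d, simulates several two-error clusters
#' (distinct peptides of a synthetic protein) with the query drug and with
#' the flat-profile reference drug, and measures the conditional next-error
#' frequency of each by the ratio estimator. The result feeds
#' [build_distance_profile()] and [fit_retention()].
#'
#' The microscopic bound-state misreading probability of each drug is fixed
#' once from its preset anchor; only the geometry (d) varies, so the decay
#' of the measured values with d reflects drug retention, not parameter
#' changes.
#'
#' @param aga Query preset name.
#' @param reference Reference preset name (near-flat profile).
#' @param d_values Distances to probe.
#' @param clusters_per_d Number of distinct cluster geometries per distance.
#' @param concentration Nominal concentration for all simulations.
#' @param config `sim_config`; sub-seeds are derived from `config$seed`.
#' @return data.frame with columns `aga`, `d`, `cluster`, `efnext`.
#' @export
simulate_distance_profile <- function(aga, reference = "Str", d_values = 0:6,
                                      clusters_per_d = 3L, concentration = 8,
                                      config = sim_config()) {
  period <- 12L
  stopifnot(max(d_values) + 3L <= period)
  n_pep <- clusters_per_d
  prot_len <- period * (n_pep + 2L)
  out <- list()
  run <- 0L
  ## pin each drug's bound-state misreading rate to its first preset anchor:
  ## the microscopic rate must not change with the simulated geometry
  anchor <- lapply(stats::setNames(nm = c(aga, reference)), function(drug) {
    a <- aga_presets(drug)$anchors
    list(efnext = a$efnext[1], d = a$d[1])
  })
  for (drug in c(aga, reference)) {
    for (d in d_values) {
      for (j in seq_len(n_pep)) {
        run <- run + 1L
        s <- period * j  # cleavage site; peptide j+1 spans s+1 .. s+period
        p1 <- s + 2L
        p2 <- p1 + d + 1L
        res <- stats::setNames(c("E", "E"), c(p1, p2))
        prot <- synthetic_protein(length = prot_len, period = period,
                                  residues = res, id = sprintf("DP%d", j))
        subs <- rbind(substitution_spec(prot, p1, "D"),
                      substitution_spec(prot, p2, "D"))
        cfg <- config
        if (!is.null(config$seed)) cfg$seed <- config$seed + 13L * run
        params <- cluster_params(drug, c(p1, p2),
                                 efnext = anchor[[drug]]$efnext,
                                 d_anchor = anchor[[drug]]$d)
        labels <- stats::setNames(subs$label, subs$position)
        cnt <- sample_counts(prot, params, cfg, concentration = concentration,
                             labels = labels)
        tab <- emit_intensity_table(cnt, cfg,
                                    condition = list(aga = params$name, d = d),
                                    seed = if (is.null(cfg$seed)) NULL else cfg$seed + 1L)
        cfg0 <- cfg
        if (!is.null(cfg$seed)) cfg0$seed <- cfg$seed + 7L
        cnt0 <- sample_counts(prot, params, cfg0, concentration = 0,
                              labels = labels)
        tab0 <- emit_intensity_table(cnt0, cfg0,
                                     condition = list(aga = params$name, d = d),
                                     seed = if (is.null(cfg0$seed)) NULL else cfg0$seed + 1L)
        est <- efnext_from_tables(tab, first = subs$label[1],
                                  cluster = paste(subs$label, collapse = "+"),
                                  baseline = tab0)
        out[[run]] <- data.frame(aga = params$name, d = d, cluster = j,
                                 efnext = est$efnext, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
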