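#' Build a reference-normalized distance profile
#'
#' Distance profiles describe how the conditional next-error frequency
#' decays with the number of correct residues between the two errors. To
#' cancel peptide-specific ionization and detectability factors, each
#' drug's value at distance d is divided by the reference drug's value at
#' the same d (the reference, streptomycin by default, has a near-flat
#' profile and is set to 1). Two scaling conventions are exposed:
#' `"reference"` (default) anchors only the reference at 1, so the other
#' drugs' absolute level relative to the reference is retained;
#' `"per_aga"` additionally rescales every drug's curve to 1 at its
#' smallest measured distance, retaining only the decay shape.
#'
#' Multiple clusters at the same distance are aggregated as mean +/- SD.
#'
#' @param efnext_by_cluster data.frame with columns `aga`, `d`, `efnext`
#'   (one row per measured cluster).
#' @param reference Name of the reference drug (must be measured at every
#'   distance used; other drugs' points without a reference at that d are
#'   dropped with a warning).
#' @param scaling `"reference"` or `"per_aga"`.
#' @return data.frame of class `distance_profile`: `aga`, `d`,
#'   `efnext_norm`, `sd`, `n`, with attributes `reference` and `scaling`.
#' @export
build_distance_profile <- function(efnext_by_cluster, reference = "Str",
                                   scaling = c("reference", "per_aga")) {
  scaling <- match.arg(scaling)
  stopifnot(all(c("aga", "d", "efnext") %in% names(efnext_by_cluster)))
  df <- efnext_by_cluster
  ref <- df[df$aga == reference, , drop = FALSE]
  if (nrow(ref) == 0L)
    stop(sprintf("reference drug '%s' not present", reference), call. = FALSE)
  ref_mean <- tapply(ref$efnext, ref$d, mean)
  have <- df$d %in% as.numeric(names(ref_mean))
  if (any(!have)) {
    warning(sprintf("dropping %d point(s) at distances without a %s reference",
                    sum(!have), reference))
    df <- df[have, , drop = FALSE]
  }
  df$norm <- df$efnext / unname(ref_mean[as.character(df$d)])
  agg <- do.call(rbind, lapply(split(df, list(df$aga, df$d), drop = TRUE),
    function(g) data.frame(aga = g$aga[1], d = g$d[1],
                           efnext_norm = mean(g$norm),
                           sd = if (nrow(g) > 1L) stats::sd(g$norm) else NA_real_,
                           n = nrow(g), stringsAsFactors = FALSE)))
  if (scaling == "per_aga") {
    for (a in unique(agg$aga)) {
      sel <- agg$aga == a
      anchor <- agg$efnext_norm[sel][which.min(agg$d[sel])]
      agg$efnext_norm[sel] <- agg$efnext_norm[sel] / anchor
      agg$sd[sel] <- agg$sd[sel] / anchor
    }
  }
  agg <- agg[order(agg$aga, agg$d), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("distance_profile", "data.frame"),
            reference = reference, scaling = scaling)
}

#' Fit the retention probability from a distance profile
#'
#' Fits the exponential decay `N(d) = c * q^d` to a drug's normalized
#' distance profile by nonlinear least squares with `q` constrained to
#' `[0, 1]`. Because the profile is already a ratio to the reference at the
#' matched distance, the shared `d + 1` translocation offset cancels and
#' the exponent is `d`. `q` estimates the per-translocation probability
#' that the drug stays bound to the ribosome. The confidence interval is a
#' parametric bootstrap over the points' uncertainties (points with no SD
#' are kept fixed).
#'
#' @param profile `distance_profile` (or data.frame with `aga`, `d`,
#'   `efnext_norm`, optionally `sd`).
#' @param aga Drug to fit; may be omitted if only one is present.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param level Confidence level.
#' @return List of class `retention_fit`: `aga`, `q`, `c`, `ci`
#'   (length-2), `n_points`, `boot_q`, `degenerate`.
#' @export
fit_retention <- function(profile, aga = NULL, n_boot = 200L, seed = NULL,
                          level = 0.95) {
  stopifnot(all(c("d", "efnext_norm") %in% names(profile)))
  if (is.null(aga)) {
    drugs <- unique(profile$aga)
    if (length(drugs) != 1L)
      stop("profile contains several drugs; pick one with 'aga'", call. = FALSE)
    aga <- drugs
  }
  pts <- profile[profile$aga == aga, , drop = FALSE]
  pts <- pts[order(pts$d), , drop = FALSE]
  if (length(unique(pts$d)) < 3L)
    stop("need at least 3 distinct distances to fit retention", call. = FALSE)
  y <- pts$efnext_norm; d <- pts$d
  sds <- if ("sd" %in% names(pts)) pts$sd else rep(NA_real_, nrow(pts))
  fit_one <- function(yy) {
    if (diff(range(yy)) < 1e-12) return(c(q = 1, c = mean(yy)))
    ft <- minpack.lm::nlsLM(yy ~ c0 * q^d,
                            start = list(c0 = max(yy), q = 0.7),
                            lower = c(0, 0), upper = c(Inf, 1),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(ft)
    c(q = unname(co[["q"]]), c = unname(co[["c0"]]))
  }
  est <- fit_one(y)
  degenerate <- diff(range(y)) < 1e-12
  boot_q <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      yy <- y + ifelse(is.na(sds) | sds <= 0, 0, stats::rnorm(length(y), 0, sds))
      yy[yy < 0] <- 0
      out <- tryCatch(fit_one(yy)[["q"]], error = function(e) NA_real_)
      out
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- if (all(is.na(boot_q))) c(NA_real_, NA_real_) else
    unname(stats::quantile(boot_q, c(alpha, 1 - alpha), na.rm = TRUE))
  if (degenerate) ci[2] <- 1
  structure(list(aga = aga, q = est[["q"]], c = est[["c"]], ci = ci,
                 n_points = nrow(pts), boot_q = boot_q,
                 degenerate = degenerate, level = level),
            class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf("retention_fit '%s': q = %.3f (%d%% CI %.3f-%.3f), %d points%s\n",
              x$aga, x$q, round(100 * x$level), x$ci[1], x$ci[2], x$n_points,
              if (x$degenerate) " [degenerate: flat profile]" else ""))
  invisible(x)
}

#' Classify an aminoglycoside into group I or group II
#'
#' Bactericidal aminoglycosides fall into two phenotypic groups: group I
#' drugs (streptomycin-like) are potent inducers of single misreading
#' events but make only weak, long-range clusters; group II drugs
#' (apramycin/sisomycin-like) induce moderate single errors but, once
#' bound, misread following codons at high frequency with a steep distance
#' decay. The rule is a two-dimensional threshold on the median single
#' error frequency and the adjacent-cluster conditional next-error
#' frequency.
#'
#' @param median_single_ef Median single-substitution error frequency at the
#'   drug's working concentration.
#' @param efnext_adjacent Conditional next-error frequency for an adjacent
#'   (d = 0) cluster.
#' @param efnext_cutoff Adjacent next-error frequency at or above which the
#'   drug is group II.
#' @param ef_single_min Minimum single error frequency required to call any
#'   group (below it the drug shows no misreading action).
#' @return `"I"`, `"II"` or `"unclassified"`.
#' @export
classify_aga <- function(median_single_ef, efnext_adjacent,
                         efnext_cutoff = 0.2, ef_single_min = 1e-5) {
  if (is.na(median_single_ef) || is.na(efnext_adjacent)) return("unclassified")
  if (median_single_ef < ef_single_min && efnext_adjacent < efnext_cutoff)
    return("unclassified")
  if (efnext_adjacent >= efnext_cutoff) "II" else "I"
}
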