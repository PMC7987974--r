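#' Enrichment of a peptide species in the insoluble fraction
#'
#' The aggregation readout: the species' insoluble/soluble intensity ratio,
#' normalized by the median insoluble/soluble ratio of the correct peptides
#' in the same replicates. Enrichment of 1 means the missense species
#' partitions like the bulk of correctly translated protein; values above 1
#' indicate aggregation. Significance is a t-test on the log-ratios across
#' replicates.
#'
#' @param insoluble,soluble Per-replicate intensities of the species.
#' @param correct_insoluble,correct_soluble Matrices (peptides x replicates)
#'   of correct-peptide intensities in the two fractions.
#' @param alternative t-test sidedness (`"two.sided"` default; `"greater"`
#'   mirrors a one-tailed aggregation test).
#' @return List with `enrichment`, `p_value`, `upper_limit` (set when a
#'   soluble intensity is zero and the ratio is only bounded from below),
#'   `per_replicate`.
#' @export
aggregation_enrichment <- function(insoluble, soluble,
                                   correct_insoluble, correct_soluble,
                                   alternative = "two.sided") {
  stopifnot(length(insoluble) == length(soluble))
  correct_insoluble <- as.matrix(correct_insoluble)
  correct_soluble <- as.matrix(correct_soluble)
  stopifnot(ncol(correct_insoluble) == length(insoluble),
            all(dim(correct_insoluble) == dim(correct_soluble)))
  upper <- any(soluble == 0, na.rm = TRUE)
  ratio <- insoluble / soluble
  ref <- apply(correct_insoluble / correct_soluble, 2, stats::median, na.rm = TRUE)
  enr <- ratio / ref
  p <- NA_real_
  finite <- is.finite(log(enr))
  if (sum(finite) >= 2L)
    p <- tryCatch(stats::t.test(log(enr[finite]), mu = 0,
                                alternative = alternative)$p.value,
                  error = function(e) NA_real_)  # constant log-ratios
  list(enrichment = mean(enr[is.finite(enr)]), p_value = p,
       upper_limit = upper, per_replicate = enr)
}

#' Thermostability curve of a missense species
#'
#' Per temperature, the missense/parent intensity ratio from a stepwise
#' thermal denaturation, rescaled so the anchor temperature equals 1. A
#' destabilized substitution loses soluble signal faster than its parent
#' and gives a curve falling below 1.
#'
#' @param raw Named numeric vector: temperature (deg C, as names) ->
#'   missense intensity.
#' @param parent Named numeric vector of the parental peptide at the same
#'   temperatures.
#' @param anchor Anchor temperature whose ratio is set to 1.
#' @return data.frame of class `stability_curve`: `temperature`, `value`.
#' @export
thermostability_normalize <- function(raw, parent, anchor = 41) {
  temps <- as.numeric(names(raw))
  stopifnot(!anyNA(temps), identical(names(raw), names(parent)))
  if (!any(temps == anchor))
    stop(sprintf("anchor temperature %g not measured", anchor), call. = FALSE)
  ratio <- raw / parent
  value <- unname(ratio / ratio[[as.character(anchor)]])
  structure(data.frame(temperature = temps, value = value),
            class = c("stability_curve", "data.frame"), anchor = anchor)
}

#' Filter proteins by quantification presence
#'
#' Keeps rows (proteins) quantified in at least `min_fraction` of all
#' samples (columns), the confidence cut applied before imputation.
#'
#' @param mat Numeric matrix, proteins x samples, `NA` = not quantified.
#' @param min_fraction Minimum fraction of non-missing samples.
#' @return The filtered matrix.
#' @export
presence_filter <- function(mat, min_fraction = 0.6) {
  mat <- as.matrix(mat)
  keep <- rowMeans(!is.na(mat)) >= min_fraction
  mat[keep, , drop = FALSE]
}

#' Impute missing values from a downshifted normal distribution
#'
#' Missing (not-quantified) log-intensities are drawn per sample from a
#' normal law modeled on that sample's observed distribution, narrowed to
#' `width` times the sample SD and shifted down by `downshift` SDs --
#' missing values in label-free proteomics arise mostly from low-abundance
#' censoring, so imputed values should sit in the left tail. Observed
#' values are never altered.
#'
#' @param mat Log-scale intensity matrix, proteins x samples.
#' @param width Imputation SD as a fraction of the sample SD.
#' @param downshift Shift of the imputation mean, in sample SDs.
#' @param seed RNG seed.
#' @return Matrix with missing values filled in.
#' @export
impute_missing <- function(mat, width = 0.3, downshift = 1.8, seed = NULL) {
  mat <- as.matrix(mat)
  with_seed(seed, {
    for (j in seq_len(ncol(mat))) {
      miss <- is.na(mat[, j])
      if (!any(miss)) next
      obs <- mat[!miss, j]
      if (length(obs) < 2L)
        stop(sprintf("sample %d has fewer than 2 observed values; cannot model its distribution", j),
             call. = FALSE)
      mu <- mean(obs); s <- stats::sd(obs)
      mat[miss, j] <- stats::rnorm(sum(miss), mu - downshift * s, width * s)
    }
    mat
  })
}

#' Scale a profile to the unit interval
#'
#' Rescales a protein's (or substitution's) intensities across biological
#' states to `[0, 1]` by `(x - min) / (max - min)`, the normalization used
#' before comparing response profiles. A constant vector is degenerate: all
#' zeros are returned with attribute `degenerate = TRUE`.
#'
#' @param x Numeric vector with at least 2 values.
#' @return Scaled vector (attribute `degenerate` flags constant input).
#' @export
scale_to_interval <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0)
    return(structure(rep(0, length(x)), degenerate = TRUE))
  structure((x - rng[1]) / diff(rng), degenerate = FALSE)
}
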