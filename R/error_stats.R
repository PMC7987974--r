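#' Error frequency of a missense peptide species
#'
#' The error frequency E_f of a substitution (or substitution pattern) is
#' the ratio of the integrated intensity of the missense peptide species to
#' that of its correct parental peptide, computed per replicate and
#' aggregated by the median. When the parental peptide is missing in a
#' replicate, the median intensity of all correct peptide species in that
#' replicate is used instead and the record is flagged `median-fallback`.
#' Missing missense intensities are never treated as zeros: they are imputed
#' at the detection floor and the record is flagged as an upper limit. A
#' species entirely absent from the table yields a missing (`NA`) frequency.
#'
#' @param table `intensity_table` (long form).
#' @param species Species name of the missense peptide.
#' @param parent Species name of the correct parental peptide.
#' @param condition Optional named list restricting rows (column = value).
#' @param correct_species Character vector of species treated as "correct
#'   peptides" for the median fallback; defaults to `parent`.
#' @param detection_floor Floor used for upper-limit imputation; defaults to
#'   the table's `detection_floor` attribute, else the smallest observed
#'   intensity.
#' @return One-row data.frame: `species`, `ef`, `n_replicates`,
#'   `parent_source` (`"measured"` or `"median-fallback"`), `upper_limit`.
#' @export
compute_ef <- function(table, species, parent = "correct", condition = NULL,
                       correct_species = parent, detection_floor = NULL) {
  stopifnot(is.data.frame(table),
            all(c("species", "replicate", "intensity") %in% names(table)))
  df <- table
  for (nm in names(condition)) df <- df[df[[nm]] == condition[[nm]], , drop = FALSE]
  floor <- detection_floor %||% attr(table, "detection_floor") %||%
    min(df$intensity, na.rm = TRUE)
  reps <- sort(unique(df$replicate))
  if (!any(df$species == species)) {
    return(data.frame(species = species, ef = NA_real_, n_replicates = 0L,
                      parent_source = NA_character_, upper_limit = NA,
                      stringsAsFactors = FALSE))
  }
  vals <- numeric(0); fallback <- FALSE; imputed <- 0L; used <- 0L
  for (r in reps) {
    sub <- df[df$replicate == r, , drop = FALSE]
    i_m <- sub$intensity[sub$species == species]
    i_p <- sub$intensity[sub$species == parent]
    i_m <- if (length(i_m)) i_m[1] else NA_real_
    i_p <- if (length(i_p)) i_p[1] else NA_real_
    if (is.na(i_p)) {
      corr <- sub$intensity[sub$species %in% correct_species]
      i_p <- stats::median(corr, na.rm = TRUE)
      if (is.finite(i_p)) fallback <- TRUE
    }
    if (!is.finite(i_p)) next
    used <- used + 1L
    if (is.na(i_m)) {
      vals <- c(vals, floor / i_p)
      imputed <- imputed + 1L
    } else {
      vals <- c(vals, i_m / i_p)
    }
  }
  if (used == 0L) {
    return(data.frame(species = species, ef = NA_real_, n_replicates = 0L,
                      parent_source = NA_character_, upper_limit = NA,
                      stringsAsFactors = FALSE))
  }
  data.frame(species = species, ef = stats::median(vals), n_replicates = used,
             parent_source = if (fallback) "median-fallback" else "measured",
             upper_limit = imputed > 0L, stringsAsFactors = FALSE)
}

#' Consistent-induction filter against chemical background
#'
#' Identifications whose signal is not consistently induced more than
#' `fold`-fold by treatment (relative to the untreated control) are dropped:
#' constant-intensity features are chemical background (isobaric oxidations,
#' deamidations), not misreading products.
#'
#' @param treated,untreated Per-replicate intensity vectors of the same
#'   species (paired by position; missing treated values fail the test,
#'   missing untreated values pass it for that replicate).
#' @param fold Induction threshold.
#' @return `TRUE` (keep) if induction exceeds `fold` in every replicate.
#' @export
induction_filter <- function(treated, untreated, fold = 2) {
  stopifnot(length(treated) == length(untreated), fold > 0)
  ok <- mapply(function(tr, un) {
    if (is.na(tr)) return(FALSE)
    if (is.na(un)) return(TRUE)
    tr > fold * un
  }, treated, untreated)
  all(ok)
}

#' Expected cluster frequency under independent errors
#'
#' If misreading events were stochastic and independent, the frequency of a
#' cluster would be the product of the single error frequencies of its
#' members. Upper-limit flags on any input propagate to the result.
#'
#' @param efs Numeric vector of single error frequencies.
#' @param upper_limit Logical vector of upper-limit flags (recycled).
#' @return List with `value` (the product) and `upper_limit`.
#' @export
stochastic_expectation <- function(efs, upper_limit = FALSE) {
  stopifnot(is.numeric(efs), length(efs) >= 1L, all(efs >= 0))
  list(value = prod(efs), upper_limit = any(rep_len(upper_limit, length(efs))))
}

#' Error amplification over the stochastic expectation
#'
#' `A = ef_cluster / (ef_first * ef_second)`: how many times more frequent
#' the observed cluster is than the product of its single-error frequencies.
#' Independent errors give A = 1; drug retention on the ribosome gives
#' A >> 1. The identity `A = efnext / ef_second` links amplification to the
#' conditional next-error frequency.
#'
#' @param ef_cluster,ef_first,ef_second Error frequencies (> 0; a zero
#'   denominator yields `Inf` with a warning, to be read as an upper-limit
#'   artifact).
#' @return Dimensionless ratio.
#' @export
amplification <- function(ef_cluster, ef_first, ef_second) {
  stopifnot(ef_cluster >= 0, ef_first >= 0, ef_second >= 0)
  denom <- ef_first * ef_second
  if (denom == 0) {
    warning("zero denominator: amplification is an upper-limit artifact")
    return(Inf)
  }
  ef_cluster / denom
}

#' Assemble the per-cluster statistics record
#'
#' @param pattern Cluster label.
#' @param ef_first,ef_second,ef_cluster Measured error frequencies.
#' @param d Inter-error distance(s), correct residues between consecutive
#'   errors.
#' @param estimator One of `"slope"`, `"ratio_absolute"`, `"ratio_lfq"`.
#' @return One-row data.frame with `ef_first`, `ef_second`, `ef_cluster`,
#'   `amplification`, `efnext`, `estimator`, `d`.
#' @export
cluster_stat <- function(pattern, ef_first, ef_second, ef_cluster, d,
                         estimator = c("ratio_absolute", "slope", "ratio_lfq")) {
  estimator <- match.arg(estimator)
  data.frame(pattern = pattern, ef_first = ef_first, ef_second = ef_second,
             ef_cluster = ef_cluster,
             amplification = amplification(ef_cluster, ef_first, ef_second),
             efnext = ef_cluster / ef_first,
             estimator = estimator, d = paste(d, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Next-error frequency as a through-origin slope
#'
#' Across a titration or time course, the cluster frequency depends linearly
#' on the frequency of the first misreading event; the slope of that line is
#' the conditional next-error frequency. The regression is through the
#' origin: with no first error there can be no cluster (translation is
#' vectorial).
#'
#' @param series data.frame with columns `ef_first` and `ef_cluster`
#'   (>= 3 points).
#' @return List with `efnext` (slope), `se` and `n`.
#' @export
efnext_slope <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("ef_first", "ef_cluster") %in% names(series)))
  series <- series[stats::complete.cases(series[, c("ef_first", "ef_cluster")]), ]
  if (nrow(series) < 3L)
    stop("need at least 3 points for the slope estimator", call. = FALSE)
  if (all(series$ef_cluster == 0))
    return(list(efnext = 0, se = 0, n = nrow(series)))
  fit <- stats::lm(ef_cluster ~ 0 + ef_first, data = series)
  ## noiseless input gives a perfect fit; its SE of 0 is meaningful here
  co <- suppressWarnings(summary(fit))$coefficients
  list(efnext = unname(co[1, 1]), se = unname(co[1, 2]), n = nrow(series))
}

#' Next-error frequency as a ratio of error frequencies
#'
#' Point estimate from absolute quantification: the ratio of the cluster's
#' error frequency to that of its first error. For three-error clusters the
#' third-step value is the frequency of the triple over that of its leading
#' double.
#'
#' @param ef_cluster,ef_first Error frequencies; `ef_first` must be > 0.
#' @param first_upper_limit If the first error's frequency is only an upper
#'   limit, the ratio is a lower limit and is flagged as such.
#' @return List with `efnext` and `lower_limit`.
#' @export
efnext_ratio <- function(ef_cluster, ef_first, first_upper_limit = FALSE) {
  stopifnot(ef_cluster >= 0)
  if (!is.finite(ef_first) || ef_first <= 0)
    stop("ef_first must be positive", call. = FALSE)
  list(efnext = ef_cluster / ef_first, lower_limit = isTRUE(first_upper_limit))
}

#' Next-error frequency from label-free intensities
#'
#' The ratio of the integrated intensity of the cluster peptide to that of
#' the peptide carrying only the first error, valid under the label-free
#' assumption of identical ionization. The estimate is refused when the
#' cluster alters the tryptic cleavage pattern, and flagged invalid when the
#' following error changes the peptide's charge-state distribution (gain or
#' loss of a basic residue, e.g. Y -> H), since intensities then no longer
#' track abundances.
#'
#' @param cluster_intensity,first_error_intensity Integrated intensities in
#'   the same sample, same peptide backbone.
#' @param cleavage_altered Does the following substitution create or destroy
#'   a cleavage site?
#' @param following_from,following_to Optional residues of the following
#'   error, used for the charge-state exclusion.
#' @return List with `efnext` (`NA` when invalid), `valid`, `reason`.
#' @export
efnext_lfq <- function(cluster_intensity, first_error_intensity,
                       cleavage_altered = FALSE,
                       following_from = NULL, following_to = NULL) {
  if (isTRUE(cleavage_altered))
    stop("LFQ next-error estimate refused: the substitution alters the tryptic cleavage pattern",
         call. = FALSE)
  basic <- c("K", "R", "H")
  if (!is.null(following_from) && !is.null(following_to) &&
      xor(toupper(following_from) %in% basic, toupper(following_to) %in% basic)) {
    return(list(efnext = NA_real_, valid = FALSE,
                reason = sprintf("charge-state change (%s -> %s)",
                                 following_from, following_to)))
  }
  stopifnot(first_error_intensity > 0, cluster_intensity >= 0)
  list(efnext = cluster_intensity / first_error_intensity, valid = TRUE,
       reason = NA_character_)
}
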