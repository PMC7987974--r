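#' Generative parameters for one aminoglycoside
#'
#' The simulator's two-state model of a translating ribosome is controlled
#' by three quantities: `beta_scale`, the per-codon probability that a free
#' drug molecule binds the elongating ribosome per micromolar of nominal
#' concentration (binding can occur at any codon, and rebinding after
#' drop-off is allowed); `q`, the per-translocation retention probability
#' that a bound drug stays bound; and `misread`, the per-position probability
#' that a bound ribosome misincorporates the designated substitution at that
#' codon. Codons without an entry in `misread` always decode correctly in
#' the bound state, which keeps the pattern space enumerable and mirrors
#' targeted MS assays that monitor a fixed set of missense species.
#'
#' @param name Drug name.
#' @param q Retention probability in `[0, 1]`.
#' @param misread Named numeric vector: names are 1-based codon positions,
#'   values bound-state misreading probabilities in `[0, 1]`.
#' @param beta_scale Per-codon binding probability per micromolar.
#' @return An object of class `aga_params`.
#' @export
aga_params <- function(name, q, misread, beta_scale = 1e-5) {
  stopifnot_scalar_prob(q, "q")
  stopifnot(is.numeric(beta_scale), length(beta_scale) == 1L, beta_scale >= 0)
  if (length(misread)) {
    stopifnot(!is.null(names(misread)), !anyNA(as.integer(names(misread))))
    if (any(misread < 0 | misread > 1))
      stop("misread probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, q = q,
                 misread = misread[order(as.integer(names(misread)))],
                 beta_scale = beta_scale),
            class = "aga_params")
}

#' @export
print.aga_params <- function(x, ...) {
  cat(sprintf("aga_params '%s': q = %g, beta_scale = %g/uM, %d misreadable position(s)\n",
              x$name, x$q, x$beta_scale, length(x$misread)))
  invisible(x)
}

#' Per-codon binding probability at a nominal concentration
#'
#' @param params `aga_params`.
#' @param concentration Nominal drug concentration (micromolar).
#' @return Probability, capped at 1.
#' @export
beta_at <- function(params, concentration) {
  stopifnot(inherits(params, "aga_params"), concentration >= 0)
  min(1, params$beta_scale * concentration)
}

#' Shipped aminoglycoside presets
#'
#' Reads the preset table from the package configuration: per drug, the
#' retention probability `q` and one or more anchor observables -- the
#' conditional next-error frequency `efnext` measured for a reference
#' cluster at inter-error distance `d`.
#'
#' @param name Optional drug name; if given, returns that preset only.
#' @return A list of presets (or a single preset), each with elements
#'   `name`, `group`, `q`, `anchors` (data.frame `efnext`, `d`, `example`)
#'   and `beta_scale`.
#' @export
#' @examples
#' aga_presets("Apr")$q
aga_presets <- function(name = NULL) {
  path <- system.file("extdata", "aga_presets.json", package = "agaclust",
                      mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  presets <- lapply(seq_len(nrow(cfg$presets)), function(i) {
    list(name = cfg$presets$name[i], group = cfg$presets$group[i],
         q = cfg$presets$q[i],
         anchors = cfg$presets$anchors[[i]],
         beta_scale = cfg$beta_scale_per_uM)
  })
  names(presets) <- cfg$presets$name
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s' (available: %s)", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  presets[[name]]
}

#' Back-solve the bound-state misreading probability from an observable
#'
#' Presets specify the observable conditional next-error frequency
#' `efnext` at a stated inter-error distance `d`, because published values
#' are observables, not microscopic rates. Under the two-state model, the
#' ratio estimator measured from peptide species intensities is
#' \deqn{E_f^{next} = c / (1 - c), \qquad c = m w \, q^{d+1},}
#' where \eqn{m w} is the bound-state misreading probability at the second
#' position and \eqn{q^{d+1}} accounts for the `d + 1` translocations
#' between the two decoding events (the `1 - c` term arises because the
#' single-first-error species requires the second codon to decode
#' correctly). This inverts that relation:
#' \deqn{m w = \frac{E_f^{next} / (1 + E_f^{next})}{q^{d+1}}.}
#'
#' @param efnext Observable conditional next-error frequency (>= 0).
#' @param q Retention probability.
#' @param d Inter-error distance (correct residues between the two errors).
#' @return Bound-state misreading probability in `[0, 1]`.
#' @export
efnext_to_misread <- function(efnext, q, d) {
  stopifnot(is.numeric(efnext), length(efnext) == 1L, efnext >= 0)
  stopifnot_scalar_prob(q, "q")
  d <- as.integer(d)
  stopifnot(d >= 0L)
  mw <- (efnext / (1 + efnext)) / q^(d + 1L)
  if (!is.finite(mw) || mw > 1)
    stop(sprintf("efnext = %g at d = %d is unreachable with q = %g (needs misreading probability %g > 1)",
                 efnext, d, q, mw), call. = FALSE)
  mw
}

#' Build simulation parameters for one error cluster from a preset
#'
#' Assigns the first (N-terminal) position of the cluster a fixed
#' bound-state misreading probability (`misread_first`; the first error
#' marks where drug-bound decoding went wrong, and its exact value cancels
#' from every conditional statistic), and each following position the
#' probability back-solved from the preset's anchor observable via
#' [efnext_to_misread()]. By default the anchor whose distance matches the
#' simulated geometry is used when available, otherwise the preset's first
#' anchor.
#'
#' @param aga Preset name (see [aga_presets()]) or an `aga_params` object
#'   (returned unchanged).
#' @param positions Increasing integer positions of the cluster errors.
#' @param efnext,d_anchor Optional override of the anchor observable and its
#'   stated distance.
#' @param misread_first Bound-state misreading probability at the first
#'   cluster position.
#' @return An `aga_params` object.
#' @export
#' @examples
#' cluster_params("Apr", c(242, 244))
cluster_params <- function(aga, positions, efnext = NULL, d_anchor = NULL,
                           misread_first = 0.5) {
  if (inherits(aga, "aga_params")) return(aga)
  preset <- aga_presets(aga)
  positions <- sort(as.integer(positions))
  if (length(positions) < 1L) stop("need at least one position", call. = FALSE)
  if (is.null(efnext)) {
    anchors <- preset$anchors
    geom_d <- if (length(positions) >= 2L) positions[2L] - positions[1L] - 1L else NA_integer_
    pick <- if (!is.na(geom_d) && any(anchors$d == geom_d)) which(anchors$d == geom_d)[1L] else 1L
    efnext <- anchors$efnext[pick]
    d_anchor <- anchors$d[pick]
  } else if (is.null(d_anchor)) {
    stop("d_anchor must accompany an explicit efnext", call. = FALSE)
  }
  mw_next <- efnext_to_misread(efnext, preset$q, d_anchor)
  misread <- c(misread_first, rep(mw_next, length(positions) - 1L))
  names(misread) <- positions
  aga_params(preset$name, preset$q, misread, beta_scale = preset$beta_scale)
}
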