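#' Predict candidate error clusters from single-substitution frequencies
#'
#' Enumerates combinations of observed single substitutions that fall inside
#' one tryptic peptide, with at most `max_intervening` correct residues
#' between consecutive errors, and scores each candidate two ways:
#' \describe{
#'   \item{stochastic}{the product of the single error frequencies -- the
#'     expectation if errors were independent;}
#'   \item{aga_expected}{the frequency of the first (N-terminal) error times
#'     `efnext_prior` for every following error -- the expectation under
#'     drug-retention-driven consecutive misreading, which is what makes a
#'     candidate worth targeting.}
#' }
#' Candidates are ranked by `aga_expected`, descending.
#'
#' @param single_ef data.frame with columns `position` and `ef` (optionally
#'   `label`); all on `protein`.
#' @param protein A `protein_record`.
#' @param efnext_prior Assumed conditional next-error frequency.
#' @param max_intervening Maximum number of correct residues between
#'   consecutive errors in a candidate.
#' @param max_order Largest number of substitutions per candidate.
#' @return data.frame with columns `members`, `positions`, `peptide_start`,
#'   `peptide_end`, `order`, `d`, `stochastic`, `aga_expected`, sorted by
#'   `aga_expected` descending. Zero rows when `single_ef` is empty.
#' @export
predict_cluster_candidates <- function(single_ef, protein, efnext_prior,
                                       max_intervening = 13L, max_order = 3L) {
  stopifnot(inherits(protein, "protein_record"))
  stopifnot_scalar_prob(efnext_prior, "efnext_prior")
  empty <- data.frame(members = character(), positions = character(),
                      peptide_start = integer(), peptide_end = integer(),
                      order = integer(), d = character(),
                      stochastic = numeric(), aga_expected = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(single_ef) || nrow(single_ef) == 0L) return(empty)
  stopifnot(all(c("position", "ef") %in% names(single_ef)))
  single_ef$position <- as.integer(single_ef$position)
  if (is.null(single_ef$label))
    single_ef$label <- as.character(single_ef$position)
  dig <- tryptic_digest(protein$sequence, 0L)
  out <- list()
  for (p in seq_len(nrow(dig))) {
    inpep <- single_ef[single_ef$position >= dig$start[p] &
                       single_ef$position <= dig$end[p], , drop = FALSE]
    inpep <- inpep[order(inpep$position), , drop = FALSE]
    m <- nrow(inpep)
    if (m < 2L) next
    for (k in 2:min(max_order, m)) {
      combs <- utils::combn(m, k)
      for (ci in seq_len(ncol(combs))) {
        idx <- combs[, ci]
        pp <- inpep$position[idx]
        gaps <- diff(pp) - 1L
        if (any(gaps > max_intervening)) next
        out[[length(out) + 1L]] <- data.frame(
          members = paste(inpep$label[idx], collapse = "+"),
          positions = paste(pp, collapse = "+"),
          peptide_start = dig$start[p], peptide_end = dig$end[p],
          order = k, d = paste(gaps, collapse = ","),
          stochastic = prod(inpep$ef[idx]),
          aga_expected = inpep$ef[idx[1]] * efnext_prior^(k - 1L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$aga_expected, res$positions), , drop = FALSE]
  rownames(res) <- NULL
  res
}
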