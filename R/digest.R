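#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine or arginine except when the next residue is
#' proline. With `missed_cleavages = k`, every union of up to `k + 1`
#' adjacent fully-cleaved peptides is also returned.
#'
#' @param sequence Amino-acid sequence.
#' @param missed_cleavages Maximum number of missed cleavage sites.
#' @return A data.frame with columns `start`, `end` (1-based, inclusive),
#'   `sequence` and `n_missed`, ordered by start then span.
#' @export
#' @examples
#' tryptic_digest("MKAILR")   # MK | AILR
#' tryptic_digest("AKPGR")    # KP suppresses cleavage
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a non-empty character string", call. = FALSE)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1]]
  ## cleavage after position i: K/R at i, not followed by P
  sites <- which(aa[-n] %in% c("K", "R") & aa[-1] != "P")
  ends <- c(sites, n)
  starts <- c(1L, sites + 1L)
  k <- as.integer(missed_cleavages)
  out <- list()
  for (i in seq_along(starts)) {
    for (j in i:min(i + k, length(starts))) {
      out[[length(out) + 1L]] <- data.frame(
        start = starts[i], end = ends[j],
        sequence = substr(sequence, starts[i], ends[j]),
        n_missed = j - i, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Locate the tryptic peptide(s) carrying a set of substitutions
#'
#' Applies the substitutions to the protein, digests the mutated sequence
#' (no missed cleavages) and returns the peptide span(s) containing the
#' substituted positions. Substituting to or from K/R can create or destroy
#' a cleavage site; such spans are flagged `cleavage_altered` because their
#' intensities are not comparable with the parental peptide, and
#' intensity-ratio estimators must exclude them. Substitutions landing in
#' different peptides give a multi-span result (flagged), which is likewise
#' excluded from cluster statistics.
#'
#' @param protein A `protein_record`.
#' @param substitutions data.frame with columns `position` and `to_aa`
#'   (e.g. rows from [substitution_spec()]).
#' @return data.frame of spans with columns `start`, `end`, `sequence`
#'   (mutated), `cleavage_altered`, `multi_span`.
#' @export
peptide_for_substitutions <- function(protein, substitutions) {
  stopifnot(inherits(protein, "protein_record"),
            all(c("position", "to_aa") %in% names(substitutions)))
  pos <- as.integer(substitutions$position)
  if (any(duplicated(pos))) stop("duplicated substitution positions", call. = FALSE)
  mutated <- protein$sequence
  for (i in seq_along(pos)) {
    substr(mutated, pos[i], pos[i]) <- toupper(substitutions$to_aa[i])
  }
  wt_dig  <- tryptic_digest(protein$sequence, 0L)
  mut_dig <- tryptic_digest(mutated, 0L)
  hit <- vapply(seq_len(nrow(mut_dig)), function(r) {
    any(pos >= mut_dig$start[r] & pos <= mut_dig$end[r])
  }, logical(1))
  spans <- mut_dig[hit, , drop = FALSE]
  wt_key  <- paste(wt_dig$start, wt_dig$end)
  altered <- !(paste(spans$start, spans$end) %in% wt_key)
  spans$cleavage_altered <- altered
  spans$multi_span <- nrow(spans) > 1L
  spans$n_missed <- NULL
  rownames(spans) <- NULL
  spans
}
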