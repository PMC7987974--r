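#' Create a protein record
#'
#' Bundles an amino-acid sequence with an optional coding sequence. All
#' residue coordinates in the package are 1-based and inclusive on the
#' sequence as supplied (whether that is a mature or precursor form is the
#' caller's choice).
#'
#' @param id Protein identifier.
#' @param sequence One-letter amino-acid sequence.
#' @param cds Optional coding sequence (RNA or DNA alphabet) whose
#'   translation must equal `sequence`.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, cds = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  if (!is.null(cds)) {
    cds <- chartr("Tt", "Uu", toupper(cds))
    if (translate_cds(cds) != sequence)
      stop("translation of cds does not match the amino-acid sequence", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, cds = cds),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein_record '%s': %d aa%s\n", x$id, nchar(x$sequence),
              if (is.null(x$cds)) "" else " (+CDS)"))
  invisible(x)
}

#' @keywords internal
codon_at <- function(protein, position) {
  n <- nchar(protein$sequence)
  if (position < 1L || position > n)
    stop(sprintf("position %d outside protein '%s' (1..%d)", position, protein$id, n),
         call. = FALSE)
  if (is.null(protein$cds)) return(NA_character_)
  substr(protein$cds, 3L * (position - 1L) + 1L, 3L * position)
}

#' Build a synthetic model protein
#'
#' Constructs a deterministic protein sequence for simulations: a filler
#' residue with arginines at regular intervals so that the tryptic digest
#' yields uniform peptides, plus user-placed residues at chosen positions
#' (e.g. the aspartate/phenylalanine/glutamate sites of a misreading
#' cluster). The coding sequence is assigned by [reverse_translate()].
#'
#' @param length Protein length in residues.
#' @param period Spacing of the arginine cleavage sites.
#' @param residues Named character vector: names are 1-based positions,
#'   values one-letter residues to place there. Positions that fall on a
#'   cleavage site cannot be overridden.
#' @param filler Residue used everywhere else.
#' @param id Identifier.
#' @return A `protein_record` with CDS.
#' @export
synthetic_protein <- function(length = 300L, period = 12L, residues = character(),
                              filler = "A", id = "SYN1") {
  aa <- rep(filler, length)
  cut <- seq(period, length, by = period)
  aa[cut] <- "R"
  if (length(residues)) {
    pos <- as.integer(names(residues))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length))
      stop("residue positions out of range", call. = FALSE)
    if (any(pos %in% cut))
      stop("cannot overwrite a cleavage-site arginine", call. = FALSE)
    aa[pos] <- toupper(unlist(residues))
  }
  seqc <- paste(aa, collapse = "")
  protein_record(id, seqc, cds = reverse_translate(seqc))
}

#' The package's example model protein
#'
#' A 300-residue synthetic elongation-factor-like protein with the canonical
#' cluster geometries used throughout the documentation and simulations:
#' D208 and F211 (a two-intervening-residue cluster, D208E-F211L) and E241,
#' E242, E244 (adjacent and one-intervening clusters, E241D-E242D and
#' E242D-E244D), each inside a single tryptic peptide.
#'
#' @return A `protein_record` with CDS.
#' @export
example_protein <- function() {
  synthetic_protein(
    length = 300L, period = 12L,
    residues = c("208" = "D", "211" = "F", "241" = "E", "242" = "E", "244" = "E"),
    id = "EFTU-SYN"
  )
}

#' Read protein (and optional coding) sequences from FASTA
#'
#' @param aa_fasta Path to an amino-acid FASTA file.
#' @param cds_fasta Optional path to a nucleotide FASTA file with matching
#'   record names; each CDS must translate to its protein.
#' @return A list of `protein_record` objects, named by identifier.
#' @export
read_proteins <- function(aa_fasta, cds_fasta = NULL) {
  aas <- Biostrings::readAAStringSet(aa_fasta)
  ids <- sub("\\s.*$", "", names(aas))
  cds <- NULL
  if (!is.null(cds_fasta)) {
    nts <- Biostrings::readDNAStringSet(cds_fasta)
    names(nts) <- sub("\\s.*$", "", names(nts))
    cds <- as.character(nts)
  }
  out <- lapply(seq_along(aas), function(i) {
    protein_record(ids[i], as.character(aas[[i]]),
                   cds = if (!is.null(cds)) cds[[ids[i]]] else NULL)
  })
  names(out) <- ids
  out
}

#' Specify an amino-acid substitution on a protein
#'
#' Builds the record used throughout the package to describe one missense
#' substitution: position, parent codon (from the protein's CDS, or from the
#' preferred-codon table when no CDS is available -- in that case downstream
#' mismatch classes are reported under the assumed codon), and the mismatch
#' position class from [classify_substitution()].
#'
#' @param protein A `protein_record`.
#' @param position 1-based residue position.
#' @param to_aa Substituted residue (one-letter code).
#' @param collapse_ile Passed to [classify_substitution()].
#' @return A one-row data.frame with columns `protein_id`, `position`,
#'   `from_aa`, `to_aa`, `parent_codon`, `mismatch_class`, `label`.
#' @export
#' @examples
#' substitution_spec(example_protein(), 242, "D")  # E242D, class "3rd"
substitution_spec <- function(protein, position, to_aa, collapse_ile = FALSE) {
  stopifnot(inherits(protein, "protein_record"))
  position <- as.integer(position)
  from_aa <- substr(protein$sequence, position, position)
  if (position < 1L || position > nchar(protein$sequence) || from_aa == "")
    stop("position outside the protein", call. = FALSE)
  to_aa <- toupper(to_aa)
  codon <- codon_at(protein, position)
  if (is.na(codon)) codon <- default_codon_preference()[[from_aa]]
  cls <- classify_substitution(codon, to_aa, collapse_ile = collapse_ile)
  data.frame(
    protein_id = protein$id, position = position,
    from_aa = from_aa, to_aa = to_aa, parent_codon = codon,
    mismatch_class = cls,
    label = sprintf("%s%d%s", from_aa, position, to_aa),
    stringsAsFactors = FALSE
  )
}
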