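#' The standard genetic code on RNA codons
#'
#' Returns the standard genetic code as a named character vector mapping the
#' 64 RNA codons (e.g. `"GAU"`) to one-letter amino-acid codes, with `"*"`
#' for the three stop codons.
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' genetic_code()[["GAU"]]  # "D"
genetic_code <- function() {
  Biostrings::RNA_GENETIC_CODE
}

#' @keywords internal
normalize_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L)
    stop("codon must be a single character string", call. = FALSE)
  codon <- chartr("Tt", "Uu", toupper(codon))
  if (!grepl("^[ACGU]{3}$", codon))
    stop(sprintf("malformed codon '%s'", codon), call. = FALSE)
  codon
}

#' Translate a coding sequence
#'
#' @param cds Coding sequence (DNA or RNA alphabet accepted), length a
#'   multiple of 3.
#' @return One-letter amino-acid string (`"*"` for stop codons).
#' @export
translate_cds <- function(cds) {
  if (!is.character(cds) || length(cds) != 1L)
    stop("cds must be a single character string", call. = FALSE)
  if (nchar(cds) == 0L) return("")
  if (nchar(cds) %% 3L != 0L)
    stop("coding sequence length is not a multiple of 3", call. = FALSE)
  codons <- substring(cds, seq(1L, nchar(cds), by = 3L), seq(3L, nchar(cds), by = 3L))
  gc <- genetic_code()
  paste(vapply(codons, function(co) gc[[normalize_codon(co)]], character(1)),
        collapse = "")
}

#' Enumerate all near-cognate variants of a codon
#'
#' Near-cognate misreading substitutes a single nucleotide of the
#' codon-anticodon duplex. For a sense codon this enumerates the 9 single
#' mismatch variants (3 positions x 3 alternative bases) together with the
#' amino acid each variant encodes. Variants encoding a stop codon are
#' flagged: they are enumerated for completeness but are never emitted as
#' amino-acid substitutions (full-length protein products only).
#'
#' @param parent_codon A sense codon (RNA or DNA alphabet).
#' @return A data.frame with one row per variant and columns
#'   `mismatch_position` (1, 2 or 3), `alt_base`, `variant_codon`, `to_aa`,
#'   `is_stop`, `synonymous`.
#' @export
#' @examples
#' v <- enumerate_near_cognate("GAU")           # Asp codon
#' subset(v, to_aa == "E")                      # D -> E via 3rd position
enumerate_near_cognate <- function(parent_codon) {
  codon <- normalize_codon(parent_codon)
  gc <- genetic_code()
  from_aa <- gc[[codon]]
  if (from_aa == "*")
    stop(sprintf("'%s' is a stop codon, not a sense codon", codon), call. = FALSE)
  bases <- c("A", "C", "G", "U")
  out <- vector("list", 9L)
  k <- 0L
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (alt in setdiff(bases, ref)) {
      variant <- codon
      substr(variant, pos, pos) <- alt
      to_aa <- gc[[variant]]
      k <- k + 1L
      out[[k]] <- data.frame(
        mismatch_position = pos,
        alt_base          = alt,
        variant_codon     = variant,
        to_aa             = to_aa,
        is_stop           = to_aa == "*",
        synonymous        = to_aa == from_aa,
        stringsAsFactors  = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Classify an amino-acid substitution by codon mismatch position
#'
#' Determines which codon position a near-cognate misreading event must have
#' occurred at to turn `parent_codon` into a codon for `to_aa`. When several
#' positions can produce the substitution, the priority 3rd > 1st > 2nd
#' resolves the class (third-position misreading is the dominant mode of
#' drug-induced decoding errors). Substitutions requiring two or more
#' nucleotide changes are classified `"non-cognate"`; these are excluded
#' from error statistics by default.
#'
#' @param parent_codon Sense codon of the correct amino acid.
#' @param to_aa One-letter code of the substituted amino acid (not `"*"`).
#' @param collapse_ile If `TRUE`, isoleucine and leucine are treated as
#'   indistinguishable targets (standard MS workflows cannot separate them by
#'   mass), so a codon reaching either residue matches a query for both.
#' @return One of `"3rd"`, `"1st"`, `"2nd"`, `"non-cognate"`.
#' @export
#' @examples
#' classify_substitution("UUU", "L")  # "3rd": UUA/UUG beat CUU (1st)
#' classify_substitution("GGU", "W")  # "non-cognate" (two changes needed)
classify_substitution <- function(parent_codon, to_aa, collapse_ile = FALSE) {
  codon <- normalize_codon(parent_codon)
  gc <- genetic_code()
  from_aa <- gc[[codon]]
  if (!is.character(to_aa) || length(to_aa) != 1L || !to_aa %in% setdiff(unique(gc), "*"))
    stop("to_aa must be a single standard one-letter amino-acid code", call. = FALSE)
  if (to_aa == from_aa)
    stop("to_aa equals the translation of parent_codon; not a substitution", call. = FALSE)
  variants <- enumerate_near_cognate(codon)
  target <- if (collapse_ile && to_aa %in% c("I", "L")) c("I", "L") else to_aa
  hit <- variants$to_aa %in% target & !variants$is_stop
  positions <- unique(variants$mismatch_position[hit])
  if (length(positions) == 0L) return("non-cognate")
  for (p in c(3L, 1L, 2L)) {
    if (p %in% positions) return(c("1st", "2nd", "3rd")[p])
  }
}

#' Default preferred-codon table
#'
#' One preferred codon per amino acid (RNA alphabet), shipped as a JSON
#' configuration file. Used to reverse-translate synthetic protein sequences
#' deterministically when no coding sequence is supplied.
#'
#' @return Named character vector, amino acid -> codon.
#' @export
default_codon_preference <- function() {
  path <- system.file("extdata", "codon_preference.json", package = "agaclust",
                      mustWork = TRUE)
  pref <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  pref[names(pref) %in% strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]]
}

#' Deterministic reverse translation
#'
#' Maps each residue to the single preferred codon from
#' [default_codon_preference()] (or a user table), so that
#' `translate_cds(reverse_translate(s)) == s`.
#'
#' @param sequence Amino-acid sequence (one-letter codes).
#' @param preference Named character vector amino acid -> codon.
#' @return Coding sequence string (RNA alphabet).
#' @export
reverse_translate <- function(sequence, preference = default_codon_preference()) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string", call. = FALSE)
  if (nchar(sequence) == 0L) return("")
  aas <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(aas, names(preference))
  if (length(unknown))
    stop(sprintf("no preferred codon for residue(s): %s",
                 paste(unique(unknown), collapse = ", ")), call. = FALSE)
  paste(preference[aas], collapse = "")
}
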