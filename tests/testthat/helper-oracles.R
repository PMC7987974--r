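# Independent oracles used across the suite. They deliberately re-derive
# results by brute force (path enumeration, direct codon-table lookups)
# rather than calling the package's own dynamic programming.

# Exhaustive enumeration over all 2^L bound/unbound state sequences of the
# elongation chain. Transitions: binding with probability beta at every
# codon (rebinding allowed), retention with probability q per translocation.
oracle_pattern_probability <- function(pattern, L, beta, q, misread, eps0 = 0) {
  designated <- as.integer(names(misread))
  Tm <- rbind(U = c(U = 1 - beta, B = beta),
              B = c(U = (1 - q) * (1 - beta), B = q + (1 - q) * beta))
  init <- c(U = 1 - beta, B = beta)
  states <- expand.grid(rep(list(c("U", "B")), L), stringsAsFactors = FALSE)
  total <- 0
  for (r in seq_len(nrow(states))) {
    s <- unlist(states[r, ], use.names = FALSE)
    p <- init[[s[1]]]
    if (L > 1) for (i in 2:L) p <- p * Tm[s[i - 1], s[i]]
    for (i in seq_len(L)) {
      j <- match(i, designated)
      if (is.na(j)) next
      mw <- misread[[j]]
      e <- if (i %in% pattern) {
        if (s[i] == "B") mw else eps0
      } else {
        if (s[i] == "B") 1 - mw else 1 - eps0
      }
      p <- p * e
    }
    total <- total + p
  }
  total
}

# aga_params whose beta at concentration 1 equals `beta` exactly
test_params <- function(beta, q, misread, name = "test") {
  aga_params(name, q, misread, beta_scale = beta)
}

# protein of plain alanines, long enough for any designated position
test_protein <- function(L, id = "T1") {
  protein_record(id, strrep("A", L))
}

random_aa_sequence <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}
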