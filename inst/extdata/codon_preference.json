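{
  "_comment": "One preferred codon per amino acid (RNA alphabet), E. coli K-12 biased usage. Used for deterministic reverse translation of synthetic proteins.",
  "A": "GCG", "R": "CGU", "N": "AAC", "D": "GAU", "C": "UGC",
  "Q": "CAG", "E": "GAA", "G": "GGC", "H": "CAU", "I": "AUU",
  "L": "CUG", "K": "AAA", "M": "AUG", "F": "UUU", "P": "CCG",
  "S": "AGC", "T": "ACC", "W": "UGG", "Y": "UAU", "V": "GUG"
}
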