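{
  "_comment": [
    "Generative presets per aminoglycoside. q is the per-translocation probability",
    "that the drug stays bound; efnext is the observable conditional next-error",
    "frequency for the anchor cluster at the stated inter-error distance d",
    "(number of correct intervening residues). The simulator back-solves the",
    "bound-state misreading probability from (efnext, d, q).",
    "q for Apr and the generic group II drugs is 0.5, the centre of the 0.3-0.7",
    "range returned by exponential distance fits; q for Str (0.97, near-flat",
    "profile) and Par (0.9, weak distance dependence) are implementer choices",
    "consistent with the flat and weakly decaying profiles of those drugs."
  ],
  "schema_version": 1,
  "beta_scale_per_uM": 1e-05,
  "presets": [
    {
      "name": "Str", "group": "I", "q": 0.97,
      "anchors": [
        {"efnext": 0.08, "d": 2, "example": "D208E-F211L"},
        {"efnext": 0.05, "d": 1, "example": "E242D-E244D"}
      ]
    },
    {
      "name": "Par", "group": "I", "q": 0.9,
      "anchors": [{"efnext": 0.09, "d": 1, "example": "E242D-E244D"}]
    },
    {
      "name": "Apr", "group": "II", "q": 0.5,
      "anchors": [{"efnext": 0.25, "d": 1, "example": "E242D-E244D"}]
    },
    {
      "name": "Sis", "group": "II", "q": 0.5,
      "anchors": [{"efnext": 0.40, "d": 0, "example": "E241D-E242D"}]
    },
    {
      "name": "KanA", "group": "II", "q": 0.5,
      "anchors": [{"efnext": 0.36, "d": 0, "example": "E241D-E242D"}]
    },
    {
      "name": "groupII", "group": "II", "q": 0.5,
      "anchors": [{"efnext": 0.40, "d": 0, "example": "generic adjacent cluster"}]
    }
  ]
}
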