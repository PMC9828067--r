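{
  "comment": "Amyloid peptide regions, one-letter codes. ABri/ADan: the 34-residue amyloidogenic C-terminal peptides released from mutant BRI2; identical over residues 1-22. Abeta: residues 1-42 of the APP-derived amyloid-beta peptide.",
  "canonical_c_terminus": {"ABri": 34, "ADan": 34, "Abeta": 42},
  "sequences": {
    "ABri": "EASNCFAIRHFENKFAVETLICSRTVKKNIIEEN",
    "ADan": "EASNCFAIRHFENKFAVETLICFNLFLNSQEKHY",
    "Abeta": "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
  }
}
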