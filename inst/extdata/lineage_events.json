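{
  "comment": "Curated per-branch residue replacements for the whale myoglobin lineage, 1-based mature-chain numbering. Branch events are stated parent-to-child; ancestors are reconstructed by reverse application starting from the packaged swMb sequence.",
  "path": ["aMbWp", "aMbWb", "swMb"],
  "branches": [
    {"parent": "aMbWp", "child": "aMbWb",
     "events": ["E27D", "V13I", "T34K", "D53A", "Q116H", "K118R", "N140K"]},
    {"parent": "aMbWb", "child": "swMb",
     "events": ["D4E", "N12H", "I13V", "V28I", "G35S", "K45R", "N66V", "G74A", "D109E", "F151Y"]}
  ],
  "variants": [
    {"id": "aMbWb'", "of": "aMbWb", "events": ["G1V", "G15A"],
     "comment": "Alternative whale-ancestor reconstruction; events stated variant-to-reference, so the variant is obtained by reverse application."}
  ]
}
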