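# Demo pipeline: small seeded cohort, both study nail designs.
seed: 7
"n": 10   # quoted: a bare n is a YAML 1.1 boolean
nails: [pfna2, intertan]
nail_length: 200
nail_distal_diameter: 10
write_meshes: false
options:
  density: 2
  threshold: 0.1
  linkage_radius: 2
  exclude_entry_mm: 15
  gap_step: 2
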