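# Demo pipeline configuration: simulate a small cohort and run the full
# statin/CVM analysis grid.
sim:
  n_patients: 2000
  seed: 1
endpoint: primary
cohort: main
truncation_levels: [5, 1, 0.1]
substance_codes: ["303.90", "304.20", "305.00"]
seed: 1
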