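{
  "reference": "synthetic_reference.fasta",
  "libraries": [
    {
      "id": "L1",
      "path": "synthetic_L1_tags.tsv",
      "format": "tsv"
    },
    {
      "id": "L2",
      "path": "synthetic_L2_tags.tsv",
      "format": "tsv"
    }
  ],
  "fdr_cutoff": 0.001,
  "min_abs_log2": 1,
  "tpm_floor": 0.01,
  "max_mismatch": 1,
  "saturation_points": 5,
  "seed": 99
}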