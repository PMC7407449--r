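{
  "seed": 1,
  "out_dir": "flymap_out",
  "stages": ["map_rf", "place", "complementation", "tiling", "viability"],
  "map_rf": { "pair_counts": "table3_pair_counts.tsv", "ci_level": 0.95 },
  "place": { "rf_table": "table4_refined_rf.tsv", "method": "flank_subtraction" },
  "complementation": {
    "panel": "df_panel_synthetic.tsv",
    "alleles": "dcp2_alleles_synthetic.tsv",
    "annotation": "gene_annotation_synthetic.tsv",
    "radius": 1
  },
  "tiling": { "panel": "tiling_panel_synthetic.tsv", "size_tol": 0.1 },
  "viability": {
    "proportions": [
      { "name": "nontubby_larvae_to_pupae", "numerator": 313, "denominator": 468 },
      { "name": "rescue_eclosed_act5c", "numerator": 94, "denominator": 442 }
    ],
    "fertility": [
      { "name": "transhet_males", "fertile": 28, "total": 70 },
      { "name": "transhet_females", "fertile": 18, "total": 83 }
    ]
  }
}
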