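{
  "n_leaves": 5,
  "tree_height": 0.35,
  "n_genes": 8,
  "gene_len": 300,
  "spacer_len": 60,
  "sub_rate": 1,
  "gene_rate_sd": 0.7,
  "dnap_rate": 0.3,
  "n_families": 3,
  "n_subgroups": 2,
  "swap_events": {},
  "dnap_slot2": false,
  "seed": 11
}
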