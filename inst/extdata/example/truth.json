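{
  "tree_newick": "((g001:0.2100292018,g003:0.2100292018)n8:0.1399707982,((g002:0.02781570622,g004:0.02781570622)n9:0.3094084433,g005:0.3372241495)n7:0.01277585046)n6;",
  "leaf_states": [
    {
      "leaf_id": "g001",
      "family": 1,
      "subgroup": 1,
      "swapped": false,
      "family_label": "PolA",
      "subgroup_label": "A1"
    },
    {
      "leaf_id": "g002",
      "family": 2,
      "subgroup": 1,
      "swapped": true,
      "family_label": "PolB",
      "subgroup_label": "B1"
    },
    {
      "leaf_id": "g003",
      "family": 1,
      "subgroup": 1,
      "swapped": false,
      "family_label": "PolA",
      "subgroup_label": "A1"
    },
    {
      "leaf_id": "g004",
      "family": 1,
      "subgroup": 1,
      "swapped": false,
      "family_label": "PolA",
      "subgroup_label": "A1"
    },
    {
      "leaf_id": "g005",
      "family": 1,
      "subgroup": 1,
      "swapped": false,
      "family_label": "PolA",
      "subgroup_label": "A1"
    }
  ],
  "swap_events": [
    {
      "branch": "g002",
      "family": 2,
      "subgroup": 1
    }
  ]
}
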