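{
  "n_dogs": 829,
  "n_breeds": 59,
  "n_assigned": 803,
  "n_assigned_breeds": 49,
  "n_unassigned": 26,
  "hom3_dogs": 198,
  "hom3_haplotypes": 52,
  "hom2_dogs": 40,
  "hom1_dogs": 163,
  "het_estimated_dogs": 428,
  "registry_subhaplotypes": 106,
  "het_subhaplotypes": 84,
  "subhaplotypes_total": 190,
  "recurrent_haplotypes": 131,
  "singleton_haplotypes": 59,
  "recurrent_copies": 1547,
  "recurrent_copies_88_12": 1228,
  "recurrent_copies_88_88L": 319,
  "recurrent_types_88_12": 101,
  "recurrent_types_88_88L": 30,
  "top_hap_count_hp12": 68,
  "second_top_count_hp25": 62,
  "dla12_001_01_01_carriers": 545,
  "donor_ranks": [9, 28, 52],
  "matched_dogs": [411, 650, 733]
}
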