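# Mimic of the haloarchaeal conserved chromosomal origin: minimal AT-rich
# core flanked by the inverted ORB pair (each with its G-string), plus the
# perfect G-rich inverted-repeat enhancer just inside the boxes and the
# adjacent cdc6 gene. No titration cluster.
name: oriC1m
replicon_id: chr_mimic
replicon_length: 120000
origin_position: 30000
gc_background: 0.6
seed: 101
architecture:
  orb_consensus: TTCCAGTGGAAACGAAAGGG
  n_origin_orbs: 2
  orb_spacing: 5
  at_core_len: 150
  at_core_fraction: 0.85
  gstring_len: 8
  enhancer_arm: GGGGAGGGGG
  titration_orb_count: 0
  titration_region_len: 0
  cdc6_gene_len: 1200
  cdc6_offset: 100
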