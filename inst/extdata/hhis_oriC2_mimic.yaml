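# Mimic of the second chromosomal origin: inverted ORB pair and AT core (no
# enhancer repeat), cdc6 gene downstream, and an ORB-rich titration cluster
# of 11 boxes in a 722-bp intergenic region directly downstream of the gene.
name: oriC2m
replicon_id: chr_mimic
replicon_length: 60000
origin_position: 20000
gc_background: 0.6
seed: 202
architecture:
  orb_consensus: TTCCAGTGGAAACGAAAGGG
  n_origin_orbs: 2
  orb_spacing: 5
  at_core_len: 150
  at_core_fraction: 0.85
  gstring_len: 8
  enhancer_arm: null
  titration_orb_count: 11
  titration_region_len: 722
  cdc6_gene_len: 1200
  cdc6_offset: 100
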