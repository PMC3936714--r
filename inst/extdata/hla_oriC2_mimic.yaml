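# Mimic of the Halorubrum lacusprofundi homolog of the second chromosomal
# origin: same ori-cdc6 layout but only three ORB elements in its titration
# region. The region length is not documented for this species; 400 bp is
# the package's choice of a comparable intergenic span.
name: hla_oriC2m
replicon_id: hla_chr_mimic
replicon_length: 60000
origin_position: 20000
gc_background: 0.6
seed: 303
architecture:
  orb_consensus: TTCCAGTGGAAACGAAAGGG
  n_origin_orbs: 2
  orb_spacing: 5
  at_core_len: 150
  at_core_fraction: 0.85
  gstring_len: 8
  enhancer_arm: null
  titration_orb_count: 3
  titration_region_len: 400
  cdc6_gene_len: 1200
  cdc6_offset: 100
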