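# Bundled 10-Mb evaluation fixture: two 5-Mb chromosomes, ~50,000 read
# pairs, every curation event kind, and 300 candidate sites.
seed: 1
sim:
  n_chromosomes: 2
  chromosome_length: 5000000
  gc_fraction: 0.41
  segdup_count: 2
  segdup_length: 20000
  segdup_divergence: 0.02
  satellite_monomer_length: 171
  satellite_copy_count: 100
  satellite_divergence: 0.05
  default_gap_length: 50000
  component_length: 100000
  read_length: 150
  insert_mean: 450
  insert_sd: 50
  per_base_error_rate: 0
  depth: 1.5
  contaminant_fraction: 0.005
events:
  - kind: false_duplication
    length: 20000
    divergence: 0
  - kind: collapse
    length: 15000
    divergence: 0.02
    dest: same_arm
  - kind: collapse
    length: 12000
    divergence: 0.02
    dest: other_arm
  - kind: collapse
    length: 10000
    divergence: 0.02
    dest: same_pericen
  - kind: collapse
    length: 10000
    divergence: 0
    dest: other_pericen
  - kind: collapse
    length: 12000
    divergence: 0.02
    dest: scaffold
  - kind: collapse
    length: 12000
    divergence: 0.02
    dest: scaffold_cen
  - kind: gap_closure
    length: 6000
  - kind: inversion
    length: 30000
  - kind: base_error
  - kind: retile
    length: 50000
  - kind: centromere_model
  - kind: alt_locus
    novel_length: 10000
    flank: 5000
sites:
  n_sites: 300
  depth: 30
  read_length: 100
params:
  min_non_n_fraction: 0.5
  min_mapq: 20
  snv_cutoff: 0.90
  indel_cutoff: 0.70
  min_depth: 1
  merge_distance: 100000
  top_k: 10
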