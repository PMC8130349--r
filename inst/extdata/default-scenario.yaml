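# Three-population permafrost scenario: one living, one intact-dead, one
# lysed population, sequenced as the 2x2 iDNA/eDNA x repair design.
seed: 1
fragment_redundancy: 5
heterogeneity: 0
thresholds:
  damage_max: 0.1
  delta_max: 0.05
populations:
  - genome_id: young_living
    genome_length: 40000
    gc_fraction: 0.55
    relative_abundance: 1
    vitality: living
    ptr: 1.3
  - genome_id: fossil_aerobe
    genome_length: 40000
    gc_fraction: 0.45
    relative_abundance: 1
    vitality: dead_intact
    damage: {delta_ss: 0.3, delta_ds: 0.01, overhang_decay: 0.6,
             nick_rate: 0.005, blocker_rate: 0.01,
             frag_mu: 5.2983173665480363, frag_sigma: 0.5}
  - genome_id: lysed_relic
    genome_length: 40000
    gc_fraction: 0.5
    relative_abundance: 1
    vitality: lysed
    damage: {delta_ss: 0.3, delta_ds: 0.01, overhang_decay: 0.6,
             nick_rate: 0.005, blocker_rate: 0.01,
             frag_mu: 5.2983173665480363, frag_sigma: 0.5}
libraries:
  - {fraction: iDNA, repaired: false, read_length: 100, target_depth: 15,
     repair_efficiency: 1, block_prob: 0.9, seq_error_rate: 0.001}
  - {fraction: iDNA, repaired: true, read_length: 100, target_depth: 15,
     repair_efficiency: 1, block_prob: 0.9, seq_error_rate: 0.001}
  - {fraction: eDNA, repaired: false, read_length: 100, target_depth: 15,
     repair_efficiency: 1, block_prob: 0.9, seq_error_rate: 0.001}
  - {fraction: eDNA, repaired: true, read_length: 100, target_depth: 15,
     repair_efficiency: 1, block_prob: 0.9, seq_error_rate: 0.001}
racemization:
  Ea: 101.7
  A: 1.43e+15
  T_celsius: -7.7
  dl0: 0
  ages: {"3.4": 26000, "5.8": 100000, "14.8": 100000}
  observed:
    - {depth: 3.4, dl_bulk: 0.12, dl_cells: 0.06}
    - {depth: 5.8, dl_bulk: 0.22, dl_cells: 0.10}
    - {depth: 14.8, dl_bulk: 0.29, dl_cells: 0.15}
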