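# Example simulation configuration for `ilqtl simulate --config` /
# read_sim_config(). Omitted keys take the defaults of
# simulation_config(); genome defaults to the 12-chromosome tomato
# genome of default_genome().
n_lines: 54
seed: 1
locations: [LOC1, LOC2, LOC3]
blocks: 8
il_reps: 1
control_reps: 6
seg_len_mean: 25    # Mb
seg_len_sd: 8
overlap_frac: 0.25
coverage_floor: 98  # percent of the genome the library union must cover
traits:
  - {trait: FW,  mean: 98.2, var_location: 67,   var_block: 16,
     var_gxl: 18,   var_resid: 144}
  - {trait: SSC, mean: 4.48, var_location: 0.04, var_block: 0.02,
     var_gxl: 0.04, var_resid: 0.2}
planted_qtls:
  - {trait: FW, chrom: '2', pos_mb: 25, effect_pct: -31}
missing:
  - {line: SP_3-1, location: LOC1}
  - {line: SP_3-1, location: LOC2}
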