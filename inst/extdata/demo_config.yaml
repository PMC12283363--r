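# Demonstration configuration for run_pipeline(): a small four-cohort
# simulated BC1 study. Thresholds omitted here fall back to the package
# defaults (QC: DP in [4,100], mean DP in [1,1.5], MAF in [0.2,0.3],
# missingness > 75%, 5%/95% percentile trim; smoothing w = 20; 1-Mb bins;
# 500 permutations). The mean-DP bounds are overridden to match the
# simulated ~25x depth.
seed: 11
output_dir: null
simulation:
  markers: 5000
  observation:
    p_missing: 0.1
    e_het_to_hom: 0.01
    e_hom_to_het: 0.01
    e_hom_ler: 0.03
    depth_mean: 25
    depth_dropout: false
  cohorts:
    - label: wt_male
      sex: male
      genotype: WT
      n_samples: 60
      transmitted_mean: 4.8
      nu: 5
    - label: mut_male
      sex: male
      genotype: mut
      n_samples: 60
      transmitted_mean: 6.0
      nu: 1
    - label: wt_female
      sex: female
      genotype: WT
      n_samples: 60
      transmitted_mean: 3.0
      nu: 5
    - label: mut_female
      sex: female
      genotype: mut
      n_samples: 60
      transmitted_mean: 6.15
      nu: 1
qc:
  mean_dp_range: [15, 35]
interference:
  n_perm: 100
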