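# Demo configuration for the command-line wrapper:
#   Rscript inst/scripts/twinstrat.R run --config pipeline-demo.yaml --out demo_out
sim:
  n_mz_pairs: 80
  n_dz_pairs: 120
  n_controls: 500
  n_snps: 2000
  n_qtns_per_trait: 3
  h2_target: 0.8
  c2_shared: 0.1
  diagnosis_quantile: 0.75
  rng_seed: 1
qtl_alpha: 1.0e-5
fdr: 0.10
min_call_rate: 0.95
min_maf: 0.05
hwe_p: 0.001
dz_p: 0.05
dz_or: 3.0
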