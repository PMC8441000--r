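# Demo: fully simulated run at reduced scale (completes in seconds).
seed: 42
simulate:
  n_discovery: 400
  n_test: 250
  n_snps: 120
  n_causal: 10
qc:
  preset: mavan
prune:
  window_kb: 50
  step_snps: 5
  r2_max: 0.2
clump:
  window_kb: 250
  r2_max: 0.2
scan:
  grid_size: 100
  covariates: pcs10
  n_pcs: 10
alpha_refine: 0.05
gxe:
  probe_sd: 1
  alpha: 0.05
bootstrap:
  enabled: false
imputation:
  enabled: true
  m: 30
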