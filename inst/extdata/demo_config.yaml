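# Demo pipeline: three simulated cohorts sharing a latent stromal factor
# that drives a 24-gene module and survival (log-hazard 0.5 per factor
# unit), screened at the derivation cutoffs (r > 0.4 / 0.4 / 0.3,
# adjusted p < 0.05).
anchor: SALL4
r_min: [0.4, 0.4, 0.3]
q_max: 0.05
quantile_q: 0.6666667
signature_name: demo_anchor_signature
maxstat:
  minprop: 0.1
  n_perm: 200
cox_covariates: []
seed: 7
cohorts:
  - simulate:
      n_samples: 150
      n_genes: 1500
      module_genes: 24
      anchor_loading: 1.2
      module_loading: 1.2
      noise_sd: 1.0
      beta: 0.5
      baseline_hazard: 0.035
      censor_max: 120
  - simulate:
      n_samples: 150
      n_genes: 1500
      module_genes: 24
      anchor_loading: 1.2
      module_loading: 1.2
      noise_sd: 1.0
      beta: 0.5
      baseline_hazard: 0.035
      censor_max: 120
  - simulate:
      n_samples: 150
      n_genes: 1500
      module_genes: 24
      anchor_loading: 1.2
      module_loading: 1.2
      noise_sd: 1.0
      beta: 0.5
      baseline_hazard: 0.035
      censor_max: 120
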