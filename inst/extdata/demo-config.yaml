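# Demo pipeline configuration: small synthetic multi-study cohort,
# end-to-end (simulate -> process -> fit -> report).
out_dir: isosub-demo
simulate: true
outcomes: wc
strata: [children, adolescents, older]
unit: 10
estimator: random_effects_gls
variance: cluster_robust
seed: 20260301
verbose: true
sim:
  n_studies: 6
  persons_per_study: 12
  n_days: 2
  nonwear_blocks: 1
thresholds:
  sedentary_max: 100
  light_max: 2295
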