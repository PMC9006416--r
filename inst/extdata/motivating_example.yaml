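# Constrained randomisation of the ten-emergency-department trial:
# process outcome (ICC 0.1), standardised effect 0.5, prognostic value 2
# per covariate, all three covariates balanced and adjusted. The
# candidate_sets block makes cmd_power() compare best-10%, simple and
# worst-10% randomisation under common random numbers.
seed: 2026
n_reps: 1000
example: true
scenarios:
  - k_per_arm: 5
    cluster_size: 300
    icc: 0.1
    theta: 0.5
    gamma: 2
    n_balanced: 3
    n_adjusted: 3
candidate_sets:
  - fraction: 0.1
    side: best
  - fraction: 1.0
    side: all
  - fraction: 0.1
    side: worst
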