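arms:
- Arm A
- Arm B
- Arm C
true_ys:
- 0.25
- 0.25
- 0.25
outcome_type: binary
highest_is_best: no
start_probs:
- 0.333333333333333
- 0.333333333333333
- 0.333333333333333
min_probs:
- 0.25
- 0.25
- 0.25
rescale_probs: limits
soften_power:
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
control_prob_rule: none
data_looks:
- 500.0
- 750.0
- 1000.0
- 1250.0
- 1500.0
- 1750.0
- 2000.0
- 2250.0
- 2500.0
- 2750.0
- 3000.0
- 3250.0
- 3500.0
- 3750.0
- 4000.0
- 4250.0
- 4500.0
- 4750.0
- 5000.0
- 5250.0
- 5500.0
- 5750.0
- 6000.0
- 6250.0
- 6500.0
- 6750.0
- 7000.0
- 7250.0
- 7500.0
- 7750.0
- 8000.0
- 8250.0
- 8500.0
- 8750.0
- 9000.0
- 9250.0
- 9500.0
- 9750.0
- 10000.0
randomised_at_looks:
- 700.0
- 950.0
- 1200.0
- 1450.0
- 1700.0
- 1950.0
- 2200.0
- 2450.0
- 2700.0
- 2950.0
- 3200.0
- 3450.0
- 3700.0
- 3950.0
- 4200.0
- 4450.0
- 4700.0
- 4950.0
- 5200.0
- 5450.0
- 5700.0
- 5950.0
- 6200.0
- 6450.0
- 6700.0
- 6950.0
- 7200.0
- 7450.0
- 7700.0
- 7950.0
- 8200.0
- 8450.0
- 8700.0
- 8950.0
- 9200.0
- 9450.0
- 9700.0
- 9950.0
- 10000.0
inferiority:
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
superiority:
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
- 0.99
equivalence_prob:
- 1.0
- 1.0
- 1.0
- 1.0
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
- 0.9
equivalence_diff: 0.025
equivalence_only_first: no
futility_only_first: no
prior_alpha: 1.0
prior_beta: 1.0
n_draws: 10000
label: 0.25/0.25/0.25
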