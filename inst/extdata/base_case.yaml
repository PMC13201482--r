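# Base-case model configuration: 3-year decision tree with published arm
# totals, a 15-year discounted Markov scenario (transition probabilities
# below are SYNTHETIC placeholders -- supply study estimates for real use),
# and the national budget-impact block.
seed: 1
tree:
  accrual_years: 7
  comparator: no_aid
  strategies:
    - name: no_aid
      total_cost: 2669
      mean_utility: 0.601
    - name: unilateral
      total_cost: 11420
      mean_utility: 0.832
    - name: bilateral
      total_cost: 19420
      mean_utility: 0.832
markov:
  horizon: 15
  discount_rate: 0.03
  device_price_per_ear: 8000
  ears: 1
  replacement_interval: 3
  reevaluation_cost: 0
  cohort_size: 1
  matrix:
    user:            # synthetic: users progress more slowly
      - [0.92, 0.06, 0.02]
      - [0.00, 0.94, 0.06]
      - [0.00, 0.00, 1.00]
    non_user:        # synthetic
      - [0.85, 0.10, 0.05]
      - [0.00, 0.88, 0.12]
      - [0.00, 0.00, 1.00]
  initial:           # arm-specific severity mix of the 2023 survey
    user: [0.13043478260869565, 0.4420289855072464, 0.427536231884058]
    non_user: [0.425, 0.36388888888888893, 0.2111111111111111]
  state_utility:     # published cell mean utilities (mild, moderate, severe)
    user: [0.763, 0.807, 0.904]
    non_user: [0.592, 0.598, 0.614]
  state_cost:        # annual direct medical INR (3-year aggregates / 3)
    user: [1456, 1456, 1456]
    non_user: [527.67, 527.67, 527.67]
cea:
  wtp_threshold: 100000   # illustrative; set to 1x per-capita GDP in INR
bia:
  population: 149000000
  prevalence: 0.10
  need_fraction: 0.047
  unilateral_fraction: 0.35
  cost_unilateral: 12368
  cost_bilateral: 20368
  horizon_years: 3
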