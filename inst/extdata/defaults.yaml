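# Base-case parameters of the NTG cost-utility model.
# All keys are optional: anything omitted keeps the same built-in default.
# Costs in 2023 USD; probabilities are annual unless noted.

transitions.p_mild_to_moderate_positive: 0.044
transitions.p_moderate_to_severe_positive: 0.018
transitions.p_mild_to_moderate_traditional: 0.149
transitions.p_moderate_to_severe_traditional: 0.056

utilities.u_mild: 0.80
utilities.u_moderate: 0.75
utilities.u_severe: 0.71
utilities.u_dead: 0.0

mortality.bands.age_from: [65, 70]
mortality.bands.age_to: [69, 74]
mortality.bands.p_death: [0.00364, 0.00518]
mortality.glaucoma_odds_ratio: 1.8

costs.annual_dual_therapy: 307.24
costs.annual_triple_therapy: 470.45
costs.trabeculectomy: 530.97
costs.followup_no_progression: 79.55
costs.followup_progression: 119.32
costs.first_year_moderate_B: 381.84
costs.first_year_severe_B: 381.84
costs.consecutive_year_moderate_B: 254.56
costs.consecutive_year_severe_B: 254.56
costs.dual_to_triple_ratio: 3
costs.dose_multiplier_after_progression: 1.5
costs.surgical_failure_rate: 0.20

econ.discount_rate: 0.035
econ.horizon: 10
econ.start_age: 64
econ.cohort_size: 100000
econ.gdp_per_capita: 12692.90
econ.half_cycle_correction: true
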