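# Run-configuration template for the odorthresh pipeline.
# Every key is optional; omitted keys fall back to the package defaults.

seed: 1

# Session termination rules per experiment design.
rules_exp1:
  reversals_required: 7
  session_cap_min: 40
rules_exp2:
  reversals_required: 4

# Imputation fractions for incomplete sessions.
floor_fraction: 0.03   # dog cleared the lowest step
fail_fraction: 0.80    # welfare / time-cap stop

# Dilution ladder override (highest concentration first).
# ladder:
#   - {step_number: 1, odor_flow: 1000, clean_flow: 0.25, nominal_fraction: 0.80}
#   - {step_number: 2, odor_flow: 1000, clean_flow: 1.0,  nominal_fraction: 0.50}
#   - {step_number: 3, odor_flow: 750,  clean_flow: 2.25, nominal_fraction: 0.25}
#   - {step_number: 4, odor_flow: 360,  clean_flow: 2.65, nominal_fraction: 0.12}
#   - {step_number: 5, odor_flow: 90,   clean_flow: 2.91, nominal_fraction: 0.03}

# Synthetic-generator effect parameters (see ?effect_spec for the full list).
# effects:
#   sigma_dog: 0.15
#   sigma_e: 0.10

# Column mappings attach external CSV headers to the canonical schemas,
# canonical field -> native column name.
# mappings:
#   trials:
#     outcome: Response
#     latency_s: Latency.s.
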