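# Shared fixtures, built in code.

# Gene-noise essential-hypertension study: profiles (1,1), (1,0), (0,1), (0,0)
tong_table <- function() {
  cc_table(cases = c(20, 13, 161, 117), controls = c(18, 24, 261, 319))
}

tong_prevalence <- function(n = 1e5) prevalence(0.252, n = n)

# A table whose exposure-profile proportions match a scenario exactly
# (expected counts, no sampling): plug-in estimates must recover the truth.
exact_table <- function(scenario, n_cases = 1e6, n_controls = 1e6) {
  d <- cell_distributions(scenario)
  cc_table(cases = n_cases * d$cases, controls = n_controls * d$controls)
}
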