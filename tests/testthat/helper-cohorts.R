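# shared fixtures, all generated in code

complete_cohort <- function(n = 120, seed = 11, ...) {
  generate_cohort(cohort_spec(n = n, seed = seed,
                              missing_rates = c(thal = 0, ca = 0), ...))
}

# strongly separable cohort: scaled-up generative coefficients
separable_cohort <- function(n = 400, seed = 5, scale = 8) {
  generate_cohort(cohort_spec(
    n = n, seed = seed, missing_rates = c(thal = 0, ca = 0),
    risk_coefficients = default_risk_coefficients() * scale))
}

encode_complete <- function(cohort) {
  sc <- fit_minmax(as.matrix(as.data.frame(cohort)[, uci_numeric_fields()]))
  one_hot_encode(cohort, scaling = sc)
}

# small training configuration used throughout the tests
tiny_config <- function(...) {
  args <- list(lstm_units = 8L, epochs = 10L, learning_rate = 0.01,
               batch_size = 32L, k = 5L, seed = 1L)
  override <- list(...)
  args[names(override)] <- override
  do.call(run_config, args)
}
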