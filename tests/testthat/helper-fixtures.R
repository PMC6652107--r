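# Shared fixtures: small parameter sets and designs used across tests.

# a modest all-positive coupling set with gentle dynamics
params_mild <- function() {
  model_parameters(k_homeostasis = 0.05, k_EH = 0.2, k_HK = 0.1,
                   k_HM = 0.15, k_HE = 0.1, k_ME = 0.2)
}

# dense sampling design used for identifiability/recovery checks
dense_design <- function(n = 1) {
  study_design(phx_n = rep(n, 7), sham_n = rep(n, 7), untreated_n = n,
               days = c(2, 4, 6, 8, 10, 14, 21))
}

random_nonneg_params <- function() {
  do.call(model_parameters, as.list(stats::runif(6, 0, 2)))
}
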