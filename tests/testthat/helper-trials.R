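# shared helpers: quick trial-table constructors used across the suite

make_trials <- function(estimate, se, id = paste0("trial ", seq_along(estimate))) {
  tibble::tibble(id = id, estimate = estimate, se = se)
}

# two identical trials (the paper-style soundness-check configuration)
equal_trials <- function(estimate = 0.3, se = 1, k = 2) {
  make_trials(rep(estimate, k), rep(se, k))
}

# RESPIRE 14-day trials with standard errors reconstructed from the 95% CIs
respire14 <- function() pf_fixture("respire_14d")

methods_all <- function() pf_methods()
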