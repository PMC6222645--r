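# shared fixtures: the five-factor space, its design, and a way to turn a
# bare coefficient vector into a recovery_model through the public API
# (fit a noiseless table generated from that vector)

study_space <- chd_factor_space()
study_design <- ccf_design(study_space, n_center = 3)

model_from_coef <- function(coef, compound = "synthetic",
                            design = study_design) {
  truth <- matrix(coef, ncol = 1, dimnames = list(NULL, compound))
  tab <- simulate_recoveries(design, truth, noise_sd = 0)
  fit_full_model(tab, compound)
}

# a coefficient vector that is zero except for the named terms
coef_vector <- function(..., space = study_space) {
  terms <- term_basis(space$name)
  v <- stats::setNames(rep(0, length(terms)), terms)
  set <- c(...)
  v[names(set)] <- set
  v
}
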