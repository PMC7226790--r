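# shared fixtures for the suite

# reference parameter set (published rate table plus package defaults)
tab1_params <- function(...) model_params(...)

# reduced-scale parameters: thymic inputs and carrying capacity scaled
# down so that exact event-level simulation is cheap
reduced_params <- function(factor = 100) {
  p <- model_params()
  update_params(p, lambda_in = p$lambda_in / factor,
                lambda_r = p$lambda_r / factor, N = p$N / factor)
}

# random positive states spanning realistic compartment magnitudes
# (S below the logistic clamp boundary at 2N)
rand_states <- function(n, seed = 1) {
  set.seed(seed)
  cbind(S = runif(n, 0, 1.8) * 20000,
        Tin = runif(n, 0, 12000),
        Treg = runif(n, 0, 1e5),
        Taut = runif(n, 0, 800),
        I = runif(n, 0, 1000))
}

# parameters whose channels are all structurally silent at the zero state
silent_params <- function() {
  update_params(model_params(), r = 0, mu_a = 0, alpha = 0,
                lambda_in = 0, lambda_r = 0, d_in = 0, d_r = 0, d_a = 0,
                sigma = 0, rho1 = 0, rho2 = 0, delta = 0, d_i = 0)
}
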