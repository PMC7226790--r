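test_that("the SDE drift coincides with the deterministic vector field", {
  p <- tab1_params()
  sts <- rand_states(100, seed = 21)
  for (i in seq_len(nrow(sts)))
    expect_lt(max(abs(sde_drift(sts[i, ], p) - model_rhs(sts[i, ], p))),
              1e-10)
  e1 <- steady_state_E1(p)
  expect_equal(unname(sde_drift(e1$state, p)), rep(0, 5), tolerance = 1e-12)
  e2 <- steady_state_E2(update_params(p, rho1 = 1e-4, rho2 = 4.4e-4))[[1]]
  expect_equal(unname(sde_drift(e2$state, p = update_params(
    p, rho1 = 1e-4, rho2 = 4.4e-4))[1]), 0, tolerance = 1e-10)
})

test_that("the diffusion factor factorises the transition covariance", {
  p <- tab1_params()
  nu <- transition_stoichiometry()
  sts <- rand_states(100, seed = 22)
  for (i in seq_len(nrow(sts))) {
    st <- sts[i, ]
    H <- diffusion_factor(st, p)
    expect_identical(dim(H), c(5L, 7L))
    q <- transition_rates(round(st), p)  # oracle from the channel list
    Bq <- nu %*% (t(nu) * as.numeric(transition_rates(round(st), p)))
    Hr <- diffusion_factor(round(st), p)
    expect_lt(max(abs(Hr %*% t(Hr) - Bq)), 1e-13 * max(abs(Bq)))
    # conversion channels induce the only cross-compartment covariances
    HH <- Hr %*% t(Hr)
    expect_equal(HH["Tin", "Treg"], -unname(q["q5"]), tolerance = 1e-12)
    expect_equal(HH["Tin", "Taut"], -unname(q["q6"]), tolerance = 1e-12)
    expect_equal(HH["Treg", "Taut"], 0)
  }
  expect_equal(unname(diffusion_factor(rep(0, 5), silent_params())),
               matrix(0, 5, 7))
  expect_warning(diffusion_factor(c(-1, 0, 0, 0, 0), p), "clamped")
})

test_that("with the noise switched off Euler-Maruyama is the explicit Euler method", {
  p <- tab1_params()
  times <- seq(0, 2, by = 1e-3)
  tr <- em_simulate(p, default_init(), times, seed = 1, noise_scale = 0)
  y <- default_init()
  for (n in seq_len(200)) y <- pmax(y + 1e-3 * model_rhs(y, p), 0)
  expect_equal(unname(as.numeric(tr[201, -1])), unname(y), tolerance = 1e-12)
})

test_that("EM paths are reproducible and respect nonnegativity", {
  p <- tab1_params()
  times <- seq(0, 2, by = 1e-3)
  tr1 <- em_simulate(p, default_init(), times, seed = 42)
  tr2 <- em_simulate(p, default_init(), times, seed = 42)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_true(all(as.matrix(tr1[, -1]) >= 0))
  expect_error(em_simulate(p, default_init(), c(0, 0.1, 0.3), seed = 1),
               "uniform")
})

test_that("ensemble summaries are exact for one path and reproducible", {
  p <- tab1_params()
  times <- seq(0, 1, by = 1e-3)
  ens1 <- sde_ensemble(p, default_init(), times, n_real = 1, seed = 7)
  tr <- em_simulate(p, default_init(), times, seed = attr(ens1, "seeds")[1])
  expect_equal(ens1$mean_Taut, tr$Taut, tolerance = 1e-12)
  expect_true(all(as.matrix(ens1[, grep("^sd_", names(ens1))]) == 0))
  ens2 <- sde_ensemble(p, default_init(), times, n_real = 5, seed = 7,
                       record_every = 10)
  ens3 <- sde_ensemble(p, default_init(), times, n_real = 5, seed = 7,
                       record_every = 10)
  expect_identical(as.data.frame(ens2), as.data.frame(ens3))
  expect_identical(attr(ens2, "seeds"), attr(ens3, "seeds"))
})

test_that("the ensemble mean tracks the deterministic solution", {
  p <- tab1_params()
  times <- seq(0, 5, by = 1e-3)
  ens <- sde_ensemble(p, default_init(), times, n_real = 200, seed = 31,
                      record_every = 1000)
  tr <- simulate_ode(p, default_init(), ens$t)
  for (comp in c("S", "Tin", "Treg", "Taut", "I")) {
    m <- ens[[paste0("mean_", comp)]]
    se <- ens[[paste0("sd_", comp)]] / sqrt(attr(ens, "n_real"))
    z <- abs(m - tr[[comp]]) / pmax(se, 1e-9)
    expect_lt(z[2], 3)        # componentwise agreement at t = 1
    expect_lt(max(z[-1]), 5)  # family-wise bound over all sampled times
  }
})

test_that("halving the step changes ensemble means by less than Monte-Carlo error", {
  p <- tab1_params()
  n <- 100
  e1 <- sde_ensemble(p, default_init(), seq(0, 2, by = 2e-3), n_real = n,
                     seed = 5, record_every = 1000)
  e2 <- sde_ensemble(p, default_init(), seq(0, 2, by = 1e-3), n_real = n,
                     seed = 6, record_every = 2000)
  i1 <- nrow(e1); i2 <- nrow(e2)
  for (comp in c("S", "Taut")) {
    d <- abs(e1[[paste0("mean_", comp)]][i1] - e2[[paste0("mean_", comp)]][i2])
    se <- sqrt(e1[[paste0("sd_", comp)]][i1]^2 / n +
               e2[[paste0("sd_", comp)]][i2]^2 / n)
    expect_lt(d, 4 * se)
  }
})
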