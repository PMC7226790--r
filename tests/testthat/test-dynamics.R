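# independent literal transcription of the vector field, term by term
rhs_oracle <- function(x, p) {
  x <- unname(x)
  c(p$r * x[1] * (1 - x[1] / p$N) - p$mu_a * x[4] * x[1],
    p$lambda_in - p$d_in * x[2] - p$alpha * x[2] * x[1],
    p$lambda_r - p$d_r * x[3] + p$alpha * p$p * x[2] * x[1] +
      p$rho1 * x[3] * x[5],
    p$alpha * (1 - p$p) * x[2] * x[1] - p$d_a * x[4] -
      p$delta * x[3] * x[4] + p$rho2 * x[4] * x[5],
    p$sigma * x[4] - p$d_i * x[5])
}

test_that("the vector field vanishes at E1 and at the empty state", {
  p <- tab1_params()
  expect_equal(unname(model_rhs(c(0, 9000, 67500, 0, 0), p)), rep(0, 5))
  p0 <- update_params(p, lambda_in = 0, lambda_r = 0)
  expect_equal(unname(model_rhs(rep(0, 5), p0)), rep(0, 5))
  expect_error(model_rhs(c(1, 2, NA, 4, 5), p), "invalid state")
  expect_error(model_rhs(c(-1, 2, 3, 4, 5), p), "invalid state")
})

test_that("the vector field matches a term-by-term transcription", {
  p <- update_params(tab1_params(), rho2 = 6e-4, d_a = 0.9)
  sts <- rand_states(50, seed = 7)
  for (i in seq_len(nrow(sts)))
    expect_equal(unname(model_rhs(sts[i, ], p)), rhs_oracle(sts[i, ], p),
                 tolerance = 1e-14)
})

test_that("the analytic Jacobian matches central finite differences", {
  p <- tab1_params()
  sts <- rand_states(10, seed = 3)
  for (i in seq_len(nrow(sts))) {
    st <- sts[i, ]
    J <- model_jacobian(st, p)
    h <- pmax(abs(st), 1) * 1e-6
    Jfd <- sapply(1:5, function(j) {
      e <- rep(0, 5); e[j] <- h[j]
      (model_rhs(st + e, p) - model_rhs(pmax(st - e, 0), p)) / (2 * h[j])
    })
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("E1 has the expected closed form, spectrum and instability", {
  p <- tab1_params()
  e1 <- steady_state_E1(p)
  expect_equal(unname(e1$state), c(0, 9000, 67500, 0, 0))
  expect_identical(e1$stability, "unstable")
  expect_lt(e1$residual, 1e-9)
  ev <- e1$eigenvalues
  # block structure at S = Taut = I = 0 forces these four eigenvalues
  for (lam in c(p$r, -p$d_in, -p$d_r, -p$d_i))
    expect_lt(min(abs(ev - lam)), 1e-9)
  e1b <- steady_state_E1(update_params(p, lambda_in = 0))
  expect_equal(unname(e1b$state[2]), 0)
  expect_error(steady_state_E1(update_params(p, d_in = 0)), "degenerate")
})

test_that("E2 solves the regulatory quadratic and carries -d_in in its spectrum", {
  p <- update_params(tab1_params(), rho1 = 1e-4, rho2 = 4.4e-4)
  e2 <- steady_state_E2(p)
  expect_length(e2, 2)
  # generic polynomial-root oracle for Treg*
  roots <- Re(polyroot(c(p$lambda_r * p$rho2,
                         p$rho1 * p$d_a - p$rho2 * p$d_r,
                         p$rho1 * p$delta)))
  got <- sort(vapply(e2, function(s) s$state[["Treg"]], 0))
  expect_equal(got, sort(roots), tolerance = 1e-9)
  for (s in e2) {
    expect_lt(max(abs(model_rhs(s$state, p)) / pmax(abs(s$state), 1)), 1e-9)
    expect_lt(min(abs(s$eigenvalues + p$d_in)), 1e-8)
    # S-row decoupling at S = 0 gives the eigenvalue r - mu_a * Taut*
    expect_lt(min(abs(s$eigenvalues - (p$r - p$mu_a * s$state[["Taut"]]))),
              1e-8)
  }
  # negative discriminant: no cell-free autoimmune state exists
  # (rho1*d_a = rho2*d_r makes the linear term vanish, leaving -4*a*c < 0)
  pneg <- update_params(tab1_params(), rho1 = 1.6e-4, rho2 = 1e-4)
  expect_gt(0, (pneg$rho2 * pneg$d_r - pneg$rho1 * pneg$d_a)^2 -
               4 * pneg$rho1 * pneg$rho2 * pneg$delta * pneg$lambda_r)
  expect_length(steady_state_E2(pneg), 0)
})

test_that("the interior steady state is a genuine fixed point", {
  p <- tab1_params()
  ss <- find_interior_steady_state(p)
  expect_false(is.null(ss))
  expect_true(all(ss$state > 0))
  scale <- pmax(abs(ss$state), 1)
  expect_lt(max(abs(model_rhs(ss$state, p)) / scale), 1e-8)
  # long-horizon ODE relaxation lands on the same point (stable regime)
  tr <- simulate_ode(p, default_init(), seq(0, 200, by = 0.5))
  endpoint <- as.numeric(tr[nrow(tr), -1])
  expect_lt(max(abs(endpoint - ss$state) / scale), 1e-3)
})

test_that("stronger Treg suppression lowers the autoreactive steady level", {
  p <- tab1_params()
  taut <- vapply(c(1e-6, 3e-6, 1e-5, 3e-5), function(d) {
    ss <- find_interior_steady_state(update_params(p, delta = d))
    ss$state[["Taut"]]
  }, 0)
  expect_true(all(diff(taut) < 0))
})

test_that("ODE integration is consistent, convergent and nonnegative", {
  p <- tab1_params()
  e1 <- steady_state_E1(p)
  tr <- simulate_ode(p, e1$state, seq(0, 5, by = 0.1))
  expect_lt(max(abs(as.matrix(tr[, -1]) -
                    matrix(e1$state, nrow(tr), 5, byrow = TRUE))), 1e-5)
  tr1 <- simulate_ode(p, default_init(), seq(0, 30, by = 0.5),
                      rtol = 1e-8, atol = 1e-8)
  tr2 <- simulate_ode(p, default_init(), seq(0, 30, by = 0.5),
                      rtol = 5e-9, atol = 5e-9)
  end1 <- as.numeric(tr1[nrow(tr1), -1]); end2 <- as.numeric(tr2[nrow(tr2), -1])
  expect_lt(max(abs(end1 - end2) / pmax(abs(end2), 1)), 1e-6)
  expect_true(all(as.matrix(tr1[, -1]) > -1e-6))
  expect_error(simulate_ode(p, default_init(), c(0, 0, 1)), "increasing")
})

test_that("eigenvalues agree with the roots of the characteristic polynomial", {
  # Faddeev-LeVerrier expansion of det(xI - J) as an independent oracle
  p <- tab1_params()
  ss <- find_interior_steady_state(p)
  J <- model_jacobian(ss$state, p)
  n <- 5; M <- diag(n); cf <- c(1)
  for (k in 1:n) {
    M <- J %*% M
    ck <- -sum(diag(M)) / k
    cf <- c(cf, ck)
    M <- M + ck * diag(n)
  }
  roots <- polyroot(rev(cf))
  ev <- ss$eigenvalues
  for (r in roots) expect_lt(min(Mod(ev - r)), 1e-6 * max(Mod(ev)))
})

test_that("suppression strength separates damped from growing oscillatory regimes", {
  stable <- find_interior_steady_state(regime_point(delta = 2.22e-6))
  unstable <- find_interior_steady_state(regime_point(delta = 4.44e-7))
  expect_identical(stable$stability, "stable")
  expect_identical(unstable$stability, "unstable")
  # both regimes are oscillatory: the leading eigenvalues are complex
  expect_gt(abs(Im(stable$eigenvalues[1])), 0.1)
  expect_gt(abs(Im(unstable$eigenvalues[1])), 0.1)
})

test_that("stability maps reproduce the feasibility and threshold structure", {
  p <- tab1_params()
  sm1 <- stability_map(p, 5e-4, 8e-4, delta = 4.44e-7)
  ss <- find_interior_steady_state(update_params(p, rho1 = 5e-4, rho2 = 8e-4,
                                                 delta = 4.44e-7))
  expect_equal(sm1$max_re[1, 1], max(Re(ss$eigenvalues)), tolerance = 1e-9)
  rho1g <- seq(1e-4, 2e-3, length.out = 5)
  rho2g <- seq(1e-5, 1e-3, length.out = 5)
  sm <- stability_map(p, rho1g, rho2g, delta = 2.22e-6)
  # weak cytokine effect on autoreactive proliferation: stable wherever feasible
  col1 <- sm$max_re[, 1]
  expect_true(all(col1[!is.na(col1)] < 0))
  # along increasing rho2 at fixed rho1 a single stable->unstable switch,
  # with the threshold nondecreasing in rho1
  thresholds <- rep(NA_real_, length(rho1g))
  for (i in seq_along(rho1g)) {
    v <- sm$max_re[i, ]
    feas <- which(!is.na(v))
    signs <- v[feas] > 0
    expect_true(all(diff(signs) >= 0))  # once unstable, stays unstable
    thresholds[i] <- if (any(signs)) rho2g[feas[which(signs)[1]]] else Inf
  }
  expect_false(is.unsorted(thresholds))  # nondecreasing, Inf = never unstable
  expect_error(stability_map(p, numeric(), rho2g), "empty")
})
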