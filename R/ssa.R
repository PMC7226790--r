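#' Stoichiometry of the 12 transition channels
#'
#' Columns are the per-event state changes of the continuous-time Markov
#' chain, in channel order: (1) host-cell birth, (2) host-cell death
#' (natural plus killing by autoreactive cells), (3) naive T-cell
#' production, (4) naive T-cell death, (5) activation to regulatory, (6)
#' activation to autoreactive, (7) regulatory production plus
#' cytokine-driven proliferation, (8) regulatory death, (9) autoreactive
#' cytokine-driven proliferation, (10) autoreactive death plus Treg
#' suppression, (11) cytokine secretion, (12) cytokine clearance.
#'
#' @return A 5x12 integer matrix (rows = `S, Tin, Treg, Taut, I`).
#' @export
transition_stoichiometry <- function() {
  m <- cbind(c(1, 0, 0, 0, 0), c(-1, 0, 0, 0, 0),
             c(0, 1, 0, 0, 0), c(0, -1, 0, 0, 0),
             c(0, -1, 1, 0, 0), c(0, -1, 0, 1, 0),
             c(0, 0, 1, 0, 0), c(0, 0, -1, 0, 0),
             c(0, 0, 0, 1, 0), c(0, 0, 0, -1, 0),
             c(0, 0, 0, 0, 1), c(0, 0, 0, 0, -1))
  dimnames(m) <- list(state_names(), paste0("q", 1:12))
  m
}

#' Transition rates of the Markov chain
#'
#' The 12 channel rates at an integer state `n = (n1, ..., n5)`:
#' `q1 = b1*n1 + b2*n1^2` (clamped at 0 where the logistic birth term is
#' negative, i.e. `n1 > b1*N/r`), `q2 = d1*n1 + d2*n1^2 + mu_a*n1*n4`,
#' `q3 = lambda_in`, `q4 = d_in*n2`, `q5 = alpha*p*n1*n2`,
#' `q6 = alpha*(1-p)*n1*n2`, `q7 = lambda_r + rho1*n3*n5`, `q8 = d_r*n3`,
#' `q9 = rho2*n4*n5`, `q10 = (d_a + delta*n3)*n4`, `q11 = sigma*n4`,
#' `q12 = d_i*n5` (cytokine clearance).
#'
#' @param state Nonnegative integer 5-vector.
#' @param pars A [model_params()] object.
#' @return Named numeric vector of 12 nonnegative rates (events/day).
#' @export
transition_rates <- function(state, pars) {
  n <- as_state(state, integer = TRUE)
  q <- .rates12_cpp(as.numeric(n), param_vector(pars))
  names(q) <- paste0("q", 1:12)
  q
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Samples one exact path of the continuous-time Markov chain: waiting
#' times are exponential with the total rate, and the next channel is
#' chosen with probability proportional to its rate.  Counts remain
#' nonnegative integers; a state where all rates vanish is frozen until
#' `t_max`.
#'
#' At the full reference parameter scale total rates are of order 1e5 per
#' day, so exact simulation over long horizons is expensive; analyses at
#' that scale use the SDE ([em_simulate()]), and the exact sampler is
#' typically run on reduced-scale parameter sets.
#'
#' @param pars A [model_params()] object.
#' @param init Nonnegative integer 5-vector initial state.
#' @param t_max Final time (days), positive.
#' @param seed Integer seed (required: paths are reproducible by seed).
#' @param max_events Safety cap on the number of recorded events.
#' @return A [trajectory()] of kind `"ssa"` with one row per event (plus
#'   the initial state and the final time) and attribute `n_events`.
#' @export
ssa_simulate <- function(pars, init, t_max, seed, max_events = 2e6) {
  validate_params(pars)
  init <- as_state(init, integer = TRUE)
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be positive")
  if (missing(seed) || is.null(seed)) stop("seed must be supplied")
  set.seed(seed)
  res <- .ssa_core(param_vector(pars), as.integer(round(init)), t_max,
                   as.integer(max_events))
  if (res$status == 2)
    warning("SSA path truncated at ", max_events,
            " events (t = ", signif(res$times[length(res$times)], 6), ")")
  trajectory(res$times, res$states, kind = "ssa", seed = seed,
             n_events = res$n_events)
}

#' Deterministic drift implied by the transition channels
#'
#' The stoichiometry-weighted sum of channel rates,
#' `sum_k nu_k * q_k(state)`.  Wherever the logistic birth rate is not
#' clamped this equals [model_rhs()] exactly, which is the consistency
#' contract between the Markov chain and the ODE.
#'
#' @inheritParams transition_rates
#' @return Named numeric 5-vector.
#' @export
channel_drift <- function(state, pars) {
  n <- as_state(state)
  q <- .rates12_cpp(as.numeric(n), param_vector(pars))
  out <- as.numeric(transition_stoichiometry() %*% q)
  names(out) <- state_names()
  out
}
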