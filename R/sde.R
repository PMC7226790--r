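#' Drift of the Ito SDE model
#'
#' The drift vector of the chemical-Langevin-type SDE is the channel drift
#' evaluated at the continuous state, and coincides with the deterministic
#' vector field [model_rhs()] wherever the logistic birth rate is not
#' clamped.
#'
#' @param state Nonnegative numeric 5-vector.
#' @param pars A [model_params()] object.
#' @return Named numeric 5-vector.
#' @export
sde_drift <- function(state, pars) channel_drift(state, pars)

#' Diffusion factor H of the Ito SDE
#'
#' The 5x7 matrix `H` such that the SDE reads
#' `dY = mu(Y) dt + H(Y) dW` with seven independent Wiener processes, one
#' per birth/death channel group: (1) host-cell birth+death, (2) naive
#' T-cell birth+death, (3) conversion naive->regulatory, (4) conversion
#' naive->autoreactive, (5) regulatory birth+death, (6) autoreactive
#' birth+death, (7) cytokine birth+death.  Entries are square roots of
#' summed channel rates; the conversion columns carry `-sqrt(q5)` /
#' `-sqrt(q6)` in the naive row and `+sqrt(q5)` / `+sqrt(q6)` in the
#' regulatory / autoreactive rows, so that `H %*% t(H)` equals the
#' transition covariance `B = sum_k nu_k nu_k' q_k` -- the defining
#' contract of the Ito construction.
#'
#' Negative state components are clamped to zero (with a warning) before
#' rates are evaluated, since all rates vanish at empty populations.
#'
#' @inheritParams sde_drift
#' @return A 5x7 numeric matrix.
#' @export
diffusion_factor <- function(state, pars) {
  x <- as.numeric(state)
  if (length(x) != 5L || !all(is.finite(x)))
    stop("invalid state: need 5 finite components")
  if (any(x < 0)) {
    warning("negative state component(s) clamped to zero")
    x <- pmax(x, 0)
  }
  q <- .rates12_cpp(x, param_vector(pars))
  H <- matrix(0, 5, 7,
              dimnames = list(state_names(), paste0("W", 1:7)))
  H[1, 1] <- sqrt(q[1] + q[2])
  H[2, 2] <- sqrt(q[3] + q[4])
  H[2, 3] <- -sqrt(q[5]); H[3, 3] <- sqrt(q[5])
  H[2, 4] <- -sqrt(q[6]); H[4, 4] <- sqrt(q[6])
  H[3, 5] <- sqrt(q[7] + q[8])
  H[4, 6] <- sqrt(q[9] + q[10])
  H[5, 7] <- sqrt(q[11] + q[12])
  H
}

#' Euler-Maruyama integration of the SDE
#'
#' Integrates the Ito SDE on a uniform time grid with the explicit
#' Euler-Maruyama scheme
#' `Y[n+1] = Y[n] + mu(Y[n]) dt + H(Y[n]) sqrt(dt) xi[n]`,
#' where `xi[n]` is a standard normal 7-vector.  Components that step
#' below zero are clamped to zero; if the clamped fraction of steps
#' exceeds `clamp_warn`, a warning suggests a smaller step.
#'
#' @param pars A [model_params()] object.
#' @param init Nonnegative numeric 5-vector.
#' @param times Uniform increasing time grid (days); the grid spacing is
#'   the integration step (default grids use `dt = 1e-3`).
#' @param seed Integer seed (required).
#' @param clamp_warn Warn if more than this fraction of component-steps
#'   was clamped at zero.
#' @param noise_scale Factor multiplying the diffusion term; 0 degenerates
#'   the scheme to the explicit Euler method for the ODE (diagnostic use).
#' @return A [trajectory()] of kind `"sde"` with attribute `clamped`
#'   (number of clamped component-steps).
#' @export
em_simulate <- function(pars, init, times, seed, clamp_warn = 0.05,
                        noise_scale = 1) {
  validate_params(pars)
  init <- as_state(init)
  dts <- diff(times)
  if (length(dts) < 1L || any(dts <= 0))
    stop("times must be strictly increasing")
  dt <- dts[1]
  if (max(abs(dts - dt)) > 1e-9 * dt)
    stop("times must be a uniform grid (the grid spacing is the EM step)")
  if (missing(seed) || is.null(seed)) stop("seed must be supplied")
  set.seed(seed)
  res <- .em_core(param_vector(pars), as.numeric(init), dt,
                  length(times) - 1L, 1L, noise_scale)
  frac <- res$clamped / (5 * res$n_steps)
  if (frac > clamp_warn)
    warning(sprintf(paste0("%.1f%% of component-steps clamped at zero; ",
                           "consider a smaller time step"), 100 * frac))
  out <- trajectory(times, res$states, kind = "sde", seed = seed)
  attr(out, "clamped") <- res$clamped
  out
}

#' Ensemble of Euler-Maruyama realisations
#'
#' Runs `n_real` independent SDE paths (each with its own derived seed,
#' `seed + i - 1`, all recorded) and summarises the per-time mean and
#' standard deviation across realisations.  The per-path trajectories are
#' discarded; their final-time states are kept for stationary-variance
#' checks against the linear-noise approximation.
#'
#' @inheritParams em_simulate
#' @param n_real Number of realisations.
#' @param record_every Record every k-th grid point in the summary (the
#'   integration step is still the grid spacing).
#' @return An `ensemble_summary`: data frame with columns `t`,
#'   `mean_S ... mean_I`, `sd_S ... sd_I`; attributes `seeds`, `n_real`
#'   and `final_states` (an `n_real` x 5 matrix at the final grid time).
#' @export
sde_ensemble <- function(pars, init, times, n_real, seed, record_every = 1L) {
  validate_params(pars)
  init <- as_state(init)
  if (n_real < 1L) stop("n_real must be >= 1")
  if (missing(seed) || is.null(seed)) stop("seed must be supplied")
  dts <- diff(times)
  dt <- dts[1]
  if (any(dts <= 0) || max(abs(dts - dt)) > 1e-9 * dt)
    stop("times must be a uniform increasing grid")
  n_steps <- length(times) - 1L
  record_every <- as.integer(record_every)
  rec_idx <- seq(1L, length(times), by = record_every)
  seeds <- as.integer((as.numeric(seed) + seq_len(n_real) - 1) %%
                        .Machine$integer.max)
  pv <- param_vector(pars)
  s1 <- matrix(0, length(rec_idx), 5)
  s2 <- matrix(0, length(rec_idx), 5)
  finals <- matrix(NA_real_, n_real, 5,
                   dimnames = list(NULL, state_names()))
  for (i in seq_len(n_real)) {
    set.seed(seeds[i])
    res <- .em_core(pv, as.numeric(init), dt, n_steps, record_every, 1)
    st <- res$states
    s1 <- s1 + st
    s2 <- s2 + st^2
    finals[i, ] <- st[nrow(st), ]
  }
  mu <- s1 / n_real
  sd <- if (n_real > 1) sqrt(pmax(s2 - n_real * mu^2, 0) / (n_real - 1))
        else matrix(0, nrow(mu), 5)
  out <- data.frame(t = times[rec_idx], mu, sd)
  names(out) <- c("t", paste0("mean_", state_names()),
                  paste0("sd_", state_names()))
  class(out) <- c("ensemble_summary", "data.frame")
  attr(out, "seeds") <- seeds
  attr(out, "n_real") <- n_real
  attr(out, "final_states") <- finals
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble summary: %d realisations, %d time points>\n",
              attr(x, "n_real"), nrow(x)))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Write an ensemble summary as CSV
#'
#' Columns `t`, `mean_*`, `sd_*` per compartment.
#'
#' @param ens An `ensemble_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  utils::write.csv(as.data.frame(ens), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
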