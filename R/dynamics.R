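#' Right-hand side of the deterministic model
#'
#' Evaluates the vector field of the five-compartment autoimmune model:
#' \deqn{\dot S = rS(1 - S/N) - \mu_a T_{aut} S}
#' \deqn{\dot T_{in} = \lambda_{in} - d_{in} T_{in} - \alpha T_{in} S}
#' \deqn{\dot T_{reg} = \lambda_r - d_r T_{reg} + \alpha p T_{in} S + \rho_1 T_{reg} I}
#' \deqn{\dot T_{aut} = \alpha(1-p) T_{in} S - d_a T_{aut} - \delta T_{reg} T_{aut} + \rho_2 T_{aut} I}
#' \deqn{\dot I = \sigma T_{aut} - d_i I}
#'
#' @param state Numeric 5-vector `(S, Tin, Treg, Taut, I)`, components
#'   nonnegative.
#' @param pars A [model_params()] object.
#' @return Named numeric 5-vector of time derivatives.
#' @export
model_rhs <- function(state, pars) {
  x <- as_state(state)
  S <- x[[1]]; Tin <- x[[2]]; Treg <- x[[3]]; Taut <- x[[4]]; I <- x[[5]]
  out <- c(pars$r * S * (1 - S / pars$N) - pars$mu_a * Taut * S,
           pars$lambda_in - pars$d_in * Tin - pars$alpha * Tin * S,
           pars$lambda_r - pars$d_r * Treg + pars$alpha * pars$p * Tin * S +
             pars$rho1 * Treg * I,
           pars$alpha * (1 - pars$p) * Tin * S - pars$d_a * Taut -
             pars$delta * Treg * Taut + pars$rho2 * Taut * I,
           pars$sigma * Taut - pars$d_i * I)
  names(out) <- state_names()
  out
}

#' Analytic Jacobian of the model
#'
#' Partial derivatives of [model_rhs()] with respect to the state, used for
#' stability classification and the linear-noise approximation.
#'
#' @inheritParams model_rhs
#' @return A 5x5 numeric matrix with rows/columns ordered
#'   `(S, Tin, Treg, Taut, I)`.
#' @export
model_jacobian <- function(state, pars) {
  x <- as_state(state)
  S <- x[[1]]; Tin <- x[[2]]; Treg <- x[[3]]; Taut <- x[[4]]; I <- x[[5]]
  J <- matrix(0, 5, 5, dimnames = list(state_names(), state_names()))
  J[1, 1] <- pars$r * (1 - 2 * S / pars$N) - pars$mu_a * Taut
  J[1, 4] <- -pars$mu_a * S
  J[2, 1] <- -pars$alpha * Tin
  J[2, 2] <- -pars$d_in - pars$alpha * S
  J[3, 1] <- pars$alpha * pars$p * Tin
  J[3, 2] <- pars$alpha * pars$p * S
  J[3, 3] <- -pars$d_r + pars$rho1 * I
  J[3, 5] <- pars$rho1 * Treg
  J[4, 1] <- pars$alpha * (1 - pars$p) * Tin
  J[4, 2] <- pars$alpha * (1 - pars$p) * S
  J[4, 3] <- -pars$delta * Taut
  J[4, 4] <- -pars$d_a - pars$delta * Treg + pars$rho2 * I
  J[4, 5] <- pars$rho2 * Taut
  J[5, 4] <- pars$sigma
  J[5, 5] <- -pars$d_i
  J
}

#' Integrate the deterministic model
#'
#' Adaptive integration (lsoda via \pkg{deSolve}) of the ODE system on a
#' user-supplied time grid.
#'
#' @param pars A [model_params()] object.
#' @param init Initial state `(S, Tin, Treg, Taut, I)`, nonnegative.
#' @param times Increasing numeric vector of output times (days).
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @return A [trajectory()] of kind `"ode"`.
#' @examples
#' tr <- simulate_ode(model_params(), c(18000, 7200, 63000, 0, 0),
#'                    seq(0, 10, by = 0.1))
#' @export
simulate_ode <- function(pars, init, times, rtol = 1e-8, atol = 1e-8) {
  validate_params(pars)
  init <- as_state(init)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least two points")
  f <- function(t, y, parms) list(model_rhs(pmax(y, 0), pars))
  out <- deSolve::ode(y = init, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 1e5)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(out, "istate")[1],
         "); see deSolve::diagnostics for details")
  if (nrow(out) < length(times))
    stop("ODE integration stopped early at t = ", out[nrow(out), 1])
  trajectory(out[, 1], out[, 2:6], kind = "ode")
}

#' Steady state constructor
#'
#' @param state Named numeric 5-vector.
#' @param label One of `"E1"`, `"E2"`, `"E_star"`.
#' @param eigenvalues Complex 5-vector (may be NULL before classification).
#' @param stability `"stable"`, `"unstable"`, `"marginal"` or NA.
#' @param residual Max absolute value of the vector field at `state`.
#' @return A `steady_state` object.
#' @keywords internal
steady_state <- function(state, label, eigenvalues = NULL,
                         stability = NA_character_, residual = NA_real_) {
  structure(list(state = stats::setNames(as.numeric(state), state_names()),
                 label = label, eigenvalues = eigenvalues,
                 stability = stability, residual = residual),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady state %s: %s>\n", x$label,
              if (is.na(x$stability)) "unclassified" else x$stability))
  print(signif(x$state, 6))
  if (!is.null(x$eigenvalues)) {
    cat("eigenvalues:\n")
    print(signif(x$eigenvalues, 4))
  }
  invisible(x)
}

#' Cell-free steady state E1
#'
#' The state with no healthy cells, no autoreactive cells and no cytokine:
#' `E1 = (0, lambda_in/d_in, lambda_r/d_r, 0, 0)`.  It is unstable whenever
#' `r > 0`, since `r` is always one of its eigenvalues (a vanished host-cell
#' population regrows logistically).
#'
#' @param pars A [model_params()] object.
#' @param margin Stability margin passed to [classify_stability()].
#' @return A classified `steady_state` labelled `"E1"`.
#' @export
steady_state_E1 <- function(pars, margin = 1e-8) {
  validate_params(pars)
  if (pars$d_in == 0 || pars$d_r == 0)
    stop("degenerate parameters: d_in and d_r must be positive for E1")
  ss <- steady_state(c(0, pars$lambda_in / pars$d_in,
                       pars$lambda_r / pars$d_r, 0, 0), "E1")
  classify_stability(ss, pars, margin = margin)
}

#' Cell-free steady states E2 with active autoimmunity
#'
#' Steady states with `S = 0` but positive autoreactive T-cell and cytokine
#' levels.  `Treg*` solves the quadratic
#' `rho1*delta*Treg^2 + (rho1*d_a - rho2*d_r)*Treg + lambda_r*rho2 = 0`,
#' and the remaining components follow:
#' `Taut* = d_i*(d_a + delta*Treg*)/(rho2*sigma)`,
#' `I* = (d_a + delta*Treg*)/rho2`, `Tin* = lambda_in/d_in`.
#' Zero, one or two such states exist depending on the sign of the
#' discriminant; only fully positive solutions are returned.
#'
#' @inheritParams steady_state_E1
#' @return A list (possibly empty) of classified `steady_state` objects
#'   labelled `"E2"`.
#' @export
steady_state_E2 <- function(pars, margin = 1e-8) {
  validate_params(pars)
  if (pars$rho1 <= 0 || pars$rho2 <= 0 || pars$delta <= 0)
    stop("steady_state_E2 requires rho1, rho2, delta > 0")
  a <- pars$rho1 * pars$delta
  b <- pars$rho1 * pars$d_a - pars$rho2 * pars$d_r
  cc <- pars$lambda_r * pars$rho2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(list())
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  out <- list()
  for (Treg in roots) {
    if (!is.finite(Treg) || Treg <= 0) next
    Taut <- pars$d_i * (pars$d_a + pars$delta * Treg) / (pars$rho2 * pars$sigma)
    I <- (pars$d_a + pars$delta * Treg) / pars$rho2
    Tin <- pars$lambda_in / pars$d_in
    st <- c(0, Tin, Treg, Taut, I)
    if (any(st[-1] <= 0)) next
    out[[length(out) + 1L]] <-
      classify_stability(steady_state(st, "E2"), pars, margin = margin)
  }
  out
}

# closed-form reduction of the interior fixed point to one equation in S:
# given S in (0, N), all remaining components follow, and the Taut balance
# becomes a scalar function g(S) whose roots are interior steady states.
interior_components <- function(S, pars) {
  Taut <- pars$r * (1 - S / pars$N) / pars$mu_a
  I <- pars$sigma * Taut / pars$d_i
  Tin <- pars$lambda_in / (pars$d_in + pars$alpha * S)
  den <- pars$d_r - pars$rho1 * I
  if (den <= 0) return(NULL)  # Treg balance infeasible (unbounded Tregs)
  Treg <- (pars$lambda_r + pars$alpha * pars$p * Tin * S) / den
  c(S, Tin, Treg, Taut, I)
}

interior_gap <- function(S, pars) {
  st <- interior_components(S, pars)
  if (is.null(st)) return(NA_real_)
  pars$alpha * (1 - pars$p) * st[2] * S - pars$d_a * st[4] -
    pars$delta * st[3] * st[4] + pars$rho2 * st[4] * st[5]
}

# Newton polish of a full 5-D fixed point using the analytic Jacobian
newton_polish <- function(state, pars, maxit = 50, tol = 1e-12) {
  x <- as.numeric(state)
  for (i in seq_len(maxit)) {
    f <- model_rhs(pmax(x, 0), pars)
    scale <- pmax(abs(x), 1)
    if (max(abs(f) / scale) < tol) break
    J <- model_jacobian(pmax(x, 0), pars)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) break
    x <- x - step
  }
  x
}

#' Interior steady state E*
#'
#' Locates the coexistence fixed point with all five components positive:
#' the state of controlled low-level autoreactivity.  No closed form
#' exists; the search reduces the fixed-point conditions to a single
#' scalar equation in `S` on `(0, N)` (all other components have closed
#' forms given `S`), scans for sign changes, solves each bracket with
#' [stats::uniroot()], and polishes the result by Newton iteration on the
#' full system.  Since every interior fixed point satisfies the reduction,
#' the scan enumerates all of them up to its resolution; a fallback
#' multistart Newton search from perturbed E1 states covers near-tangent
#' root pairs that could slip between scan points.
#'
#' @inheritParams steady_state_E1
#' @param n_scan Number of scan points for the sign-change search.
#' @return A classified `steady_state` labelled `"E_star"`, or `NULL` if no
#'   positive fixed point is found.  If several interior fixed points
#'   exist, the one with the largest `S` is returned and the others are
#'   available in attribute `"others"`.
#' @export
find_interior_steady_state <- function(pars, margin = 1e-8, n_scan = 2000) {
  validate_params(pars)
  Sgrid <- seq(pars$N * 1e-8, pars$N * (1 - 1e-10), length.out = n_scan)
  gv <- vapply(Sgrid, interior_gap, 0, pars = pars)
  roots <- numeric()
  for (i in seq_len(n_scan - 1L)) {
    if (is.na(gv[i]) || is.na(gv[i + 1L])) next
    if (gv[i] == 0) roots <- c(roots, Sgrid[i])
    else if (gv[i] * gv[i + 1L] < 0)
      roots <- c(roots, stats::uniroot(interior_gap, c(Sgrid[i], Sgrid[i + 1L]),
                                       pars = pars, tol = 1e-13)$root)
  }
  states <- list()
  for (S in roots) {
    st <- interior_components(S, pars)
    if (is.null(st)) next
    st <- newton_polish(st, pars)
    if (all(st > 0)) states[[length(states) + 1L]] <- st
  }
  if (!length(states)) {
    # fallback multistart Newton from perturbed E1 states, in case a pair
    # of near-tangent roots slipped between scan points; a root is only
    # accepted as interior if every component is meaningfully positive
    # (Newton happily converges to boundary states with S ~ 1e-20)
    e1 <- c(0, pars$lambda_in / pars$d_in, pars$lambda_r / pars$d_r, 0, 0)
    starts <- list(e1 + c(pars$N / 2, 0, 0, 10, 10),
                   e1 + c(pars$N / 10, 0, 0, 1, 1),
                   e1 + c(pars$N * 0.9, 0, 0, 100, 100))
    for (s0 in starts) {
      st <- newton_polish(pmax(s0, 1e-6), pars)
      if (all(st > 1e-3) &&
          max(abs(model_rhs(st, pars)) / pmax(abs(st), 1)) < 1e-8) {
        states[[length(states) + 1L]] <- st
        break
      }
    }
  }
  if (!length(states)) return(NULL)
  # drop duplicates, order by S
  Svals <- vapply(states, `[`, 0, 1L)
  keep <- !duplicated(round(Svals, 6))
  states <- states[keep][order(Svals[keep])]
  sslist <- lapply(states, function(st)
    classify_stability(steady_state(st, "E_star"), pars, margin = margin))
  main <- sslist[[length(sslist)]]
  if (length(sslist) > 1L) attr(main, "others") <- sslist[-length(sslist)]
  main
}

#' Classify the stability of a steady state
#'
#' Fills in the eigenvalues of the Jacobian at the state and labels the
#' state `stable` if the largest real part is below `-margin`, `unstable`
#' if above `+margin`, and `marginal` otherwise.  Stability is always
#' decided from the numerical eigenvalues of the analytic Jacobian.
#'
#' @param ss A `steady_state` (or bare numeric 5-vector, which is wrapped).
#' @param pars A [model_params()] object.
#' @param margin Stability margin on the largest real part (1/day).
#' @return The `steady_state` with `eigenvalues`, `stability` and
#'   `residual` filled in.
#' @export
classify_stability <- function(ss, pars, margin = 1e-8) {
  if (!inherits(ss, "steady_state"))
    ss <- steady_state(ss, label = "E_star")
  ev <- eigen(model_jacobian(ss$state, pars), only.values = TRUE)$values
  ss$eigenvalues <- ev[order(-Re(ev))]
  mre <- max(Re(ev))
  ss$stability <- if (mre < -margin) "stable"
                  else if (mre > margin) "unstable" else "marginal"
  ss$residual <- max(abs(model_rhs(ss$state, pars)))
  ss
}

#' Stability map of E* over a cytokine-proliferation grid
#'
#' For each `(rho1, rho2)` grid cell, finds the interior steady state E*
#' and records the largest real part of its Jacobian eigenvalues; cells
#' where E* is infeasible carry `NA` as sentinel.
#'
#' @param pars Base [model_params()] (its `rho1`, `rho2`, `delta` are
#'   overridden cell-wise).
#' @param rho1_grid,rho2_grid Monotone increasing numeric vectors.
#' @param delta Treg suppression rate used for the whole map (defaults to
#'   `pars$delta`).
#' @return A `stability_map` object: list with the grids, `delta`, and the
#'   matrix `max_re` (rows = `rho1_grid`, columns = `rho2_grid`).
#' @export
stability_map <- function(pars, rho1_grid, rho2_grid, delta = pars$delta) {
  if (!length(rho1_grid) || !length(rho2_grid))
    stop("empty parameter grid")
  if (is.unsorted(rho1_grid, strictly = TRUE) ||
      is.unsorted(rho2_grid, strictly = TRUE))
    stop("grids must be strictly increasing")
  vals <- matrix(NA_real_, length(rho1_grid), length(rho2_grid),
                 dimnames = list(signif(rho1_grid, 6), signif(rho2_grid, 6)))
  for (i in seq_along(rho1_grid)) {
    for (j in seq_along(rho2_grid)) {
      p <- update_params(pars, rho1 = rho1_grid[i], rho2 = rho2_grid[j],
                         delta = delta)
      ss <- find_interior_steady_state(p)
      if (!is.null(ss)) vals[i, j] <- max(Re(ss$eigenvalues))
    }
  }
  structure(list(rho1_grid = rho1_grid, rho2_grid = rho2_grid,
                 delta = delta, max_re = vals),
            class = "stability_map")
}

#' @export
print.stability_map <- function(x, ...) {
  cat(sprintf("<stability map: %d x %d grid, delta = %g>\n",
              length(x$rho1_grid), length(x$rho2_grid), x$delta))
  cat(sprintf("  feasible cells: %d / %d; stable (max Re < 0): %d\n",
              sum(!is.na(x$max_re)), length(x$max_re),
              sum(x$max_re < 0, na.rm = TRUE)))
  invisible(x)
}

#' Default parameter grids for stability and variance maps
#'
#' The published maps do not print their axis ranges; these package
#' defaults span the region where the feasibility and stability boundaries
#' of E* are visible.
#'
#' @param n Number of points per axis.
#' @return List with `rho1_grid` and `rho2_grid`.
#' @export
default_map_grids <- function(n = 41) {
  list(rho1_grid = seq(1e-4, 5e-3, length.out = n),
       rho2_grid = seq(1e-5, 1e-3, length.out = n))
}

#' Reference operating points
#'
#' `regime_point()` returns parameters at the documented operating point
#' where the suppression rate delta switches the interior state E* between
#' damped (stable) and sustained (unstable) oscillatory regimes:
#' `rho1 = 5e-4`, `rho2 = 8e-4`, with E* stable at `delta = 2.22e-6` and
#' unstable at `delta = 4.44e-7`.  At the package default
#' `rho1 = 0.0022, rho2 = 4.4e-4`, E* is stable for both delta values (the
#' methods vignette discusses this calibration).
#'
#' @param pars Base parameters to override.
#' @param delta Suppression rate.
#' @return A `model_params` object.
#' @export
regime_point <- function(pars = model_params(), delta = 2.22e-6) {
  update_params(pars, rho1 = 5e-4, rho2 = 8e-4, delta = delta)
}

#' Default initial condition
#'
#' The reference simulation initial condition
#' `(S, Tin, Treg, Taut, I) = (18000, 7200, 63000, 0, 0)`.
#'
#' @return Named numeric 5-vector.
#' @export
default_init <- function() {
  stats::setNames(c(18000, 7200, 63000, 0, 0), state_names())
}
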