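#' Diffusion matrix B of the linear-noise approximation
#'
#' The transition covariance `B(state) = sum_k nu_k nu_k' q_k(state)` over
#' the 12 Markov-chain channels: the end product of the system-size
#' expansion of the master equation, and identically `H %*% t(H)` with the
#' SDE diffusion factor of [diffusion_factor()].
#'
#' @inheritParams sde_drift
#' @return A symmetric positive-semidefinite 5x5 matrix.
#' @export
diffusion_matrix_B <- function(state, pars) {
  x <- as_state(state)
  q <- .rates12_cpp(as.numeric(x), param_vector(pars))
  nu <- transition_stoichiometry()
  B <- nu %*% (t(nu) * q)
  dimnames(B) <- list(state_names(), state_names())
  (B + t(B)) / 2
}

#' Solve the continuous Lyapunov equation
#'
#' Finds the unique symmetric `C` with `A C + C A' + B = 0`, which exists
#' iff `A` is Hurwitz (all eigenvalues with negative real part).  Solved by
#' Kronecker vectorisation, `(I (x) A + A (x) I) vec(C) = -vec(B)`, which
#' is exact and cheap at this dimension.
#'
#' Near-boundary steady states of this model can have Jacobian entries
#' spanning many orders of magnitude (regulatory T-cell levels reach 1e7
#' while suppression rates sit at 1e-6), which makes the raw Kronecker
#' system numerically singular even though `A` is comfortably Hurwitz.
#' The solver therefore first balances `A` by a diagonal similarity
#' (Osborne equilibration, or a caller-supplied `scale` such as the
#' steady-state components), solves in balanced coordinates and maps the
#' covariance back.
#'
#' @param A Square drift matrix (Jacobian at a stable steady state).
#' @param B Symmetric diffusion matrix of the same dimension.
#' @param scale Optional positive diagonal balancing vector (e.g. the
#'   steady-state component magnitudes); derived from `A` by Osborne
#'   iteration when omitted.
#' @return The symmetric solution matrix `C`.
#' @examples
#' solve_lyapunov(matrix(-1), matrix(2))  # Ornstein-Uhlenbeck: B/(2|A|) = 1
#' @export
solve_lyapunov <- function(A, B, scale = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  d <- nrow(A)
  if (ncol(A) != d || any(dim(B) != d)) stop("A and B must be square, same size")
  if (max(abs(B - t(B))) > 1e-8 * max(1, max(abs(B))))
    stop("B must be symmetric")
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0)
    stop("unstable steady state: A is not Hurwitz (max Re eigenvalue = ",
         signif(max(Re(ev)), 4), "); no stationary covariance exists")
  if (is.null(scale)) {
    # Osborne equilibration: equalise row and column norms of D^-1 A D
    s <- rep(1, d)
    for (it in 1:20) {
      Ab <- A * outer(1 / s, s)
      for (i in seq_len(d)) {
        r <- sqrt(sum(Ab[i, -i]^2)); cn <- sqrt(sum(Ab[-i, i]^2))
        if (r > 0 && cn > 0) {
          f <- sqrt(r / cn)
          s[i] <- s[i] * f
          Ab[i, ] <- Ab[i, ] / f
          Ab[, i] <- Ab[, i] * f
        }
      }
    }
  } else {
    if (length(scale) != d || any(scale <= 0))
      stop("scale must be a positive vector of length nrow(A)")
    s <- as.numeric(scale)
  }
  Ab <- A * outer(1 / s, s)
  Bb <- B * outer(1 / s, 1 / s)
  Id <- diag(d)
  M <- kronecker(Id, Ab) + kronecker(Ab, Id)
  Cb <- matrix(solve(M, -as.numeric(Bb)), d, d)
  C <- Cb * outer(s, s)
  C <- (C + t(C)) / 2
  dimnames(C) <- dimnames(B)
  C
}

#' Stationary covariance of fluctuations around E*
#'
#' Linear-noise approximation at the interior steady state: with
#' `A = model_jacobian(E*)` and `B = diffusion_matrix_B(E*)`, the
#' stationary covariance of the Gaussian fluctuations solves the Lyapunov
#' equation `A C + C A' + B = 0`.  The headline scalar is
#' `Var(Taut) = C["Taut","Taut"]`, the variance of stochastic
#' oscillations in the autoreactive T-cell count; variances are reported
#' in absolute counts (no system-size rescaling).
#'
#' @param pars A [model_params()] object.
#' @param ss Optionally a precomputed `steady_state`; found with
#'   [find_interior_steady_state()] if omitted.
#' @return A `covariance_result`: list with `steady_state`, `A`, `B`, `C`,
#'   `var_Taut` and `residual` (norm of `A C + C A' + B`).
#' @export
stationary_covariance <- function(pars, ss = NULL) {
  validate_params(pars)
  if (is.null(ss)) ss <- find_interior_steady_state(pars)
  if (is.null(ss))
    stop("no feasible interior steady state E* at these parameters")
  if (ss$stability != "stable")
    stop("E* is ", ss$stability,
         "; the stationary covariance requires a stable steady state")
  A <- model_jacobian(ss$state, pars)
  B <- diffusion_matrix_B(ss$state, pars)
  C <- solve_lyapunov(A, B, scale = pmax(abs(ss$state), 1))
  res <- norm(A %*% C + C %*% t(A) + B, "F")
  structure(list(steady_state = ss, A = A, B = B, C = C,
                 var_Taut = C["Taut", "Taut"], residual = res),
            class = "covariance_result")
}

#' @export
print.covariance_result <- function(x, ...) {
  cat("<linear-noise stationary covariance at E*>\n")
  cat("  E*:", paste(signif(x$steady_state$state, 5), collapse = ", "), "\n")
  cat("  Var(Taut) =", signif(x$var_Taut, 6),
      " (sd =", signif(sqrt(x$var_Taut), 6), "cells)\n")
  cat("  Lyapunov residual (Frobenius):", signif(x$residual, 3), "\n")
  invisible(x)
}

#' Variance map of autoreactive-cell fluctuations
#'
#' For each `(rho1, rho2)` cell, the stationary variance `Var(Taut)` of the
#' linear-noise approximation around E*, with `NA` sentinels where E* is
#' infeasible or unstable.  The `status` matrix distinguishes the cases.
#'
#' @inheritParams stability_map
#' @return A `variance_map`: list with the grids, `delta`, matrices
#'   `var_Taut`, `max_re` and character matrix `status`
#'   (`"stable"`, `"unstable"`, `"marginal"`, `"infeasible"`).
#' @export
variance_map <- function(pars, rho1_grid, rho2_grid, delta = pars$delta) {
  if (!length(rho1_grid) || !length(rho2_grid))
    stop("empty parameter grid")
  dn <- list(signif(rho1_grid, 6), signif(rho2_grid, 6))
  v <- matrix(NA_real_, length(rho1_grid), length(rho2_grid), dimnames = dn)
  m <- v
  st <- matrix("infeasible", length(rho1_grid), length(rho2_grid),
               dimnames = dn)
  for (i in seq_along(rho1_grid)) {
    for (j in seq_along(rho2_grid)) {
      p <- update_params(pars, rho1 = rho1_grid[i], rho2 = rho2_grid[j],
                         delta = delta)
      ss <- find_interior_steady_state(p)
      if (is.null(ss)) next
      m[i, j] <- max(Re(ss$eigenvalues))
      st[i, j] <- ss$stability
      if (ss$stability == "stable")
        v[i, j] <- stationary_covariance(p, ss)$var_Taut
    }
  }
  structure(list(rho1_grid = rho1_grid, rho2_grid = rho2_grid,
                 delta = delta, var_Taut = v, max_re = m, status = st),
            class = "variance_map")
}

#' @export
print.variance_map <- function(x, ...) {
  cat(sprintf("<variance map: %d x %d grid, delta = %g>\n",
              length(x$rho1_grid), length(x$rho2_grid), x$delta))
  tab <- table(factor(x$status,
                      c("stable", "marginal", "unstable", "infeasible")))
  cat("  cells:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (any(x$status == "stable"))
    cat("  Var(Taut) range over stable cells:",
        paste(signif(range(x$var_Taut, na.rm = TRUE), 4), collapse = " .. "),
        "\n")
  invisible(x)
}

#' Write a variance map as CSV
#'
#' Long format: one row per cell with columns
#' `rho1,rho2,delta,max_re_eig,var_Taut,status`.
#'
#' @param vm A `variance_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variance_map <- function(vm, path) {
  df <- expand.grid(rho1 = vm$rho1_grid, rho2 = vm$rho2_grid,
                    KEEP.OUT.ATTRS = FALSE)
  ij <- cbind(match(df$rho1, vm$rho1_grid), match(df$rho2, vm$rho2_grid))
  df$delta <- vm$delta
  df$max_re_eig <- vm$max_re[ij]
  df$var_Taut <- vm$var_Taut[ij]
  df$status <- vm$status[ij]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
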