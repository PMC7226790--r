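#' Model parameters for the autoimmune T-cell model
#'
#' Constructs the full parameter set of the five-compartment model of
#' autoimmune dynamics: healthy host cells `S`, naive T cells `Tin`,
#' regulatory T cells `Treg`, autoreactive T cells `Taut` and a cytokine
#' growth factor `I`.  Defaults are the published reference values for the
#' deterministic rates, completed by documented package defaults for the
#' quantities the reference table leaves open (`d_a`, `rho1`, `rho2`, the
#' stochastic birth/death split of the logistic term, and the system-size
#' scale `Omega`).
#'
#' The logistic growth `r*S*(1 - S/N)` of healthy cells is decomposed for
#' the stochastic models into a birth rate `b1*n + b2*n^2` and a death rate
#' `d1*n + d2*n^2`, constrained by `b1 - d1 = r` and `d2 - b2 = r/N`.  Only
#' the differences are fixed deterministically; the package default takes
#' `d1 = r` (hence `b1 = 2r`), `b2 = -r/N` and `d2 = 0`, i.e. a logistic
#' birth term and a linear death term, which is the convention adopted for
#' cell populations.  The split changes stochastic properties such as
#' variances and persistence times, so `d1` is exposed.
#'
#' @param r Host-cell logistic growth rate (1/day).
#' @param N Host-cell carrying capacity (cells).
#' @param mu_a Rate at which autoreactive T cells kill healthy cells
#'   (1/(cell day)).
#' @param alpha Activation rate of naive T cells by antigen presented from
#'   healthy cells (1/(cell day)).
#' @param lambda_in,lambda_r Thymic production rates of naive and regulatory
#'   T cells (cells/day).
#' @param d_in,d_r,d_a,d_i Death/clearance rates of naive T cells,
#'   regulatory T cells, autoreactive T cells and cytokine (1/day).  `d_a`
#'   is not part of the published reference table; the package default 0.5
#'   is a documented calibration choice (see the methods vignette).
#' @param p Fraction of activated naive cells that become regulatory
#'   (dimensionless, in \[0,1\]); the remaining `1-p` become autoreactive.
#' @param delta Suppression rate of autoreactive T cells by regulatory T
#'   cells (1/(cell day)).
#' @param sigma Cytokine secretion rate by autoreactive T cells (1/day).
#' @param rho1,rho2 Cytokine-driven proliferation rates of regulatory and
#'   autoreactive T cells (1/(unit day)).  Defaults are the values used for
#'   the published simulation figures.
#' @param d1 Linear death coefficient of the host-cell birth/death split
#'   (1/day); `b1` is derived as `r + d1`.
#' @param b2 Quadratic birth coefficient (must be `<= 0`); default `-r/N`.
#' @param d2 Quadratic death coefficient; default 0, and `d2 - b2` must
#'   equal `r/N`.
#' @param Omega System-size scale (dimensionless metadata; state variables
#'   are absolute counts throughout the package).
#'
#' @return An object of class `model_params`: a named list of all rate
#'   constants, including the derived `b1`.
#' @examples
#' p <- model_params()
#' p$lambda_in / p$d_in   # naive T-cell homeostatic level: 9000
#' @export
model_params <- function(r = 2, N = 20000, mu_a = 0.0044, alpha = 4e-5,
                         lambda_in = 18000, d_in = 2,
                         lambda_r = 54000, d_r = 0.8,
                         p = 0.4, delta = 2.22e-6, sigma = 0.8, d_i = 0.6,
                         d_a = 0.5, rho1 = 0.0022, rho2 = 4.4e-4,
                         d1 = r, b2 = -r / N, d2 = 0, Omega = 1000) {
  pars <- list(r = r, N = N, mu_a = mu_a, alpha = alpha,
               lambda_in = lambda_in, d_in = d_in,
               lambda_r = lambda_r, d_r = d_r,
               p = p, delta = delta, sigma = sigma, d_i = d_i,
               d_a = d_a, rho1 = rho1, rho2 = rho2,
               b1 = r + d1, d1 = d1, b2 = b2, d2 = d2, Omega = Omega)
  class(pars) <- "model_params"
  validate_params(pars)
  pars
}

#' Validate a `model_params` object
#'
#' Checks the invariants of the parameter set: nonnegative rates (except
#' `b2 <= 0`), `0 <= p <= 1`, `N > 0`, and the stochastic-decomposition
#' constraints `b1 - d1 = r` and `d2 - b2 = r/N`.
#'
#' @param pars A `model_params` object (or bare named list with the same
#'   fields).
#' @return `pars`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(pars) {
  need <- c("r", "N", "mu_a", "alpha", "lambda_in", "d_in", "lambda_r",
            "d_r", "p", "delta", "sigma", "d_i", "d_a", "rho1", "rho2",
            "b1", "d1", "b2", "d2", "Omega")
  miss <- setdiff(need, names(pars))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  vals <- unlist(pars[need])
  if (!all(is.finite(vals)))
    stop("all parameters must be finite numbers")
  nonneg <- setdiff(need, c("b2"))
  bad <- nonneg[vals[nonneg] < 0]
  if (length(bad))
    stop("parameter(s) must be >= 0: ", paste(bad, collapse = ", "))
  if (pars$b2 > 0) stop("b2 must be <= 0")
  if (pars$p > 1) stop("p must lie in [0, 1]")
  if (pars$N <= 0) stop("N must be > 0")
  if (abs(pars$b1 - pars$d1 - pars$r) > 1e-8 * max(1, pars$r))
    stop("stochastic split must satisfy b1 - d1 = r")
  if (abs(pars$d2 - pars$b2 - pars$r / pars$N) > 1e-12 * max(1, pars$r / pars$N))
    stop("stochastic split must satisfy d2 - b2 = r/N")
  invisible(pars)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Autoimmune T-cell model parameters (per day):\n")
  nm <- setdiff(names(x), "Omega")
  vals <- vapply(nm, function(n) format(x[[n]], digits = 6), "")
  cat(paste0("  ", format(nm, width = 10), " = ", vals), sep = "\n")
  cat("  Omega      =", x$Omega, "(system-size metadata)\n")
  invisible(x)
}

#' Update parameters by name
#'
#' Convenience wrapper that replaces named entries of a `model_params`
#' object and revalidates.  When `r` or `N` change and the birth/death
#' split was not overridden in the same call, `b1` and `b2` are rederived
#' from the defaults `d1 = r`, `b2 = -r/N`, `d2 = 0`.
#'
#' @param pars A `model_params` object.
#' @param ... Named scalar replacements, e.g. `rho2 = 8e-4`.
#' @return The updated, validated `model_params` object.
#' @export
update_params <- function(pars, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(pars)
  unknown <- setdiff(names(repl), names(pars))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  out <- unclass(pars)
  out[names(repl)] <- repl
  if (any(c("r", "N") %in% names(repl)) &&
      !any(c("b1", "d1", "b2", "d2") %in% names(repl))) {
    out$d1 <- out$r
    out$b1 <- 2 * out$r
    out$b2 <- -out$r / out$N
    out$d2 <- 0
  }
  if ("d1" %in% names(repl) && !"b1" %in% names(repl))
    out$b1 <- out$r + out$d1
  class(out) <- "model_params"
  validate_params(out)
  out
}

#' Read model parameters from a key-value configuration file
#'
#' The configuration format is one `key = value` pair per line; blank
#' lines and lines starting with `#` are ignored.  Keys must be parameter
#' names accepted by [model_params()] (`d1`, `b2`, `d2` may be given to
#' override the birth/death split); unknown keys are rejected with an
#' error naming them.  Keys not present keep their package defaults.
#'
#' @param path Path to the configuration file.
#' @return A validated `model_params` object.
#' @seealso [write_params_config()]
#' @export
read_params_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, 1L) != 2L]
  if (length(bad))
    stop("malformed config line(s): ", paste(sQuote(bad), collapse = ", "))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric value for key(s): ",
         paste(keys[is.na(vals)], collapse = ", "))
  allowed <- names(formals(model_params))
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicated config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  do.call(model_params, as.list(stats::setNames(vals, keys)))
}

#' Write model parameters to a key-value configuration file
#'
#' @param pars A `model_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_params_config()]
#' @export
write_params_config <- function(pars, path) {
  validate_params(pars)
  keys <- setdiff(names(pars), "b1")  # b1 is derived as r + d1
  lines <- vapply(keys, function(k)
    sprintf("%s = %s", k, format(pars[[k]], digits = 17)), "")
  writeLines(c("# autoimmune T-cell model configuration", lines), path)
  invisible(path)
}

# parameters as the fixed-order numeric vector the compiled cores consume
param_vector <- function(pars) {
  c(pars$r, pars$N, pars$mu_a, pars$alpha, pars$lambda_in, pars$d_in,
    pars$lambda_r, pars$d_r, pars$p, pars$delta, pars$sigma, pars$d_i,
    pars$d_a, pars$rho1, pars$rho2, pars$b1, pars$d1, pars$b2, pars$d2)
}

#' Population-scale transformation of the model
#'
#' The model is invariant under a rescaling of the T-cell compartments by a
#' factor `k > 0`: replacing `Tin`, `Treg`, `Taut` by `k*Tin`, `k*Treg`,
#' `k*Taut` while replacing `mu_a`, `lambda_in`, `lambda_r`, `sigma`,
#' `delta` by `mu_a/k`, `k*lambda_in`, `k*lambda_r`, `sigma/k`, `delta/k`
#' yields a system with identical dynamics except that the T-cell
#' populations are scaled by `k`; `S`, the cytokine, and the rates `rho1`,
#' `rho2`, `d_in`, `d_r`, `d_a`, `d_i` are unchanged.  This is the lever
#' used to fit model output to count data whose absolute scale is not
#' identifiable (see [fit_scale_to_counts()]).
#'
#' @param pars A `model_params` object.
#' @param k Positive scaling factor of the T-cell populations.
#' @return A list with elements
#'   \describe{
#'     \item{params}{the transformed `model_params`,}
#'     \item{scale_state}{a function mapping a state vector
#'       `(S, Tin, Treg, Taut, I)` (or a matrix with those columns) to its
#'       scaled counterpart `(S, k*Tin, k*Treg, k*Taut, I)`,}
#'     \item{k}{the factor.}
#'   }
#' @examples
#' tr <- scale_transform(model_params(), k = 2)
#' tr$params$lambda_in  # 36000
#' @export
scale_transform <- function(pars, k) {
  validate_params(pars)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("k must be a positive scalar")
  newp <- update_params(pars,
                        mu_a = pars$mu_a / k,
                        lambda_in = k * pars$lambda_in,
                        lambda_r = k * pars$lambda_r,
                        sigma = pars$sigma / k,
                        delta = pars$delta / k)
  fac <- c(S = 1, Tin = k, Treg = k, Taut = k, I = 1)
  scale_state <- function(state) {
    if (is.matrix(state) || is.data.frame(state)) {
      out <- as.matrix(state)
      stopifnot(ncol(out) == 5L)
      sweep(out, 2L, fac, `*`)
    } else {
      stopifnot(length(state) == 5L)
      out <- as.numeric(state) * fac
      names(out) <- state_names()
      out
    }
  }
  list(params = newp, scale_state = scale_state, k = k)
}

state_names <- function() c("S", "Tin", "Treg", "Taut", "I")

# coerce/validate a 5-component state vector
as_state <- function(state, integer = FALSE) {
  x <- as.numeric(state)
  if (length(x) != 5L)
    stop("state must have 5 components (S, Tin, Treg, Taut, I)")
  if (!all(is.finite(x))) stop("invalid state: non-finite component")
  if (any(x < 0)) stop("invalid state: negative component")
  if (integer && any(abs(x - round(x)) > 1e-9))
    stop("invalid state: components must be integers for the Markov chain")
  names(x) <- state_names()
  x
}
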