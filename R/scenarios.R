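#' Run a named analysis scenario
#'
#' Desk-scale, fully scripted versions of the package's figure-level
#' experiments.  Every run writes its artifacts (CSV/JSON) plus a
#' `manifest.json` recording the resolved parameters, seeds and output
#' files, sufficient to reproduce the run bit-for-bit (deterministic
#' stages) or in distribution (stochastic stages).
#'
#' Scenarios:
#' \describe{
#'   \item{`ode-regimes`}{ODE trajectories at the regime operating point
#'     ([regime_point()]) for `delta = 2.22e-6` (damped onto E*) and
#'     `delta = 4.44e-7` (oscillations growing away from E*), each started
#'     from a small perturbation of E*; writes two trajectory CSVs and an
#'     `oscillation_metrics.json`.}
#'   \item{`ensemble`}{Euler-Maruyama ensemble at the default parameters
#'     from the reference initial condition, plus the matching ODE
#'     solution and band statistics.}
#'   \item{`stability-map`}{[stability_map()] on the default grids.}
#'   \item{`variance-map`}{[variance_map()] on the default grids.}
#'   \item{`synth-eau`}{Synthetic per-eye EAU counts with the default
#'     generator configuration.}
#'   \item{`compare`}{Synthetic EAU counts plus a scale-and-offset fit of
#'     the model Taut curve to them ([fit_scale_to_counts()]).}
#' }
#'
#' @param scenario Scenario name (see above).
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; per-realisation seeds are derived from it by a
#'   counter scheme and recorded in the manifest.
#' @param overrides Named list of [model_params()] overrides; unknown
#'   names are rejected.
#' @param n_real Number of stochastic realisations (ensemble scenario).
#' @param t_max Horizon (days) for trajectory scenarios.
#' @param dt Euler-Maruyama step (days).
#' @param grid_n Grid resolution per axis for the map scenarios.
#' @return Invisibly, the manifest as a list.
#' @export
run_scenario <- function(scenario, out_dir, seed = 1L,
                         overrides = list(), n_real = 200,
                         t_max = 100, dt = 1e-3, grid_n = 9) {
  valid <- c("ode-regimes", "ensemble", "stability-map", "variance-map",
             "synth-eau", "compare")
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% valid)
    stop("unknown scenario ", sQuote(scenario), "; valid scenarios: ",
         paste(valid, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pars <- do.call(update_params, c(list(model_params()), overrides))
  outputs <- character()
  add <- function(x, f) { outputs[length(outputs) + 1L] <<- f; x }
  extra <- list()

  if (scenario == "ode-regimes") {
    metrics <- list()
    for (lab in c("damped", "sustained")) {
      delta <- if (lab == "damped") 2.22e-6 else 4.44e-7
      p <- regime_point(pars, delta = delta)
      ss <- find_interior_steady_state(p)
      tr <- simulate_ode(p, ss$state * 1.001, seq(0, 40, by = 0.02))
      f <- file.path(out_dir, sprintf("ode_%s_delta%.3g.csv", lab, delta))
      add(write_trajectory(tr, f), f)
      om <- oscillation_metrics(tr, "Taut")
      metrics[[lab]] <- list(delta = delta,
                             max_re_eig = max(Re(ss$eigenvalues)),
                             stability = ss$stability,
                             frequency = om$frequency,
                             decay_rate = om$decay_rate,
                             amplitude_ratio = om$amplitude_ratio)
    }
    f <- file.path(out_dir, "oscillation_metrics.json")
    jsonlite::write_json(metrics, f, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)
    extra$metrics <- metrics
  } else if (scenario == "ensemble") {
    times <- seq(0, min(t_max, 50), by = dt)
    ens <- sde_ensemble(pars, default_init(), times, n_real = n_real,
                        seed = seed, record_every = max(1L, round(0.05 / dt)))
    f <- file.path(out_dir, "ensemble.csv"); add(write_ensemble(ens, f), f)
    tr <- simulate_ode(pars, default_init(), ens$t)
    f <- file.path(out_dir, "ode.csv"); add(write_trajectory(tr, f), f)
    bs <- band_statistics(ens, tr, after = 5)
    f <- file.path(out_dir, "band_statistics.json")
    jsonlite::write_json(list(coverage = bs$coverage,
                              mean_band_width = bs$mean_band_width),
                         f, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)
    extra$seeds <- attr(ens, "seeds")
    extra$coverage <- bs$coverage
  } else if (scenario == "stability-map") {
    g <- default_map_grids(grid_n)
    sm <- stability_map(pars, g$rho1_grid, g$rho2_grid)
    df <- expand.grid(rho1 = g$rho1_grid, rho2 = g$rho2_grid,
                      KEEP.OUT.ATTRS = FALSE)
    df$max_re_eig <- sm$max_re[cbind(match(df$rho1, g$rho1_grid),
                                     match(df$rho2, g$rho2_grid))]
    f <- file.path(out_dir, "stability_map.csv")
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, f)
  } else if (scenario == "variance-map") {
    g <- default_map_grids(grid_n)
    vm <- variance_map(pars, g$rho1_grid, g$rho2_grid)
    f <- file.path(out_dir, "variance_map.csv")
    add(write_variance_map(vm, f), f)
  } else if (scenario == "synth-eau") {
    cfg <- eau_config(seed = seed)
    counts <- generate_eau_counts(cfg)
    f <- file.path(out_dir, "eau_counts.csv"); add(write_counts(counts, f), f)
    extra$n_series <- vapply(split(counts$eye_id, counts$strain),
                             function(x) length(unique(x)), 0L)
  } else if (scenario == "compare") {
    cfg <- eau_config(seed = seed)
    counts <- generate_eau_counts(cfg)
    f <- file.path(out_dir, "eau_counts.csv"); add(write_counts(counts, f), f)
    tr <- simulate_ode(pars, default_init(), seq(0, 60, by = 0.05))
    attr(tr, "params") <- pars
    fit <- fit_scale_to_counts(tr, counts)
    f <- file.path(out_dir, "scale_fit.json")
    jsonlite::write_json(list(k = fit$k, offset = fit$offset,
                              residual = fit$residual, fit = fit$fit),
                         f, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)
    extra$fit <- fit[c("k", "offset", "residual")]
  }

  manifest <- list(scenario = scenario,
                   seed = seed,
                   params = unclass(pars),
                   settings = list(n_real = n_real, t_max = t_max, dt = dt,
                                   grid_n = grid_n),
                   outputs = basename(outputs))
  manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
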