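#' Oscillation metrics of a trajectory
#'
#' Quantifies oscillatory behaviour of one compartment over an analysis
#' window: the dominant frequency (periodogram of the mean-removed,
#' linearly detrended series, zero-padded for frequency resolution), the
#' exponential decay rate of oscillation peaks (slope of a least-squares
#' fit of log peak amplitude above the asymptotic baseline against peak
#' time; negative = damped, near zero or positive = sustained), the peak
#' times, and the amplitude ratio between the second and first half of the
#' window (half-amplitude = half the value range in each half).  An
#' amplitude ratio of at least 0.5 is the package's operational definition
#' of a sustained oscillation (no published threshold exists; see the
#' methods vignette).
#'
#' @param traj A [trajectory()] (or data frame with a `t` column).
#' @param compartment Column to analyse (default `"Taut"`).
#' @param window Numeric length-2 time window; default the full range.
#' @param min_prominence Peak prominence threshold as a fraction of the
#'   series range within the window.
#' @param pad Zero-padding factor for the periodogram (resolution is
#'   refined by this factor).
#' @return An `oscillation_metrics` list: `frequency` (1/day), `decay_rate`
#'   (1/day), `peak_times`, `peak_values`, `amplitude_ratio`, `n_peaks`.
#'   A constant series yields zero frequency, no peaks and amplitude
#'   ratio 0.
#' @export
oscillation_metrics <- function(traj, compartment = "Taut", window = NULL,
                                min_prominence = 0.05, pad = 7) {
  df <- as.data.frame(traj)
  if (!compartment %in% names(df)) stop("unknown compartment: ", compartment)
  if (is.null(window)) window <- range(df$t)
  sel <- df$t >= window[1] & df$t <= window[2]
  t <- df$t[sel]; x <- df[[compartment]][sel]
  if (length(t) < 64L) stop("need at least 64 samples in the window")
  # resample to a uniform grid if needed
  dts <- diff(t)
  if (max(dts) - min(dts) > 1e-9 * stats::median(dts)) {
    grid <- seq(t[1], t[length(t)], length.out = length(t))
    x <- stats::approx(t, x, xout = grid, rule = 2)$y
    t <- grid
  }
  dt <- t[2] - t[1]
  rng <- diff(range(x))
  if (rng == 0) {
    return(structure(list(frequency = 0, decay_rate = NA_real_,
                          peak_times = numeric(), peak_values = numeric(),
                          amplitude_ratio = 0, n_peaks = 0L),
                     class = "oscillation_metrics"))
  }
  # dominant frequency from the zero-padded periodogram
  sp <- stats::spec.pgram(stats::ts(x, deltat = dt), taper = 0,
                          detrend = TRUE, pad = pad, plot = FALSE)
  freq <- sp$freq[which.max(sp$spec)]
  # peaks: local maxima with prominence above a fraction of the range
  pk <- which(diff(sign(diff(x))) == -2) + 1L
  if (length(pk)) {
    prom <- vapply(pk, function(i) {
      # prominence relative to the shallower of the neighbouring valleys
      left <- if (any(pk < i)) max(pk[pk < i]) else 1L
      right <- if (any(pk > i)) min(pk[pk > i]) else length(x)
      x[i] - max(min(x[left:i]), min(x[i:right]))
    }, 0)
    pk <- pk[prom >= min_prominence * rng]
  }
  peak_times <- t[pk]; peak_values <- x[pk]
  # decay rate: exponential fit of peak height above the asymptotic level
  baseline <- mean(x[t >= t[1] + 0.75 * (t[length(t)] - t[1])])
  decay <- NA_real_
  amp <- peak_values - baseline
  ok <- amp > 0
  if (sum(ok) >= 2L)
    decay <- unname(stats::coef(stats::lm(log(amp[ok]) ~ peak_times[ok]))[2])
  # amplitude ratio second half / first half
  mid <- (window[1] + window[2]) / 2
  a1 <- diff(range(x[t <= mid])) / 2
  a2 <- diff(range(x[t >= mid])) / 2
  ratio <- if (a1 == 0) 0 else a2 / a1
  structure(list(frequency = freq, decay_rate = decay,
                 peak_times = peak_times, peak_values = peak_values,
                 amplitude_ratio = ratio, n_peaks = length(pk)),
            class = "oscillation_metrics")
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  cat(sprintf(paste0("<oscillation metrics: f = %s /day, decay = %s /day, ",
                     "%d peaks, amplitude ratio %.3g>\n"),
              signif(x$frequency, 4),
              if (is.na(x$decay_rate)) "NA" else signif(x$decay_rate, 4),
              x$n_peaks, x$amplitude_ratio))
  invisible(x)
}

#' Ensemble band statistics
#'
#' Builds the mean +/- 1 SD band of an ensemble summary and reports, per
#' time point and overall, whether/how often a deterministic trajectory
#' lies inside the band.
#'
#' @param ens An `ensemble_summary` from [sde_ensemble()].
#' @param traj_det A deterministic [trajectory()] covering the ensemble
#'   times (values are interpolated onto the ensemble grid).
#' @param compartment Compartment to compare (default `"Taut"`).
#' @param after Only times `>= after` enter the coverage fraction
#'   (transient exclusion); default 0.
#' @return A list with the per-time data frame `band`
#'   (`t, lower, upper, det, inside`) and scalars `coverage` (fraction of
#'   included times with the deterministic value inside the band) and
#'   `mean_band_width`.
#' @export
band_statistics <- function(ens, traj_det, compartment = "Taut", after = 0) {
  mcol <- paste0("mean_", compartment); scol <- paste0("sd_", compartment)
  if (!mcol %in% names(ens)) stop("unknown compartment: ", compartment)
  det <- stats::approx(traj_det$t, traj_det[[compartment]], xout = ens$t,
                       rule = 2)$y
  lower <- ens[[mcol]] - ens[[scol]]
  upper <- ens[[mcol]] + ens[[scol]]
  inside <- det >= lower & det <= upper
  keep <- ens$t >= after
  list(band = data.frame(t = ens$t, lower = lower, upper = upper,
                         det = det, inside = inside),
       coverage = mean(inside[keep]),
       mean_band_width = mean(upper[keep] - lower[keep]))
}

#' Fit the population scale and onset offset of the model to count data
#'
#' The model's absolute T-cell scale is not identifiable from count data
#' up to the invariant rescaling of [scale_transform()], and experimental
#' time is measured from immunisation whereas model time starts at the
#' beginning of the immune response.  This routine least-squares fits a
#' scale `k > 0` and a day offset aligning the model curve for one
#' compartment to the per-day mean of a count table:
#' `counts(day) ~ k * model(day - offset)`.  For a fixed offset the
#' optimal `k` has a closed form; the offset is scanned on a grid and the
#' best pair is polished by Nelder-Mead.
#'
#' @param model_traj A [trajectory()]; its `compartment` column is the
#'   model curve (interpolated between grid points).
#' @param counts A count table from [generate_eau_counts()] or
#'   [read_counts()]; must contain at least 4 distinct days.
#' @param compartment Model column to fit (default `"Taut"`).
#' @param offset_range Numeric length-2 range of candidate day offsets.
#' @param offset_step Grid step of the initial offset scan (days).
#' @return A list: `k`, `offset` (days), `residual` (root-mean-square over
#'   fitted days), `params` (the [scale_transform()]-transformed parameter
#'   set when `model_traj` carries a `params` attribute, else `NULL`), and
#'   the per-day data frame `fit` (`day, mean_count, fitted`).
#' @export
fit_scale_to_counts <- function(model_traj, counts, compartment = "Taut",
                                offset_range = c(0, 21), offset_step = 0.5) {
  df <- as.data.frame(counts)
  need <- c("day", "cd4_count")
  if (!all(need %in% names(df))) stop("counts must have columns day, cd4_count")
  agg <- stats::aggregate(cd4_count ~ day, df, mean)
  if (nrow(agg) < 4L) stop("counts must contain at least 4 distinct days")
  if (all(agg$cd4_count == 0)) stop("degenerate counts: all zero")
  mt <- model_traj$t; mx <- model_traj[[compartment]]
  if (is.null(mx)) stop("unknown compartment: ", compartment)
  curve <- function(tt) stats::approx(mt, mx, xout = tt, rule = 2)$y
  sse_at <- function(off) {
    m <- curve(agg$day - off)
    denom <- sum(m^2)
    k <- if (denom > 0) max(sum(agg$cd4_count * m) / denom, 0) else 0
    c(sse = sum((agg$cd4_count - k * m)^2), k = k)
  }
  offs <- seq(offset_range[1], offset_range[2], by = offset_step)
  scan <- vapply(offs, sse_at, c(sse = 0, k = 0))
  best <- which.min(scan["sse", ])
  fit0 <- c(log(max(scan["k", best], 1e-12)), offs[best])
  obj <- function(par) {
    k <- exp(par[1]); off <- par[2]
    if (off < offset_range[1] || off > offset_range[2]) return(Inf)
    sum((agg$cd4_count - k * curve(agg$day - off))^2)
  }
  opt <- stats::optim(fit0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  k <- exp(opt$par[1]); off <- opt$par[2]
  fitted <- k * curve(agg$day - off)
  pars <- attr(model_traj, "params")
  list(k = k, offset = off,
       residual = sqrt(opt$value / nrow(agg)),
       params = if (!is.null(pars)) scale_transform(pars, k)$params else NULL,
       fit = data.frame(day = agg$day, mean_count = agg$cd4_count,
                        fitted = fitted))
}
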