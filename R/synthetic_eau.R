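#' Configuration of the synthetic EAU count generator
#'
#' Defines the mean infiltration curve and sampling design of synthetic
#' per-eye CD4+ T-cell counts with the phenomenology of experimental
#' autoimmune uveoretinitis (EAU): a prodromal phase with very low
#' intra-retinal counts, a peak of infiltration between two and three
#' weeks post-immunisation, and subsequent regulation with decaying
#' oscillations around a sub-peak plateau.  Default replicate numbers are
#' 10 eyes for the B10.RIII strain and 8 for C57BL/6; absolute count
#' scales and the sampling schedule are documented package conventions
#' (the source experiments do not print theirs).
#'
#' @param strains Named list, one entry per mouse strain, each a list with
#'   `replicates` (number of eye series) and `peak_mean` (mean CD4+ count
#'   at the disease peak).
#' @param prodrome_end Last day of the prodromal phase (mean counts before
#'   this stay below a few percent of the peak).
#' @param peak_day Day of peak infiltration (between 14 and 21 by
#'   default).
#' @param rise_slope Time scale (days) of the logistic rise into the peak.
#' @param osc_freq Frequency of the post-peak damped oscillation (1/day).
#' @param osc_decay Decay rate of the post-peak oscillation (1/day).
#' @param plateau_frac Sub-peak plateau level as a fraction of the peak.
#' @param days Sampling days post-immunisation.
#' @param noise_sd Multiplicative inter-eye noise scale (log-normal sdlog).
#' @param seed Integer seed of the generator.
#' @return An `eau_config` list.
#' @export
eau_config <- function(strains = list(
                         B10.RIII = list(replicates = 10, peak_mean = 20000),
                         C57BL.6 = list(replicates = 8, peak_mean = 12000)),
                       prodrome_end = 10, peak_day = 17, rise_slope = 1.2,
                       osc_freq = 0.07, osc_decay = 0.08,
                       plateau_frac = 0.35,
                       days = c(0, 7, 10, 12, 14, 17, 21, 28, 35, 49),
                       noise_sd = 0.3, seed = 20200402) {
  cfg <- list(strains = strains, prodrome_end = prodrome_end,
              peak_day = peak_day, rise_slope = rise_slope,
              osc_freq = osc_freq, osc_decay = osc_decay,
              plateau_frac = plateau_frac, days = days,
              noise_sd = noise_sd, seed = seed)
  class(cfg) <- "eau_config"
  validate_eau_config(cfg)
  cfg
}

validate_eau_config <- function(cfg) {
  if (cfg$prodrome_end >= cfg$peak_day)
    stop("prodrome_end must come before peak_day")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(cfg$days < 0)) stop("sampling days must be nonnegative")
  if (!length(cfg$strains) || is.null(names(cfg$strains)))
    stop("strains must be a named list")
  for (s in cfg$strains) {
    if (is.null(s$replicates) || s$replicates < 2)
      stop("each strain needs at least 2 replicate eyes")
    if (is.null(s$peak_mean) || s$peak_mean <= 0)
      stop("each strain needs a positive peak_mean")
  }
  invisible(cfg)
}

#' Mean EAU infiltration curve
#'
#' The deterministic mean of the synthetic generator: a logistic rise
#' centred between the end of the prodrome and the peak day, multiplied
#' after the peak by a damped cosine relaxing onto a sub-peak plateau
#' (clamped at zero).  The family is the simplest that reproduces the
#' prodrome / peak / regulated-oscillation phenomenology; it can be
#' replaced by a model-driven curve in [generate_eau_counts()].
#'
#' @param t Days post-immunisation (vectorised).
#' @param cfg An [eau_config()].
#' @param peak_mean Peak scale (cells); defaults to 1 (unit curve).
#' @return Numeric vector of mean counts.
#' @export
eau_mean_curve <- function(t, cfg = eau_config(), peak_mean = 1) {
  t50 <- (cfg$prodrome_end + cfg$peak_day) / 2
  rise <- 1 / (1 + exp(-(t - t50) / cfg$rise_slope))
  u <- pmax(t - cfg$peak_day, 0)
  relax <- cfg$plateau_frac + (1 - cfg$plateau_frac) *
    exp(-cfg$osc_decay * u) * cos(2 * pi * cfg$osc_freq * u)
  peak_mean * pmax(rise * relax, 0)
}

#' Generate synthetic per-eye EAU count series
#'
#' Draws per-eye CD4+ count tables: for each strain and eye, the mean
#' curve at the sampling days is multiplied by i.i.d. log-normal noise
#' `exp(N(0, noise_sd^2))` and rounded to integer counts.  Counts are
#' positive and right-skewed across eyes, with across-eye spread growing
#' with the mean, as in the source experiments.  Reproducible for a fixed
#' config seed.
#'
#' @param cfg An [eau_config()].
#' @param mean_curve Optional function `f(day)` returning the mean count
#'   (e.g. a scaled model Taut curve); overrides the built-in curve and
#'   each strain's `peak_mean` is then ignored.
#' @return A `count_table` data frame with columns
#'   `strain, eye_id, day, cd4_count`.
#' @export
generate_eau_counts <- function(cfg = eau_config(), mean_curve = NULL) {
  validate_eau_config(cfg)
  set.seed(cfg$seed)
  rows <- list()
  for (strain in names(cfg$strains)) {
    sc <- cfg$strains[[strain]]
    mu <- if (is.null(mean_curve))
      eau_mean_curve(cfg$days, cfg, peak_mean = sc$peak_mean)
    else mean_curve(cfg$days)
    for (eye in seq_len(sc$replicates)) {
      noise <- if (cfg$noise_sd > 0)
        exp(stats::rnorm(length(cfg$days), 0, cfg$noise_sd)) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        strain = strain,
        eye_id = sprintf("%s_eye%02d", strain, eye),
        day = cfg$days,
        cd4_count = as.integer(round(mu * noise)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("count_table", "data.frame")
  out
}

#' Read / write per-eye count tables
#'
#' CSV with header `strain,eye_id,day,cd4_count`.  Reading validates the
#' table (nonnegative integer counts, nonnegative days) and reports
#' offending row numbers.
#'
#' @param counts A `count_table`.
#' @param path CSV path.
#' @return `write_counts`: `path` invisibly; `read_counts`: a
#'   `count_table`.
#' @export
write_counts <- function(counts, path) {
  need <- c("strain", "eye_id", "day", "cd4_count")
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ","))
  utils::write.csv(as.data.frame(counts)[, need], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, colClasses = c(strain = "character",
                                             eye_id = "character"))
  need <- c("strain", "eye_id", "day", "cd4_count")
  if (!all(need %in% names(df)))
    stop("count CSV must have columns ", paste(need, collapse = ","))
  bad <- which(!is.finite(df$cd4_count) | df$cd4_count < 0)
  if (length(bad))
    stop("negative or missing cd4_count in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(!is.finite(df$day) | df$day < 0)
  if (length(bad))
    stop("negative or missing day in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  df$day <- as.numeric(df$day)
  df$cd4_count <- as.integer(df$cd4_count)
  class(df) <- c("count_table", "data.frame")
  df
}
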