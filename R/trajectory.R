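#' Trajectory container
#'
#' A trajectory is a data frame with a time column `t` and the five state
#' columns `S, Tin, Treg, Taut, I`, carrying attributes `kind` (one of
#' `"ode"`, `"sde"`, `"ssa"`), `seed` (NULL for deterministic runs) and,
#' for Markov-chain sample paths, `n_events`.
#'
#' @param times Strictly increasing numeric vector of times (days).
#' @param states Numeric matrix with one row per time and 5 columns.
#' @param kind `"ode"`, `"sde"` or `"ssa"`.
#' @param seed Integer seed used to generate a stochastic path, or NULL.
#' @param n_events Number of Markov-chain events (SSA paths only).
#' @return A `trajectory` object (data frame).
#' @export
trajectory <- function(times, states, kind = c("ode", "sde", "ssa"),
                       seed = NULL, n_events = NULL) {
  kind <- match.arg(kind)
  states <- as.matrix(states)
  if (nrow(states) != length(times))
    stop("times and states must have the same length")
  if (ncol(states) != 5L) stop("states must have 5 columns")
  if (length(times) > 1L && any(diff(times) < 0))
    stop("times must be nondecreasing")
  out <- data.frame(t = as.numeric(times), states)
  names(out) <- c("t", state_names())
  class(out) <- c("trajectory", "data.frame")
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  if (!is.null(n_events)) attr(out, "n_events") <- n_events
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s, %d time points, t in [%g, %g]%s>\n",
              attr(x, "kind"), nrow(x), x$t[1], x$t[nrow(x)],
              if (!is.null(attr(x, "seed")))
                paste0(", seed ", attr(x, "seed")) else ""))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' The CSV has header `t,S,Tin,Treg,Taut,I` plus a `kind` column, one row
#' per time point; SSA paths carry an extra `n_events` column with the
#' total event count.
#'
#' @param traj A `trajectory`.
#' @param path Output CSV path.
#' @return `path` invisibly (write) or a `trajectory` (read; `kind` is
#'   restored from the `kind` column written alongside).
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df$kind <- attr(traj, "kind")
  if (!is.null(attr(traj, "n_events"))) df$n_events <- attr(traj, "n_events")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", state_names())
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ","))
  kind <- if ("kind" %in% names(df)) df$kind[1] else "ode"
  trajectory(df$t, as.matrix(df[, state_names()]), kind = kind,
             n_events = if ("n_events" %in% names(df)) df$n_events[1] else NULL)
}

state_matrix <- function(traj) as.matrix(traj[, state_names()])
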