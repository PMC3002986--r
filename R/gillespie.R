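#' Exact Gillespie simulation of a two-state channel population
#'
#' Simulates the birth-death process for the number of open channels under a
#' piecewise-constant activation schedule \eqn{p_\infty(t)}.  The total opening
#' propensity is \eqn{(N-n)\,p_\infty/\tau_a} and the closing propensity
#' \eqn{n\,(1-p_\infty)/\tau_a}.  Proposed waiting times are capped at the next
#' schedule breakpoint and redrawn there, which is statistically exact for
#' piecewise-constant rates (memorylessness of the exponential distribution).
#'
#' @param kinetics a [channel_kinetics()] object (finite `n_channels`).
#' @param rate_schedule data frame with columns `t_start` (sorted, first value
#'   must be `<= 0`) and `p_inf` in \[0,1\]; each row starts a segment of
#'   constant activation.
#' @param n_open_init initial number of open channels.
#' @param t_end simulation end time (ms).
#' @param seed RNG seed (required).
#' @return A `channel_trajectory`: list with `times` (event times, starting at
#'   0), `n_open` (count after each event), `window = c(0, t_end)` and
#'   `n_channels`.  The count is piecewise constant between events.
#' @export
simulate_two_state_gillespie <- function(kinetics, rate_schedule, n_open_init,
                                         t_end, seed) {
  stopifnot(inherits(kinetics, "channel_kinetics"))
  N <- kinetics$n_channels
  if (is.infinite(N))
    stop_param("Gillespie simulation needs a finite channel count")
  if (!is.data.frame(rate_schedule) ||
      !all(c("t_start", "p_inf") %in% names(rate_schedule)))
    stop_param("`rate_schedule` must be a data frame with columns ",
               "`t_start` and `p_inf`")
  ts <- rate_schedule$t_start
  ps <- rate_schedule$p_inf
  if (is.unsorted(ts, strictly = TRUE))
    stop_param("schedule breakpoints `t_start` must be strictly increasing")
  if (ts[1] > 0)
    stop_param("the first schedule segment must start at or before time 0")
  if (any(ps < 0 | ps > 1))
    stop_param("`p_inf` values must lie in [0, 1]")
  if (n_open_init < 0 || n_open_init > N)
    stop_param("`n_open_init` must lie in [0, N]")
  check_scalar(t_end, "t_end", lower = .Machine$double.xmin)
  set_sim_seed(seed)
  out <- cpp_gillespie_two_state(as.integer(N), kinetics$tau_a,
                                 as.numeric(ts), as.numeric(ps),
                                 as.integer(n_open_init), t_end)
  structure(list(times = out$times, n_open = out$n_open,
                 window = c(0, t_end), n_channels = N),
            class = "channel_trajectory")
}

#' @export
print.channel_trajectory <- function(x, ...) {
  cat(sprintf("Channel trajectory: N = %d, %d transitions on [%g, %g] ms\n",
              x$n_channels, length(x$times) - 1L, x$window[1], x$window[2]))
  invisible(x)
}

#' Open-channel count at arbitrary times
#'
#' @param traj a `channel_trajectory`.
#' @param t times at which to evaluate the (piecewise-constant) count.
#' @return integer vector of open counts.
#' @export
channel_count_at <- function(traj, t) {
  stopifnot(inherits(traj, "channel_trajectory"))
  traj$n_open[findInterval(t, traj$times)]
}

#' Time-averaged open fraction of a channel trajectory
#' @param traj a `channel_trajectory`.
#' @return mean open fraction over the observation window.
#' @export
channel_mean_fraction <- function(traj) {
  stopifnot(inherits(traj, "channel_trajectory"))
  tt <- c(traj$times, traj$window[2])
  sum(traj$n_open * diff(tt)) / diff(traj$window) / traj$n_channels
}

#' Stationary Ornstein-Uhlenbeck fluctuation path
#'
#' Samples the zero-mean Gaussian process with variance `sigma2` and
#' autocorrelation \eqn{\exp(-|s|/\tau_a)} on a regular grid, using the exact
#' conditional-Gaussian update (never Euler), so the discretization introduces
#' no error in the path statistics at the grid points.
#'
#' @param sigma2 stationary variance (>= 0).
#' @param tau_a correlation time (ms).
#' @param dt grid step (must satisfy `dt <= tau_a / 10`).
#' @param t_end path length (ms).
#' @param seed RNG seed (required).
#' @return An `ou_path`: list with `times`, `values`, `sigma2`, `tau_a`.
#' @export
simulate_ou_fluctuation <- function(sigma2, tau_a, dt, t_end, seed) {
  check_scalar(sigma2, "sigma2", lower = 0)
  check_scalar(tau_a, "tau_a", lower = .Machine$double.xmin)
  check_scalar(dt, "dt", lower = .Machine$double.xmin)
  check_scalar(t_end, "t_end", lower = dt)
  if (dt > tau_a / 10)
    stop_param("`dt` must not exceed tau_a / 10 (got dt = ", dt, ")")
  set_sim_seed(seed)
  n <- floor(t_end / dt)
  times <- seq(0, by = dt, length.out = n + 1L)
  if (sigma2 == 0) {
    values <- numeric(n + 1L)
  } else {
    rho <- exp(-dt / tau_a)
    eta1 <- stats::rnorm(1, sd = sqrt(sigma2))
    innov <- stats::rnorm(n, sd = sqrt(sigma2 * (1 - rho^2)))
    values <- c(eta1, as.numeric(
      stats::filter(innov, rho, method = "recursive", init = eta1)))
  }
  structure(list(times = times, values = values, sigma2 = sigma2,
                 tau_a = tau_a), class = "ou_path")
}

#' Export a channel trajectory as a two-column CSV (time, n_open)
#' @param traj a `channel_trajectory`.
#' @param path output file.
#' @export
write_channel_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "channel_trajectory"))
  utils::write.csv(data.frame(time = traj$times, n_open = traj$n_open),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read/write activation schedules as JSON lists of (t_start, p_inf) segments
#' @param schedule data frame with `t_start`, `p_inf`.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  write_json_file(lapply(seq_len(nrow(schedule)), function(i)
    list(t_start = schedule$t_start[i], p_inf = schedule$p_inf[i])), path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  data.frame(t_start = vapply(x, function(s) as.numeric(s$t_start), 0),
             p_inf = vapply(x, function(s) as.numeric(s$p_inf), 0))
}
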