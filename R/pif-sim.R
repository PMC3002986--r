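## Simulator front-ends for the four PIF variants and the step-response
## experiment.  All randomness flows through R's RNG, seeded once per call.

pif_sim_dispatch <- function(config, t_end, seed, adapt_mode, keep_traj = FALSE,
                             step_t = -1, step_dmu = 0) {
  stopifnot(inherits(config, "pif_config"))
  check_scalar(t_end, "t_end", lower = .Machine$double.xmin)
  set_sim_seed(seed)
  k <- config$kinetics
  a0 <- min(1, mean_adaptation(config))
  v0 <- stats::runif(1, 0, config$threshold)  # stationary phase of the PIF
  N <- k$n_channels
  n0 <- 0L
  eta0 <- 0
  sigma2_eta <- 0
  if (adapt_mode == 1L) {
    if (is.infinite(N)) adapt_mode <- 0L
    else n0 <- stats::rbinom(1L, as.integer(N), a0)
  }
  if (adapt_mode == 2L) {
    sigma2_eta <- if (is.infinite(N)) 0 else a0 * (1 - a0) / N
    if (sigma2_eta > 0) eta0 <- stats::rnorm(1, sd = sqrt(sigma2_eta))
  }
  out <- cpp_sim_pif(config$base_drive, config$adaptation_strength, k$tau_a,
                     k$pulse_duration, k$subthreshold_activation,
                     config$threshold, config$white_noise_intensity,
                     config$dt, t_end, as.numeric(N), adapt_mode, sigma2_eta,
                     a0, n0, eta0, v0, keep_traj, step_t, step_dmu)
  ov <- out$overlaps
  nsp <- length(out$spikes)
  if (nsp > 0 && ov / nsp > 0.01)
    warning(sprintf(paste0("spike pulses overlapped in %.1f%% of spikes ",
                           "(ISI < pulse duration); the pulse clock was ",
                           "restarted at each new spike"), 100 * ov / nsp),
            call. = FALSE)
  train <- spike_train(out$spikes, window = c(0, t_end), config = config,
                       seed = seed)
  if (keep_traj && adapt_mode == 1L) {
    attr(train, "channel_trajectory") <- structure(
      list(times = out$traj_t, n_open = out$traj_n, window = c(0, t_end),
           n_channels = N), class = "channel_trajectory")
  }
  train
}

#' Simulate the PIF neuron coupled to individual adaptation channels
#'
#' The channel population is simulated exactly (Gillespie with piecewise
#' constant spike-gated rates); for D = 0 the voltage is integrated
#' event-driven with analytic threshold-crossing times (statistically exact),
#' for D > 0 white noise is added on substeps of at most `config$dt` with
#' linearly interpolated crossings.
#'
#' @param config a [pif_config()] with finite channel number (an infinite
#'   count falls back to deterministic adaptation).
#' @param t_end simulated time (ms).
#' @param seed RNG seed (required).
#' @param keep_channel_trajectory also return the channel event trajectory as
#'   attribute `"channel_trajectory"`.
#' @return A [spike_train()].
#' @export
simulate_pif_channel <- function(config, t_end, seed,
                                 keep_channel_trajectory = FALSE) {
  pif_sim_dispatch(config, t_end, seed, adapt_mode = 1L,
                   keep_traj = keep_channel_trajectory)
}

#' Simulate the diffusion (Langevin) approximation of the channel model
#'
#' The open fraction is split into the deterministic filter \eqn{\bar a(t)}
#' (updated exactly) and an OU fluctuation with correlation time \eqn{\tau_a}
#' and stationary variance \eqn{\langle a\rangle(1-\langle a\rangle)/N}
#' (updated by the exact conditional-Gaussian pair together with its time
#' integral); voltage uses Euler-Maruyama for the white-noise part.
#'
#' @inheritParams simulate_pif_channel
#' @return A [spike_train()].
#' @export
simulate_pif_diffusion <- function(config, t_end, seed) {
  pif_sim_dispatch(config, t_end, seed, adapt_mode = 2L)
}

#' Simulate the deterministic-adaptation (white-noise) limit
#'
#' Infinitely many channels: the adaptation is the deterministic filter, the
#' only noise is the white current noise D.  With D = 0 the integration is
#' fully analytic (exact limit cycle).
#'
#' @inheritParams simulate_pif_channel
#' @return A [spike_train()].
#' @export
simulate_pif_white <- function(config, t_end, seed) {
  pif_sim_dispatch(config, t_end, seed, adapt_mode = 0L)
}

#' Simulate the reduced colored-noise PIF model
#'
#' PIF neuron driven by the constant effective drive plus an OU colored noise;
#' no adaptation feedback.  The OU process and its integral are advanced with
#' the exact conditional-Gaussian update; threshold crossings are located by
#' linear interpolation (the perfect integrator makes reset equivalent to
#' unwrapped level crossing, so no reset error accumulates).
#'
#' @param params an [eff_colored_params()] object.
#' @param t_end simulated time (ms).
#' @param seed RNG seed (required).
#' @param dt grid step; default `min(tau_eff, mean ISI) / 400`.
#' @return A [spike_train()].
#' @export
simulate_pif_colored <- function(params, t_end, seed, dt = NULL) {
  stopifnot(inherits(params, "eff_colored_params"))
  check_scalar(t_end, "t_end", lower = .Machine$double.xmin)
  if (is.null(dt)) dt <- min(params$tau_eff, params$mean_isi) / 400
  check_scalar(dt, "dt", lower = .Machine$double.xmin)
  set_sim_seed(seed)
  eta0 <- if (params$sigma2_eff > 0)
    stats::rnorm(1, sd = sqrt(params$sigma2_eff)) else 0
  sp <- cpp_sim_pif_colored(params$mu_eff, params$threshold, params$tau_eff,
                            params$sigma2_eff, eta0, dt, t_end)
  spike_train(sp, window = c(0, t_end), config = params, seed = seed)
}

#' Trial-averaged firing-rate response to a step of the base current
#'
#' Runs `n_trials` independent simulations (stochastic-adaptation channel
#' model when the config has finite N and D = 0 with `variant = "auto"`, else
#' the requested variant), applies a base-current step of height `step[2]` at
#' time `step[1]`, and estimates the time-dependent rate (PSTH).  An
#' exponential is fitted to the post-step PSTH, returning the fitted decay
#' constant and plateau; theory predicts relaxation towards the adapted rate
#' with effective time constant \eqn{\alpha\tau_a}.
#'
#' @param config a [pif_config()].
#' @param step numeric `c(t_on, delta_mu)`: step time (within the window) and
#'   step height.
#' @param n_trials number of trials (>= 100).
#' @param seed RNG seed (required).
#' @param t_end window length (default `step[1] + 6 * tau_a`).
#' @param binwidth PSTH bin (default 2 ms).
#' @param variant `"auto"`, `"channel"`, `"diffusion"` or `"white"`.
#' @return list with the `psth` (a `psth` object), `decay_constant`,
#'   `plateau_rate`, `onset_rate`, `pre_rate`, and the measured
#'   `adaptation_degree` \eqn{(r_\infty - r_{pre})/(r_{onset} - r_{pre})}.
#' @export
simulate_step_response <- function(config, step, n_trials, seed, t_end = NULL,
                                   binwidth = 2,
                                   variant = c("auto", "channel", "diffusion",
                                               "white")) {
  stopifnot(inherits(config, "pif_config"))
  variant <- match.arg(variant)
  if (length(step) != 2L) stop_param("`step` must be c(t_on, delta_mu)")
  t_on <- step[1]; dmu <- step[2]
  if (n_trials < 100) stop_param("`n_trials` must be at least 100")
  tau_a <- config$kinetics$tau_a
  if (is.null(t_end)) t_end <- t_on + 6 * tau_a
  if (t_on < 0 || t_on >= t_end)
    stop_param("the step must lie inside the observation window")
  seed <- check_seed(seed)
  mode <- switch(variant,
                 auto = if (is.finite(config$kinetics$n_channels) &&
                            config$white_noise_intensity == 0) 1L else
                          if (is.finite(config$kinetics$n_channels)) 2L else 0L,
                 channel = 1L, diffusion = 2L, white = 0L)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    trials[[i]] <- pif_sim_dispatch(config, t_end, derive_seed(seed, i),
                                    adapt_mode = mode,
                                    step_t = t_on, step_dmu = dmu)
  }
  ps <- time_dependent_rate(trials, binwidth = binwidth)
  ctr <- ps$t
  post <- ctr > t_on + binwidth
  pre <- ctr < t_on - binwidth
  pre_rate <- mean(ps$rate[pre])
  ## exponential fit r(t) = r_inf + A exp(-(t - t_on)/tau) on the post bins
  fit <- fit_exp_decay(ctr[post] - t_on, ps$rate[post], tau0 = tau_a)
  onset_rate <- fit$r_inf + fit$A
  list(psth = ps, decay_constant = fit$tau, plateau_rate = fit$r_inf,
       onset_rate = onset_rate, pre_rate = pre_rate,
       adaptation_degree = (fit$r_inf - pre_rate) / (onset_rate - pre_rate))
}

## least-squares exponential fit with a log-linear start and nls refinement
fit_exp_decay <- function(t, y, tau0) {
  r_inf0 <- mean(y[t > max(t) * 0.7])
  A0 <- mean(y[t < max(t) * 0.1]) - r_inf0
  if (!is.finite(A0) || abs(A0) < 1e-12) A0 <- diff(range(y)) + 1e-9
  obj <- function(p) {
    r <- y - (p[1] + p[2] * exp(-t / exp(p[3])))
    sum(r * r)
  }
  op <- stats::optim(c(r_inf0, A0, log(tau0)), obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  list(r_inf = op$par[1], A = op$par[2], tau = exp(op$par[3]))
}
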