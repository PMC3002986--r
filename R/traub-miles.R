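#' Configuration of the Traub-Miles neuron with M-type adaptation current
#'
#' Single-compartment conductance-based model (Ermentrout parameterization)
#' with sodium, delayed-rectifier potassium and leak currents plus a slow
#' M-type potassium current mediating spike-frequency adaptation:
#' \deqn{C\dot V = I - g_{Na}m^3h(V{-}E_{Na}) - g_K n^4(V{-}E_K)
#'   - g_L(V{-}E_L) - g_M a(V{-}E_K) + \sqrt{2D}\,\xi(t),}
#' where the M-current activation \eqn{a} is either the continuous gating
#' variable \eqn{w} (deterministic adaptation) or the open fraction of a
#' finite population of `n_channels` two-state channels whose voltage-dependent
#' rates are \eqn{w_\infty(V)/\tau_w(V)} (opening) and
#' \eqn{(1-w_\infty(V))/\tau_w(V)} (closing).
#'
#' The voltage dependence of \eqn{\tau_w} is scaled by `tauw_scale`, calibrated
#' so that the exponential buildup of \eqn{w} during 100 Hz firing matches the
#' nominal adaptation time constant `tau_a` (see [tm_w_buildup_constant()]).
#' Default `g_M` and `current` were calibrated to a 100 Hz firing rate at
#' N = 1000 stochastic channels (giving CV about 0.23); when comparing noise
#' sources, retune `current` with [tm_calibrate_drive()] so rates match.
#'
#' @param current applied current I (muA/cm^2).
#' @param noise_intensity white-noise intensity D ((muA/cm^2)^2 ms).
#' @param n_channels number of M channels (stochastic variant).
#' @param g_M maximal M conductance (mS/cm^2).
#' @param tau_a nominal adaptation time constant (ms) used for calibration
#'   bookkeeping.
#' @param tauw_scale scale factor of \eqn{\tau_w(V)}.
#' @param capacitance membrane capacitance (muF/cm^2).
#' @param g_Na,E_Na,g_K,E_K,g_L,E_L fast conductances (mS/cm^2) and reversal
#'   potentials (mV).
#' @param dt integration step (ms).
#' @param refresh_cap maximal Gillespie transition time before the
#'   voltage-dependent rates are refreshed (ms).
#' @param detect_threshold,refractory spike detection: upward crossing level
#'   (mV) and merge window (ms).
#' @return object of class `tm_config`.
#' @export
tm_config <- function(current = 29.5, noise_intensity = 0, n_channels = 1000,
                      g_M = 2, tau_a = 100, tauw_scale = 12.543,
                      capacitance = 1, g_Na = 100, E_Na = 50, g_K = 80,
                      E_K = -100, g_L = 0.1, E_L = -67,
                      dt = 0.01, refresh_cap = 0.05,
                      detect_threshold = 0, refractory = 2) {
  for (nm in c("capacitance", "g_Na", "g_K", "g_L", "g_M"))
    check_scalar(get(nm), nm, lower = 0)
  if (capacitance <= 0) stop_param("`capacitance` must be positive")
  check_scalar(noise_intensity, "noise_intensity", lower = 0)
  check_scalar(dt, "dt", lower = .Machine$double.xmin)
  check_scalar(refresh_cap, "refresh_cap", lower = .Machine$double.xmin)
  if (!is.infinite(n_channels)) {
    if (n_channels < 1 || n_channels != round(n_channels))
      stop_param("`n_channels` must be a positive integer or Inf")
  }
  structure(list(current = current, noise_intensity = noise_intensity,
                 n_channels = n_channels, g_M = g_M, tau_a = tau_a,
                 tauw_scale = tauw_scale, capacitance = capacitance,
                 g_Na = g_Na, E_Na = E_Na, g_K = g_K, E_K = E_K, g_L = g_L,
                 E_L = E_L, dt = dt, refresh_cap = refresh_cap,
                 detect_threshold = detect_threshold,
                 refractory = refractory), class = "tm_config")
}

#' @export
print.tm_config <- function(x, ...) {
  cat("Traub-Miles configuration with M-type adaptation\n")
  cat(sprintf("  I = %g muA/cm^2, D = %g, g_M = %g mS/cm^2, N = %s\n",
              x$current, x$noise_intensity, x$g_M, format(x$n_channels)))
  cat(sprintf("  dt = %g ms, tauw_scale = %g (nominal tau_a = %g ms)\n",
              x$dt, x$tauw_scale, x$tau_a))
  invisible(x)
}

#' Gating steady states and time constants of the Traub-Miles model
#'
#' @param V membrane voltage(s), mV.
#' @param config a [tm_config()] (only `tauw_scale` is used).
#' @return data frame with `m_inf, tau_m, h_inf, tau_h, n_inf, tau_n, w_inf,
#'   tau_w` per voltage.
#' @export
tm_gating <- function(V, config = tm_config()) {
  stopifnot(inherits(config, "tm_config"))
  out <- t(vapply(V, cpp_tm_gating, numeric(8),
                  tauw_scale = config$tauw_scale))
  as.data.frame(out)
}

tm_sim <- function(config, t_end, seed, stoch_m, keep_trace, store_every,
                   V0 = -65) {
  stopifnot(inherits(config, "tm_config"))
  check_scalar(t_end, "t_end", lower = config$dt)
  set_sim_seed(seed)
  w0 <- cpp_tm_gating(V0, config$tauw_scale)[["w_inf"]]
  N <- if (is.infinite(config$n_channels)) 1L
       else as.integer(config$n_channels)
  out <- cpp_sim_tm(config$capacitance, config$g_Na, config$E_Na, config$g_K,
                    config$E_K, config$g_L, config$E_L, config$g_M,
                    config$current, config$noise_intensity,
                    config$tauw_scale, config$dt, t_end,
                    stoch_m && is.finite(config$n_channels), N,
                    config$refresh_cap,
                    if (keep_trace) as.integer(store_every) else 0L,
                    config$detect_threshold, config$refractory, V0, w0)
  train <- spike_train(out$spikes, window = c(0, t_end), config = config,
                       seed = seed)
  if (keep_trace) {
    attr(train, "trace") <- data.frame(time_ms = out$trace_t,
                                       V_mV = out$trace_v,
                                       w = out$trace_w /
                                         if (stoch_m && is.finite(config$n_channels)) N else 1)
  }
  train
}

#' Simulate the Traub-Miles model with deterministic M current + white noise
#'
#' Stochastic Euler integration of the voltage (step `config$dt`) with
#' exponential-Euler updates of the gating variables; spikes are upward
#' crossings of `detect_threshold` merged within the refractory window.
#'
#' @param config a [tm_config()].
#' @param t_end simulated time (ms).
#' @param seed RNG seed (required).
#' @param keep_trace store the voltage/adaptation trace as attribute
#'   `"trace"` (`data.frame(time_ms, V_mV, w)`).
#' @param store_every store every k-th integration step (default 10).
#' @return A [spike_train()].
#' @export
simulate_tm_deterministic <- function(config, t_end, seed, keep_trace = FALSE,
                                      store_every = 10) {
  tm_sim(config, t_end, seed, stoch_m = FALSE, keep_trace = keep_trace,
         store_every = store_every)
}

#' Simulate the Traub-Miles model with stochastic M channels
#'
#' Hybrid scheme: deterministic integration of voltage and fast gating between
#' channel events; M-channel transitions drawn by the Gillespie algorithm with
#' voltage-dependent rates frozen for at most `refresh_cap` ms.  White noise
#' (mixed case) is allowed.
#'
#' @inheritParams simulate_tm_deterministic
#' @return A [spike_train()] (trace attribute contains the open fraction).
#' @export
simulate_tm_stochastic_m <- function(config, t_end, seed, keep_trace = FALSE,
                                     store_every = 10) {
  if (is.infinite(config$n_channels))
    return(simulate_tm_deterministic(config, t_end, seed, keep_trace,
                                     store_every))
  tm_sim(config, t_end, seed, stoch_m = TRUE, keep_trace = keep_trace,
         store_every = store_every)
}

#' Detect spikes in a sampled voltage trace
#'
#' Upward crossings of `threshold`; crossings closer than `refractory` to the
#' previous accepted spike are merged into it.
#'
#' @param trace data frame with columns `time_ms` and `V_mV` (uniformly
#'   sampled), or a numeric voltage vector with `times` supplied.
#' @param threshold detection level (mV), default 0.
#' @param refractory merge window (ms), default 2.
#' @param times sample times when `trace` is a bare numeric vector.
#' @return A [spike_train()].
#' @export
detect_spikes <- function(trace, threshold = 0, refractory = 2, times = NULL) {
  if (is.data.frame(trace)) {
    times <- trace$time_ms
    v <- trace$V_mV
  } else {
    v <- as.numeric(trace)
  }
  if (is.null(times) || !length(v)) stop_param("empty voltage trace")
  n <- length(v)
  up <- which(v[-n] < threshold & v[-1] >= threshold)
  sp <- numeric(0)
  last <- -Inf
  for (i in up) {
    frac <- (threshold - v[i]) / (v[i + 1] - v[i])
    ts <- times[i] + frac * (times[i + 1] - times[i])
    if (ts - last > refractory) {
      sp <- c(sp, ts)
      last <- ts
    }
  }
  spike_train(sp, window = range(times))
}

#' Effective buildup time constant of the M-current gating during firing
#'
#' Reproduces the calibration experiment for \eqn{\tau_w}: simulate the model
#' without the M current (`g_M = 0`, drive calibrated to ~100 Hz), then
#' integrate the w gating equation along the recorded voltage and fit an
#' exponential to the buildup of w.  The fitted constant should match the
#' nominal `tau_a` of the configuration.
#'
#' @param config a [tm_config()].
#' @param seed RNG seed.
#' @param t_sim simulated time (default `8 * tau_a`).
#' @return fitted buildup time constant (ms).
#' @export
tm_w_buildup_constant <- function(config, seed, t_sim = NULL) {
  stopifnot(inherits(config, "tm_config"))
  if (is.null(t_sim)) t_sim <- 8 * config$tau_a
  cfg0 <- config
  cfg0$g_M <- 0
  cfg0$noise_intensity <- 0
  cfg0$current <- tm_calibrate_drive(cfg0, target_rate = 0.1, seed = seed)
  tr <- simulate_tm_deterministic(cfg0, t_sim, seed, keep_trace = TRUE,
                                  store_every = 1)
  trace <- attr(tr, "trace")
  g <- tm_gating(trace$V_mV, config)
  dt <- diff(trace$time_ms[1:2])
  ee <- exp(-dt / g$tau_w)
  w <- numeric(nrow(trace))
  w[1] <- g$w_inf[1]
  for (i in 2:length(w)) w[i] <- g$w_inf[i] + (w[i - 1] - g$w_inf[i]) * ee[i]
  ## fit w(t) ~ w_inf_eff + A exp(-t/tau) on a coarse grid (cycle-averaged)
  bw <- 10  # ms
  bins <- floor(trace$time_ms / bw)
  wbar <- tapply(w, bins, mean)
  tbar <- (as.numeric(names(wbar)) + 0.5) * bw
  fit <- fit_exp_decay(tbar, as.numeric(wbar), tau0 = config$tau_a)
  fit$tau
}

#' Calibrate the applied current to a target firing rate
#'
#' Bisection on the applied current using short deterministic (or requested
#' variant) simulations; used because the drive must be retuned whenever the
#' noise intensity or channel number changes in order to compare statistics at
#' matched firing rate.
#'
#' @param config a [tm_config()].
#' @param target_rate target rate (1/ms), default 0.1 (100 Hz).
#' @param seed RNG seed.
#' @param t_sim simulation length per evaluation (ms).
#' @param variant `"deterministic"` or `"stochastic"`.
#' @param tol relative rate tolerance (default 2%).
#' @return calibrated current (muA/cm^2).
#' @export
tm_calibrate_drive <- function(config, target_rate = 0.1, seed = 1,
                               t_sim = 3000, variant = c("deterministic",
                                                         "stochastic"),
                               tol = 0.02) {
  stopifnot(inherits(config, "tm_config"))
  variant <- match.arg(variant)
  simfun <- if (variant == "deterministic") simulate_tm_deterministic
            else simulate_tm_stochastic_m
  rate_at <- function(I) {
    cfg <- config
    cfg$current <- I
    tr <- simfun(cfg, t_sim, seed)
    tt <- tr$times[tr$times > min(5 * config$tau_a, t_sim / 3)]
    length(tt) / (t_sim - min(5 * config$tau_a, t_sim / 3))
  }
  lo <- 0.5; hi <- 120
  r_hi <- rate_at(hi)
  if (r_hi < target_rate) return(hi)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target_rate) < tol * target_rate) return(mid)
    if (r > target_rate) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
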