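## Closed-form theory: inverse-Gaussian reference statistics, the weak-noise
## colored-noise ISI density and its cumulants, serial-correlation formulas for
## both noise scenarios, and the mean-field step response.

#' Inverse-Gaussian reference ISI distribution
#'
#' The ISI density of a perfect integrate-and-fire neuron driven by white
#' noise only (drift \eqn{\mu_e}, intensity D, threshold \eqn{\theta}) is the
#' inverse Gaussian with mean \eqn{\theta/\mu_e} and
#' \eqn{CV = \sqrt{2D/(\mu_e\theta)}}.  Its skewness is \eqn{3\,CV} and its
#' excess kurtosis \eqn{15\,CV^2}, which is what calibrates the rescaled shape
#' measures of [isi_shape()] to unity.
#'
#' @param mean mean ISI (> 0).
#' @param cv coefficient of variation (> 0).
#' @return object of class `ig_params`.
#' @export
ig_params <- function(mean, cv) {
  check_scalar(mean, "mean", lower = .Machine$double.xmin)
  check_scalar(cv, "cv", lower = .Machine$double.xmin)
  structure(list(mean = mean, cv = cv, shape = mean / cv^2),
            class = "ig_params")
}

#' @rdname ig_params
#' @param drift,noise_intensity,threshold alternative construction from the
#'   white-noise PIF parameters.
#' @export
ig_params_pif <- function(drift, noise_intensity, threshold = 1) {
  ig_params(mean = threshold / drift,
            cv = sqrt(2 * noise_intensity / (drift * threshold)))
}

#' Inverse-Gaussian density
#'
#' @param t evaluation times; the density is 0 for `t <= 0` by convention.
#' @param params an [ig_params()] object.
#' @export
ig_density <- function(t, params) {
  stopifnot(inherits(params, "ig_params"))
  m <- params$mean
  lam <- params$shape
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  tp <- t[pos]
  out[pos] <- sqrt(lam / (2 * pi * tp^3)) *
    exp(-lam * (tp - m)^2 / (2 * m^2 * tp))
  out
}

#' @rdname ig_density
#' @return `ig_moments`: list with `mean`, `cv`, `skewness` (= 3 CV),
#'   `kurtosis_excess` (= 15 CV^2) and the cumulants `kappa`.
#' @export
ig_moments <- function(params) {
  stopifnot(inherits(params, "ig_params"))
  m <- params$mean
  cv <- params$cv
  k2 <- (m * cv)^2
  list(mean = m, cv = cv, skewness = 3 * cv, kurtosis_excess = 15 * cv^2,
       kappa = c(kappa1 = m, kappa2 = k2, kappa3 = 3 * cv * k2^1.5,
                 kappa4 = 15 * cv^2 * k2^2))
}

## ---------------------------------------------------------------------------
## Weak-noise ISI density of the colored-noise PIF model.
##
## Non-dimensional variables: time in units of the OU correlation time tau,
## voltage in units of the threshold.  The unwrapped voltage is the Gaussian
## process x(s) = m s + int_0^s h, with h an OU process of unit correlation
## time and variance s2.  The density is the probability flux of the free
## process across the threshold, with the flux-weighted (rate-biased) initial
## condition p0(h) = (1 + h/m) phi(h) for the noise at the preceding spike
## (the weak-noise initial condition of the first-passage problem; it is what
## makes the mean ISI exactly theta/mu, independent of the noise).  All
## conditional moments are Gaussian, so the h-integral is available in closed
## form:
wn_flux <- function(s, m, s2) {
  beta <- exp(-s)
  b <- -expm1(-s)
  G <- ou_int_var0(s)        # Var of int h | h0, over sigma^2
  Vt <- ou_int_var(s)        # stationary Var of int h, over sigma^2
  d <- 1 - m * s
  mu_h <- d * b / Vt
  v_h <- s2 * G / Vt
  A <- m + b^2 * d / G
  B <- beta - b^3 / G
  E <- A + B * mu_h + (A * mu_h + B * (mu_h^2 + v_h)) / m
  stats::dnorm(d, 0, sqrt(s2 * Vt)) * E
}

## moments of the (renormalized, clipped-at-zero) flux density by composite
## Simpson quadrature on an adaptive window around the deterministic period
wn_quad <- function(m, s2, zlo = -12, zhi = 60, n = 12001) {
  That <- 1 / m
  w <- sqrt(s2 * ou_int_var(That)) / m
  lo <- max(1e-9 * That, That + zlo * w)
  hi <- That + zhi * w
  s <- seq(lo, hi, length.out = n)
  J <- pmax(wn_flux(s, m, s2), 0)
  wts <- simpson_weights(n, s[2] - s[1])
  Z <- sum(wts * J)
  k1 <- sum(wts * s * J) / Z
  ds <- s - k1
  m2 <- sum(wts * ds^2 * J) / Z
  m3 <- sum(wts * ds^3 * J) / Z
  m4 <- sum(wts * ds^4 * J) / Z
  list(norm = Z, kappa = c(kappa1 = k1, kappa2 = m2, kappa3 = m3,
                           kappa4 = m4 - 3 * m2^2),
       support = c(lo, hi))
}

#' Weak-noise ISI density of the colored-noise-driven PIF neuron
#'
#' Evaluates the weak-noise (probability-flux) approximation of the ISI
#' density for a perfect IF neuron driven by a constant drive plus OU colored
#' noise.  The raw asymptotic expression is only approximately normalized, so
#' by default it is renormalized numerically over
#' \eqn{[0,\ \langle I\rangle + 10\sqrt{\kappa_2}]} (shape-preserving).
#' Returns 0 for `t <= 0`.  A warning is issued when `epsilon >= 1`.
#'
#' @param t interval durations (same time units as the parameters).
#' @param params an [eff_colored_params()] object.
#' @param renormalize logical (default TRUE).
#' @return density values.
#' @export
colored_isi_density <- function(t, params, renormalize = TRUE) {
  stopifnot(inherits(params, "eff_colored_params"))
  if (params$epsilon >= 1)
    warning("epsilon >= 1: the weak-noise density is unreliable here",
            call. = FALSE)
  tau <- params$tau_eff
  m <- params$mu_eff * tau / params$threshold
  s2 <- params$sigma2_eff * tau^2 / params$threshold^2
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  out[pos] <- pmax(wn_flux(t[pos] / tau, m, s2), 0) / tau
  if (renormalize && s2 > 0) {
    q <- wn_quad(m, s2)
    out <- out / q$norm
  }
  out
}

#' @rdname colored_isi_density
#' @details `colored_isi_small_t()` is the quasi-static limit valid for
#'   intervals much shorter than the noise correlation time: the noise is
#'   frozen within the interval, \eqn{I = \theta/(\mu_{\rm eff}+\eta)}, with
#'   the rate-biased weight for \eqn{\eta}, giving
#'   \deqn{p_0(I) = \frac{\theta^2}{\sqrt{2\pi\sigma^2}\,\mu_{\rm eff} I^3}
#'     \exp\left(-\frac{(\theta/I-\mu_{\rm eff})^2}{2\sigma^2}\right).}
#'   Its mean is exactly \eqn{\theta/\mu_{\rm eff}} but the second and higher
#'   moments diverge, so it is only used for small-interval comparisons.
#' @export
colored_isi_small_t <- function(t, params) {
  stopifnot(inherits(params, "eff_colored_params"))
  th <- params$threshold
  mu <- params$mu_eff
  s2 <- params$sigma2_eff
  out <- numeric(length(t))
  pos <- is.finite(t) & t > 0
  tp <- t[pos]
  out[pos] <- th^2 / (sqrt(2 * pi * s2) * mu * tp^3) *
    exp(-(th / tp - mu)^2 / (2 * s2))
  out
}

#' @rdname colored_isi_density
#' @return `colored_isi_moments`: list with `mean`, `cv`, `rescaled_skewness`,
#'   `rescaled_kurtosis` and cumulants `kappa` of the (renormalized)
#'   weak-noise density, from high-resolution quadrature.
#' @export
colored_isi_moments <- function(params) {
  stopifnot(inherits(params, "eff_colored_params"))
  tau <- params$tau_eff
  m <- params$mu_eff * tau / params$threshold
  s2 <- params$sigma2_eff * tau^2 / params$threshold^2
  if (s2 <= 0)
    return(list(mean = params$mean_isi, cv = 0, rescaled_skewness = NA_real_,
                rescaled_kurtosis = NA_real_,
                kappa = c(kappa1 = params$mean_isi, kappa2 = 0, kappa3 = 0,
                          kappa4 = 0)))
  q <- wn_quad(m, s2)
  k <- q$kappa
  cv <- sqrt(k[["kappa2"]]) / k[["kappa1"]]
  list(mean = k[["kappa1"]] * tau, cv = cv,
       rescaled_skewness = (k[["kappa3"]] / k[["kappa2"]]^1.5) / (3 * cv),
       rescaled_kurtosis = (k[["kappa4"]] / k[["kappa2"]]^2) / (15 * cv^2),
       kappa = k * tau^(1:4))
}

#' Weak-noise cumulants and shape measures of the colored-noise PIF model
#'
#' Computes the first four ISI cumulants (in units of the noise correlation
#' time), the squared CV, and the rescaled skewness and kurtosis of the
#' weak-noise theory at the given \eqn{(\epsilon, \rho)}, together with their
#' leading orders in \eqn{\epsilon} (which depend on \eqn{\rho} alone) and the
#' large-\eqn{\rho} saturation constants of those leading orders
#' (\eqn{\tilde S \to 2}, \eqn{\tilde K \to 24/5}; derived from the
#' quasi-static limit with the rate-biased noise distribution at spike times).
#' As \eqn{\rho \to 0} all shape measures approach the inverse-Gaussian value
#' 1 and \eqn{CV^2 \to 2\epsilon}.
#'
#' @param epsilon weak-noise parameter \eqn{\sigma^2\tau/(\mu\theta)} (>= 0).
#' @param rho time-scale separation \eqn{\tau_{\rm eff}\, r} (> 0).
#' @return object of class `weak_noise_shape`: list with `kappa` (cumulants,
#'   time unit \eqn{\tau_{\rm eff}}), `cv2`, `rescaled_skewness`,
#'   `rescaled_kurtosis`, `leading_order` (the \eqn{\epsilon \to 0} values)
#'   and `saturation` (the \eqn{\rho\to\infty} constants of the leading
#'   orders).
#' @export
weak_noise_shape <- function(epsilon, rho) {
  check_scalar(epsilon, "epsilon", lower = 0)
  check_scalar(rho, "rho", lower = .Machine$double.xmin)
  m <- rho
  lead <- wn_shape_measures(m, 1e-4 * m)
  if (epsilon == 0) {
    kap <- c(kappa1 = 1 / m, kappa2 = 0, kappa3 = 0, kappa4 = 0)
    out <- list(kappa = kap, cv2 = 0,
                rescaled_skewness = lead$St, rescaled_kurtosis = lead$Kt)
  } else {
    full <- wn_shape_measures(m, epsilon * m)
    out <- list(kappa = full$kappa, cv2 = full$cv^2,
                rescaled_skewness = full$St, rescaled_kurtosis = full$Kt)
  }
  out$leading_order <- c(rescaled_skewness = lead$St,
                         rescaled_kurtosis = lead$Kt)
  out$saturation <- weak_noise_saturation()
  out$epsilon <- epsilon
  out$rho <- rho
  structure(out, class = "weak_noise_shape")
}

wn_shape_measures <- function(m, s2) {
  q <- wn_quad(m, s2)
  k <- q$kappa
  cv <- sqrt(k[["kappa2"]]) / k[["kappa1"]]
  list(kappa = k, cv = cv,
       St = (k[["kappa3"]] / k[["kappa2"]]^1.5) / (3 * cv),
       Kt = (k[["kappa4"]] / k[["kappa2"]]^2) / (15 * cv^2))
}

#' @rdname weak_noise_shape
#' @details In the quasi-static limit \eqn{\rho\to\infty} the interval is
#'   \eqn{I = \theta/(\mu+\eta)} with \eqn{\eta} drawn from the rate-biased
#'   stationary Gaussian; a fourth-order expansion in \eqn{\sigma/\mu} gives
#'   skewness \eqn{6\,CV} and excess kurtosis \eqn{72\,CV^2}, i.e. rescaled
#'   values 2 and 72/15 = 24/5.
#' @export
weak_noise_saturation <- function() {
  c(rescaled_skewness = 2, rescaled_kurtosis = 24 / 5)
}

#' @export
print.weak_noise_shape <- function(x, ...) {
  cat(sprintf("Weak-noise shape theory at epsilon = %g, rho = %g\n",
              x$epsilon, x$rho))
  cat(sprintf("  CV^2 = %.5g, rescaled skewness %.4f, rescaled kurtosis %.4f\n",
              x$cv2, x$rescaled_skewness, x$rescaled_kurtosis))
  cat(sprintf("  leading order: S = %.4f, K = %.4f (saturate at 2 and 4.8)\n",
              x$leading_order[1], x$leading_order[2]))
  invisible(x)
}

#' Serial correlation coefficients of the colored-noise-driven PIF neuron
#'
#' Weak-noise result: with \eqn{\hat T = \langle I\rangle/\tau_{\rm eff} =
#' 1/\rho},
#' \deqn{\rho_k = e^{-k\hat T}\,
#'   \frac{\cosh\hat T - 1}{\hat T - 1 + e^{-\hat T}},\qquad k \ge 1,}
#' a strictly positive, geometrically decaying sequence whose decay constant is
#' the ratio of effective correlation time to mean ISI; it is independent of
#' the noise variance.  All coefficients vanish as \eqn{\rho \to 0} (white
#' noise limit) and approach 1 as \eqn{\rho \to \infty}.
#'
#' @param lag positive integer lag(s).
#' @param params an [eff_colored_params()] object (only \eqn{\rho} is used).
#' @export
scc_colored <- function(lag, params) {
  stopifnot(inherits(params, "eff_colored_params"))
  if (any(lag < 1 | lag != round(lag)))
    stop_param("`lag` must be a positive integer")
  Th <- 1 / params$rho
  denom <- ou_int_var(Th) / 2          # That - 1 + exp(-That), stable
  ## e^{-k T}(cosh T - 1), written with non-positive exponents only
  num <- (exp((1 - lag) * Th) - 2 * exp(-lag * Th) + exp(-(1 + lag) * Th)) / 2
  if (Th < 0.02) {
    ## series-stable form: cosh(T)-1 = 2 sinh^2(T/2)
    num <- exp(-lag * Th) * 2 * sinh(Th / 2)^2
  }
  num / denom
}

#' Deterministic limit cycle of the adaptive PIF neuron
#'
#' For the noise-free neuron the phase plane (voltage, adaptation drive) has a
#' stable limit cycle: the adaptation drive decays from its reset value
#' \eqn{x_0} during the interval, jumps by \eqn{\Delta\delta/\tau_a} at each
#' spike, and the voltage drifts from reset to threshold in the period
#' \eqn{T^*}.  The two defining conditions (threshold crossing and
#' periodicity) give in closed form
#' \deqn{T^* = \frac{\theta + \Delta\delta}{\mu}, \qquad
#'       x_0 = \frac{\Delta\delta/\tau_a}{1 - e^{-T^*/\tau_a}}.}
#'
#' @param config a [pif_config()].
#' @return object of class `limit_cycle`: list with `period`, `x0`
#'   (adaptation drive just after reset), `jump` (drive jump per spike), plus
#'   the internals used by the SCC formula.
#' @export
limit_cycle <- function(config) {
  stopifnot(inherits(config, "pif_config"))
  k <- config$kinetics
  tau <- k$tau_a
  jump <- config$adaptation_strength * k$pulse_duration / tau
  Tstar <- 1 / stationary_rate_adapted(config)
  beta <- exp(-Tstar / tau)
  x0 <- if (jump > 0) jump / (1 - beta) else 0
  v_T <- config$base_drive - x0 * beta    # drift at threshold
  if (v_T <= 0)
    stop_param("no admissible limit cycle: drive at threshold is not positive")
  structure(list(period = Tstar, x0 = x0, jump = jump, beta = beta,
                 v_threshold = v_T, tau_a = tau), class = "limit_cycle")
}

#' Serial correlation coefficients for deterministic adaptation
#'
#' Weak-noise theory from the linearized stochastic map around the limit
#' cycle.  With \eqn{\beta = e^{-T^*/\tau_a}},
#' \eqn{u = \beta x_0 (1-\beta)/\dot v_T} and the map multiplier
#' \eqn{\gamma = \beta - u}, the SCC is the geometric sequence
#' \deqn{\rho_k = -\frac{u\,(1-\gamma\beta)}{u^2 + 1 - \gamma^2}\,
#'       \gamma^{\,k-1},\qquad k\ge 1.}
#' Odd lags are always negative; even lags are negative iff \eqn{\gamma > 0}
#' (oscillating SCC when \eqn{\gamma < 0}).  The noise intensity cancels in
#' the covariance/variance ratio, so the result is independent of D.
#'
#' @param lag positive integer lag(s).
#' @param config a [pif_config()] in the firing regime.
#' @export
scc_deterministic <- function(lag, config) {
  if (any(lag < 1 | lag != round(lag)))
    stop_param("`lag` must be a positive integer")
  lc <- limit_cycle(config)
  beta <- lc$beta
  u <- beta * lc$x0 * (1 - beta) / lc$v_threshold
  g <- beta - u
  if (u == 0) return(rep(0, length(lag)))
  -u * (1 - g * beta) / (u^2 + 1 - g^2) * g^(lag - 1)
}

#' Mean-field firing rate response to a base-current step
#'
#' The trial-averaged rate obeys the linear filter equation obtained by
#' averaging the adaptation dynamics: for a step \eqn{\Delta\mu} at
#' \eqn{t_0} the rate jumps instantaneously by \eqn{\Delta\mu/\theta} and then
#' relaxes exponentially to the adapted rate with the effective time constant
#' \eqn{\alpha\tau_a}:
#' \deqn{r(t) = r_\infty + \left(r_0 + \Delta\mu/\theta - r_\infty\right)
#'   e^{-(t-t_0)/(\alpha\tau_a)}, \quad t \ge t_0.}
#' The degree of adaptation \eqn{(r_\infty - r_0)/(r_{onset} - r_0)} equals
#' \eqn{\alpha} of [adaptation_degree()].
#'
#' @param t times (>= 0).
#' @param config a [pif_config()] describing the pre-step neuron.
#' @param step numeric `c(t_on, delta_mu)`.
#' @return rates at `t` (1/ms).
#' @export
rate_step_response <- function(t, config, step) {
  stopifnot(inherits(config, "pif_config"))
  if (length(step) != 2L) stop_param("`step` must be c(t_on, delta_mu)")
  t_on <- step[1]; dmu <- step[2]
  r0 <- stationary_rate_adapted(config)
  cfg_post <- config
  cfg_post$base_drive <- config$base_drive + dmu
  r_inf <- stationary_rate_adapted(cfg_post)
  alpha <- adaptation_degree(config)
  tau_eff <- alpha * config$kinetics$tau_a
  r_onset <- r0 + dmu / config$threshold
  ifelse(t < t_on, r0,
         r_inf + (r_onset - r_inf) * exp(-(t - t_on) / tau_eff))
}

#' Export a theory curve as a two-column CSV (abscissa, value)
#'
#' @param x abscissa values.
#' @param fn vectorized theory function.
#' @param path output file.
#' @param names column names.
#' @export
write_theory_curve <- function(x, fn, path, names = c("x", "value")) {
  df <- data.frame(x = x, value = fn(x))
  colnames(df) <- names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
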