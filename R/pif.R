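#' Configuration of the adaptive perfect integrate-and-fire neuron
#'
#' The subthreshold voltage obeys
#' \deqn{\dot v = \mu - \Delta\, a(t) + \sqrt{2D}\,\xi(t),}
#' with fire-and-reset at threshold \eqn{\theta} (reset to 0).  The open
#' fraction \eqn{a(t)} of the adaptation channels relaxes with time constant
#' \eqn{\tau_a} towards an activation that is 1 for a pulse of length
#' \eqn{\delta} after each spike and \eqn{p_0} otherwise.  \eqn{\mu} and
#' \eqn{\Delta} are in threshold units per ms (capacitance and threshold
#' absorbed), D in threshold\eqn{^2} per ms.
#'
#' The configuration is rejected when the stationary self-consistent rate
#' \eqn{r^* = (\mu - \Delta p_0) / (\theta + \Delta\delta(1 - p_0))}
#' is not positive (non-firing regime).
#'
#' @param base_drive base drive \eqn{\mu} (> 0).
#' @param adaptation_strength maximal adaptation drive \eqn{\Delta} (>= 0).
#' @param kinetics a [channel_kinetics()] object (\eqn{\tau_a, N, \delta, p_0}).
#' @param white_noise_intensity white-noise intensity \eqn{D} (>= 0).
#' @param threshold firing threshold \eqn{\theta} (default 1).
#' @param dt integration step for the Euler-Maruyama variants; default
#'   `min(tau_a, expected ISI) / 1e3`.
#' @return An object of class `pif_config`.
#' @export
pif_config <- function(base_drive, adaptation_strength, kinetics,
                       white_noise_intensity = 0, threshold = 1, dt = NULL) {
  stopifnot(inherits(kinetics, "channel_kinetics"))
  check_scalar(base_drive, "base_drive", lower = .Machine$double.xmin)
  check_scalar(adaptation_strength, "adaptation_strength", lower = 0)
  check_scalar(white_noise_intensity, "white_noise_intensity", lower = 0)
  check_scalar(threshold, "threshold", lower = .Machine$double.xmin)
  cfg <- structure(
    list(base_drive = base_drive, adaptation_strength = adaptation_strength,
         kinetics = kinetics, white_noise_intensity = white_noise_intensity,
         threshold = threshold, reset = 0, dt = dt),
    class = "pif_config")
  r <- stationary_rate_adapted(cfg)   # errors if not in the firing regime
  if (is.null(dt)) cfg$dt <- min(kinetics$tau_a, 1 / r) / 1e3
  else check_scalar(dt, "dt", lower = .Machine$double.xmin)
  cfg
}

#' Standard parameter set of the adaptive PIF model
#'
#' The reference configuration used throughout the package's tests and
#' experiments: threshold 1, \eqn{\mu} = 0.18/ms, \eqn{\Delta} = 0.8/ms,
#' \eqn{\tau_a} = 100 ms, \eqn{\delta} = 1 ms.  It fires at 100 Hz
#' (mean ISI 10 ms), has adaptation degree \eqn{\alpha = 5/9}, mean open
#' fraction 0.1 and time-scale separation \eqn{\tau_a r^* = 10}.
#'
#' @param N number of adaptation channels (default 1000; `Inf` for
#'   deterministic adaptation).
#' @param D white-noise intensity (default 0).
#' @param tau_a adaptation time constant in ms (default 100).
#' @param base_drive,adaptation_strength,pulse_duration,subthreshold_activation,dt
#'   overrides for the standard values.
#' @return A [pif_config()].
#' @export
pif_config_standard <- function(N = 1000, D = 0, tau_a = 100,
                                base_drive = 0.18, adaptation_strength = 0.8,
                                pulse_duration = 1, subthreshold_activation = 0,
                                dt = NULL) {
  pif_config(base_drive, adaptation_strength,
             channel_kinetics(N, tau_a, pulse_duration,
                              subthreshold_activation),
             white_noise_intensity = D, dt = dt)
}

#' @export
print.pif_config <- function(x, ...) {
  r <- stationary_rate_adapted(x)
  cat("Adaptive PIF configuration\n")
  cat(sprintf("  mu = %g, Delta = %g (per ms, threshold units), theta = %g\n",
              x$base_drive, x$adaptation_strength, x$threshold))
  cat(sprintf("  tau_a = %g ms, delta = %g ms, N = %s, p0 = %g, D = %g\n",
              x$kinetics$tau_a, x$kinetics$pulse_duration,
              format(x$kinetics$n_channels),
              x$kinetics$subthreshold_activation, x$white_noise_intensity))
  cat(sprintf("  stationary rate %g kHz (%g Hz), rho = %g, alpha = %g\n",
              r, 1000 * r, x$kinetics$tau_a * r, adaptation_degree(x)))
  invisible(x)
}

#' Self-consistent stationary firing rate and mean adaptation
#'
#' The PIF firing rate is drive over threshold; averaging the channel filter
#' gives the mean activation \eqn{\langle a\rangle = p_0 + r\delta(1-p_0)}, so
#' the stationary rate solves
#' \eqn{r = (\mu - \Delta\langle a\rangle)/\theta}, i.e.
#' \deqn{r^* = \frac{\mu - \Delta p_0}{\theta + \Delta\delta(1-p_0)}.}
#' The rate is independent of both noise sources, which is what makes the PIF
#' a clean testbed: noise can be varied without touching the adaptation.
#'
#' @param config a [pif_config()].
#' @return stationary firing rate (1/ms).
#' @export
stationary_rate_adapted <- function(config) {
  stopifnot(inherits(config, "pif_config"))
  k <- config$kinetics
  p0 <- k$subthreshold_activation
  r <- (config$base_drive - config$adaptation_strength * p0) /
    (config$threshold +
       config$adaptation_strength * k$pulse_duration * (1 - p0))
  if (!is.finite(r) || r <= 0)
    stop_param("configuration is in the non-firing regime: stationary rate ",
               "would be ", signif(r, 4), " <= 0")
  r
}

#' @rdname stationary_rate_adapted
#' @return `mean_adaptation`: the stationary mean open fraction
#'   \eqn{\langle a\rangle}.
#' @export
mean_adaptation <- function(config) {
  k <- config$kinetics
  p0 <- k$subthreshold_activation
  p0 + stationary_rate_adapted(config) * k$pulse_duration * (1 - p0)
}

#' Degree of adaptation
#'
#' The common scaling factor of the colored-noise reduction,
#' \eqn{\alpha = \theta / (\theta + \Delta\delta(1-p_0))}; it equals the ratio
#' of the steady-state to the instantaneous firing-rate increase after a step
#' of the base current ("percentage adaptation").
#'
#' @param config a [pif_config()].
#' @export
adaptation_degree <- function(config) {
  stopifnot(inherits(config, "pif_config"))
  k <- config$kinetics
  config$threshold /
    (config$threshold + config$adaptation_strength * k$pulse_duration *
       (1 - k$subthreshold_activation))
}

#' Non-dimensional form of a PIF configuration
#'
#' Voltage is measured in units of the threshold \eqn{\theta} and time in units
#' of \eqn{\tau_a}.  The dynamics is then fully determined by the four
#' parameters \eqn{\hat\mu = \mu\tau_a/\theta}, \eqn{\hat\Delta =
#' \Delta\tau_a/\theta}, \eqn{\hat\delta = \delta/\tau_a}, \eqn{\hat D =
#' D\tau_a/\theta^2}, plus the channel-noise intensity
#' \eqn{\hat D_a = \hat\Delta^2 \langle a\rangle(1-\langle a\rangle)/N}
#' (and \eqn{p_0} if subthreshold activation is allowed).  Given \eqn{\theta}
#' and \eqn{\tau_a} the map is a bijection; [dimensionalize()] inverts it.
#'
#' @param config a [pif_config()].
#' @return An object of class `nondim_config`.
#' @export
nondimensionalize <- function(config) {
  stopifnot(inherits(config, "pif_config"))
  k <- config$kinetics
  th <- config$threshold
  cni <- channel_noise_intensity(k, stationary_rate_adapted(config),
                                 config$adaptation_strength, th)
  structure(list(
    mu_hat = config$base_drive * k$tau_a / th,
    delta_drive_hat = config$adaptation_strength * k$tau_a / th,
    pulse_hat = k$pulse_duration / k$tau_a,
    d_white_hat = config$white_noise_intensity * k$tau_a / th^2,
    d_channel_hat = cni$noise_intensity,
    p0 = k$subthreshold_activation,
    n_channels = k$n_channels,
    threshold_ref = 1, reset_ref = 0), class = "nondim_config")
}

#' @rdname nondimensionalize
#' @param nd a `nondim_config`.
#' @param threshold,tau_a the dimensional scales to restore.
#' @export
dimensionalize <- function(nd, threshold, tau_a) {
  stopifnot(inherits(nd, "nondim_config"))
  pif_config(base_drive = nd$mu_hat * threshold / tau_a,
             adaptation_strength = nd$delta_drive_hat * threshold / tau_a,
             kinetics = channel_kinetics(nd$n_channels, tau_a,
                                         nd$pulse_hat * tau_a, nd$p0),
             white_noise_intensity = nd$d_white_hat * threshold^2 / tau_a,
             threshold = threshold)
}

#' Effective parameters of the colored-noise reduction
#'
#' For pure channel noise (D = 0) and slow adaptation, eliminating the
#' adaptation feedback maps the model onto a PIF neuron driven by a constant
#' effective drive plus an OU colored noise, with every effective parameter
#' scaled by the common factor \eqn{\alpha} (the degree of adaptation):
#' \deqn{\mu_{\rm eff} = \alpha(\mu - \Delta p_0),\quad
#'       \tau_{\rm eff} = \alpha\tau_a,\quad
#'       \sigma^2_{\rm eff} = \alpha\,\Delta^2\sigma_a^2,}
#' with \eqn{\sigma_a^2 = \langle a\rangle(1-\langle a\rangle)/N}.  The
#' weak-noise small parameter is
#' \eqn{\epsilon = \sigma^2_{\rm eff}\tau_{\rm eff}/(\mu_{\rm eff}\theta)}
#' (for which the inverse-Gaussian limit has \eqn{CV^2 = 2\epsilon}), and the
#' time-scale separation is \eqn{\rho = \tau_{\rm eff}\, r^*}.  A warning is
#' emitted when \eqn{\epsilon \ge 1} (weak-noise expansion infeasible).
#'
#' @param config a [pif_config()] (its white-noise intensity is ignored by the
#'   reduction).
#' @return An object of class `eff_colored_params` with fields `alpha`,
#'   `mu_eff`, `sigma2_eff`, `tau_eff`, `epsilon`, `rho`, `threshold`,
#'   `mean_isi`.
#' @export
effective_colored_params <- function(config) {
  stopifnot(inherits(config, "pif_config"))
  k <- config$kinetics
  r <- stationary_rate_adapted(config)
  alpha <- adaptation_degree(config)
  cni <- channel_noise_intensity(k, r, config$adaptation_strength,
                                 config$threshold)
  mu_eff <- alpha * (config$base_drive -
                       config$adaptation_strength * k$subthreshold_activation)
  sigma2_eff <- alpha * config$adaptation_strength^2 * cni$noise_variance
  tau_eff <- alpha * k$tau_a
  eff_colored_params(mu_eff = mu_eff, sigma2_eff = sigma2_eff,
                     tau_eff = tau_eff, alpha = alpha,
                     threshold = config$threshold)
}

#' @rdname effective_colored_params
#' @param mu_eff,sigma2_eff,tau_eff,alpha,threshold direct construction of the
#'   reduced model's parameters (e.g. for scanning \eqn{(\epsilon,\rho)}
#'   directly).
#' @export
eff_colored_params <- function(mu_eff, sigma2_eff, tau_eff, alpha = 1,
                               threshold = 1) {
  check_scalar(mu_eff, "mu_eff", lower = .Machine$double.xmin)
  check_scalar(sigma2_eff, "sigma2_eff", lower = 0)
  check_scalar(tau_eff, "tau_eff", lower = .Machine$double.xmin)
  check_scalar(alpha, "alpha", lower = 1e-12, upper = 1)
  epsilon <- sigma2_eff * tau_eff / (mu_eff * threshold)
  rho <- tau_eff * mu_eff / threshold
  if (epsilon >= 1)
    warning("weak-noise small parameter epsilon = ", signif(epsilon, 3),
            " >= 1: the weak-noise expansion may be infeasible", call. = FALSE)
  structure(list(alpha = alpha, mu_eff = mu_eff, sigma2_eff = sigma2_eff,
                 tau_eff = tau_eff, epsilon = epsilon, rho = rho,
                 threshold = threshold, mean_isi = threshold / mu_eff),
            class = "eff_colored_params")
}

#' Construct reduced colored-noise parameters from (epsilon, rho)
#'
#' Convenience inverse of the \eqn{(\epsilon, \rho)} map at unit threshold and
#' a given mean ISI: \eqn{\mu_{\rm eff} = \theta/\langle I\rangle},
#' \eqn{\tau_{\rm eff} = \rho\langle I\rangle},
#' \eqn{\sigma^2_{\rm eff} = \epsilon\mu_{\rm eff}\theta/\tau_{\rm eff}}.
#'
#' @param epsilon weak-noise parameter (>= 0).
#' @param rho time-scale separation (> 0).
#' @param mean_isi mean interspike interval (default 10 ms).
#' @param threshold firing threshold (default 1).
#' @export
colored_params_from_shape <- function(epsilon, rho, mean_isi = 10,
                                      threshold = 1) {
  check_scalar(epsilon, "epsilon", lower = 0)
  check_scalar(rho, "rho", lower = .Machine$double.xmin)
  mu_eff <- threshold / mean_isi
  tau_eff <- rho * mean_isi
  eff_colored_params(mu_eff = mu_eff,
                     sigma2_eff = epsilon * mu_eff * threshold / tau_eff,
                     tau_eff = tau_eff, threshold = threshold)
}

#' @export
print.eff_colored_params <- function(x, ...) {
  cat("Colored-noise reduction of the adaptive PIF model\n")
  cat(sprintf("  alpha = %g, mu_eff = %g, sigma2_eff = %g, tau_eff = %g ms\n",
              x$alpha, x$mu_eff, x$sigma2_eff, x$tau_eff))
  cat(sprintf("  epsilon = %g, rho = %g, mean ISI = %g ms\n",
              x$epsilon, x$rho, x$mean_isi))
  invisible(x)
}
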