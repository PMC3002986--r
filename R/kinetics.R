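#' Two-state adaptation-channel kinetics
#'
#' Describes a population of `n_channels` independent ion channels that switch
#' between one closed and one open state.  A single channel opens with rate
#' \eqn{p_\infty/\tau_a} and closes with rate \eqn{(1-p_\infty)/\tau_a}, where
#' \eqn{p_\infty \in [0,1]} is the steady-state open probability set by the
#' membrane voltage.  In the integrate-and-fire setting \eqn{p_\infty} is
#' replaced by a function of time: 1 during a pulse of length `pulse_duration`
#' following each spike, and `subthreshold_activation` otherwise.
#'
#' @param n_channels number of channels (positive integer, or `Inf` for the
#'   deterministic limit of an infinite population).
#' @param tau_a adaptation time constant (ms); sets the channel kinetics
#'   time scale.
#' @param pulse_duration spike-pulse width \eqn{\delta} (ms) during which the
#'   activation is held at 1.
#' @param subthreshold_activation baseline steady-state activation
#'   \eqn{p_0 \in [0,1]} between spikes (default 0: purely spike-gated).
#' @return An object of class `channel_kinetics`.
#' @export
channel_kinetics <- function(n_channels, tau_a, pulse_duration,
                             subthreshold_activation = 0) {
  if (!(is.numeric(n_channels) && length(n_channels) == 1L &&
        !is.na(n_channels) && (is.infinite(n_channels) ||
                               (n_channels >= 1 && n_channels == round(n_channels)))))
    stop_param("`n_channels` must be a positive integer count or Inf")
  check_scalar(tau_a, "tau_a", lower = .Machine$double.xmin)
  check_scalar(pulse_duration, "pulse_duration", lower = 0)
  check_scalar(subthreshold_activation, "subthreshold_activation", 0, 1)
  structure(
    list(n_channels = n_channels, tau_a = tau_a,
         pulse_duration = pulse_duration,
         subthreshold_activation = subthreshold_activation),
    class = "channel_kinetics")
}

#' @export
print.channel_kinetics <- function(x, ...) {
  cat("Two-state adaptation channel population\n")
  cat(sprintf("  N = %s channels, tau_a = %g ms, pulse delta = %g ms, p0 = %g\n",
              format(x$n_channels), x$tau_a, x$pulse_duration,
              x$subthreshold_activation))
  invisible(x)
}

#' Per-channel opening and closing rates from the steady-state activation
#'
#' The first-order kinetics of a gating variable with steady state
#' \eqn{p_\infty} and time constant \eqn{\tau_a} correspond to an opening rate
#' \eqn{p_\infty/\tau_a} (per closed channel) and a closing rate
#' \eqn{(1-p_\infty)/\tau_a} (per open channel); the two always sum to
#' \eqn{1/\tau_a}.
#'
#' @param p_inf steady-state open probability in \[0, 1\].
#' @param tau_a kinetic time constant (> 0).
#' @return list with `opening_rate` and `closing_rate` (per ms, per channel).
#' @export
rates_from_activation <- function(p_inf, tau_a) {
  check_scalar(tau_a, "tau_a", lower = .Machine$double.xmin)
  check_scalar(p_inf, "p_inf", 0, 1)
  list(opening_rate = p_inf / tau_a, closing_rate = (1 - p_inf) / tau_a)
}

#' Stationary channel-noise variance, intensity and additive-noise validity
#'
#' For a neuron firing at rate `firing_rate` the time-averaged activation is
#' \eqn{\langle a\rangle = p_0 + r\delta(1-p_0)} and the stationary variance of
#' the open fraction is the binomial value
#' \eqn{\sigma_a^2 = \langle a\rangle(1-\langle a\rangle)/N}; it is inversely
#' proportional to the channel number.  The fluctuation enters the voltage
#' equation through the adaptation strength, giving the (non-dimensional)
#' channel-noise intensity
#' \eqn{\hat D_a = (\Delta\tau_a/\theta)^2 \sigma_a^2}
#' (one small term of relative size \eqn{\delta/\langle I\rangle} is neglected,
#' as in the diffusion reduction itself).
#'
#' The diffusion model treats the channel noise as additive.  This holds when
#' the relative fluctuation of the noise strength -- driven by the slow
#' fluctuations of the instantaneous firing rate -- is small; the returned
#' `additive_validity_ratio` estimates it as
#' \eqn{\sigma_x (1-2\langle a\rangle) / (2 r (1-\langle a\rangle))} with
#' \eqn{\sigma_x^2 = \alpha \Delta^2 \sigma_a^2/\theta^2} the variance of the
#' instantaneous rate.  A warning is emitted when the ratio exceeds 0.5
#' (additive-noise approximation clearly failing).
#'
#' @param kinetics a [channel_kinetics()] object.
#' @param firing_rate stationary firing rate (1/ms), > 0.
#' @param adaptation_strength maximal adaptation drive \eqn{\Delta}
#'   (threshold units per ms).
#' @param threshold firing threshold \eqn{\theta} (default 1).
#' @return list with `noise_variance` (\eqn{\sigma_a^2}), `noise_intensity`
#'   (non-dimensional \eqn{\hat D_a}), `additive_validity_ratio`, and
#'   `mean_activation`.
#' @export
channel_noise_intensity <- function(kinetics, firing_rate,
                                    adaptation_strength, threshold = 1) {
  stopifnot(inherits(kinetics, "channel_kinetics"))
  check_scalar(firing_rate, "firing_rate", lower = .Machine$double.xmin)
  check_scalar(adaptation_strength, "adaptation_strength", lower = 0)
  check_scalar(threshold, "threshold", lower = .Machine$double.xmin)
  p0 <- kinetics$subthreshold_activation
  a_mean <- p0 + firing_rate * kinetics$pulse_duration * (1 - p0)
  if (a_mean > 1) a_mean <- 1
  N <- kinetics$n_channels
  s2 <- if (is.infinite(N)) 0 else a_mean * (1 - a_mean) / N
  Delta_hat <- adaptation_strength * kinetics$tau_a / threshold
  intensity <- Delta_hat^2 * s2
  alpha <- threshold /
    (threshold + adaptation_strength * kinetics$pulse_duration * (1 - p0))
  sigma_x <- sqrt(alpha * adaptation_strength^2 * s2) / threshold
  ratio <- if (a_mean >= 1) Inf else
    sigma_x * abs(1 - 2 * a_mean) / (2 * firing_rate * (1 - a_mean))
  if (is.finite(ratio) && ratio > 0.5)
    warning("additive-noise approximation is unreliable here: relative ",
            "fluctuation of the channel-noise strength is ",
            signif(ratio, 3), " (should be << 1)", call. = FALSE)
  list(noise_variance = s2, noise_intensity = intensity,
       additive_validity_ratio = ratio, mean_activation = a_mean)
}
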