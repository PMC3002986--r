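# theory module: IG reference, colored-noise density, weak-noise shapes,
# serial-correlation formulas, limit cycle, step response

quad_moments <- function(f, upper, n = 20001) {
  s <- seq(1e-9, upper, length.out = n)
  h <- s[2] - s[1]
  w <- rep(c(2, 4), length.out = n); w[1] <- w[n] <- 1; w <- w * h / 3
  d <- f(s)
  Z <- sum(w * d)
  m1 <- sum(w * s * d) / Z
  list(norm = Z, mean = m1,
       m2 = sum(w * (s - m1)^2 * d) / Z,
       m3 = sum(w * (s - m1)^3 * d) / Z,
       m4 = sum(w * (s - m1)^4 * d) / Z)
}

test_that("IG density normalizes; quadrature moments match the closed forms", {
  p <- ig_params(10, 0.35)
  q <- quad_moments(function(t) ig_density(t, p), 200)
  expect_equal(q$norm, 1, tolerance = 1e-8)
  expect_equal(q$mean, 10, tolerance = 1e-6)
  expect_equal(sqrt(q$m2) / q$mean, 0.35, tolerance = 1e-6)
  expect_identical(ig_density(c(-1, 0), p), c(0, 0))
})

test_that("rescaled skewness and kurtosis of the IG density equal one (analytic)", {
  # computed from quadrature moments of ig_density, not from stored constants;
  # this is the calibration identity behind isi_shape()
  for (cv in c(0.1, 0.3, 0.6)) {
    p <- ig_params(5, cv)
    q <- quad_moments(function(t) ig_density(t, p), 5 * (1 + 40 * cv^2 + 10 * cv))
    cv_q <- sqrt(q$m2) / q$mean
    St <- (q$m3 / q$m2^1.5) / (3 * cv_q)
    Kt <- ((q$m4 - 3 * q$m2^2) / q$m2^2) / (15 * cv_q^2)
    expect_equal(St, 1, tolerance = 1e-5)
    expect_equal(Kt, 1, tolerance = 1e-4)
  }
})

test_that("colored-noise density: normalization, small-t limit, IG-heavy tail", {
  par <- colored_params_from_shape(epsilon = 0.1, rho = 5, mean_isi = 10)
  q <- quad_moments(function(t) colored_isi_density(t, par), 60, n = 40001)
  expect_equal(q$norm, 1, tolerance = 1e-6)
  expect_equal(q$mean, 10, tolerance = 1e-3)
  # for t << tau_eff the full expression reduces to the quasi-static form;
  # compare across the bulk (+- 2 sd) in a strongly slow-noise regime where
  # every interval satisfies t/tau_eff < 0.015
  slow <- colored_params_from_shape(epsilon = 0.1, rho = 100, mean_isi = 10)
  sdv <- 10 * sqrt(colored_isi_moments(slow)$cv^2)
  ts <- seq(10 - 2 * sdv, 10 + 2 * sdv, length.out = 21)
  full <- colored_isi_density(ts, slow, renormalize = FALSE)
  qs <- colored_isi_small_t(ts, slow)
  expect_true(all(abs(full / qs - 1) < 0.01))
  # heavier tail than the IG with matched mean and CV
  mom <- colored_isi_moments(par)
  igp <- ig_params(mom$mean, mom$cv)
  t_tail <- seq(2 * mom$mean, 3 * mom$mean, length.out = 9)
  expect_true(all(colored_isi_density(t_tail, par) >
                    ig_density(t_tail, igp)))
  # rescaled shape of the weak-noise density exceeds the IG reference
  expect_gt(mom$rescaled_skewness, 1)
  expect_gt(mom$rescaled_kurtosis, 1)
  expect_identical(colored_isi_density(c(-1, 0), par), c(0, 0))
})

test_that("epsilon -> 0 concentrates the density at the deterministic period", {
  par <- colored_params_from_shape(epsilon = 1e-5, rho = 3, mean_isi = 10)
  grid <- seq(9.9, 10.1, length.out = 2001)
  mass_in <- sum(colored_isi_density(grid, par)) * (grid[2] - grid[1])
  expect_gt(mass_in, 0.999)
})

test_that("weak-noise shape: IG limit, saturation, and simulation oracle", {
  # rho -> 0: both rescaled measures -> 1 (inverse-Gaussian regime)
  w_small <- weak_noise_shape(0.01, 0.02)
  expect_equal(w_small$rescaled_skewness, 1, tolerance = 0.03)
  expect_equal(w_small$rescaled_kurtosis, 1, tolerance = 0.06)
  expect_equal(w_small$cv2, 2 * 0.01, tolerance = 0.02)
  # large rho: leading orders approach the saturation constants 2 and 24/5
  w_big <- weak_noise_shape(0.05, 500)
  expect_equal(unname(w_big$leading_order[1]), 2, tolerance = 0.01)
  expect_equal(unname(w_big$leading_order[2]), 4.8, tolerance = 0.02)
  # internal consistency: cv2 identical to kappa2/kappa1^2
  w <- weak_noise_shape(0.08, 4)
  expect_equal(w$cv2, w$kappa[["kappa2"]] / w$kappa[["kappa1"]]^2,
               tolerance = 1e-12)
  # simulation oracle at epsilon = 0.05, rho = 5
  par <- colored_params_from_shape(0.05, 5, mean_isi = 10)
  st <- isi_stats(as_isi_sample(simulate_pif_colored(par, 6e5, seed = 91)),
                  n_boot = 100)
  th <- weak_noise_shape(0.05, 5)
  expect_within_se(st$rescaled_skewness, th$rescaled_skewness,
                   st$se$rescaled_skewness)
  expect_within_se(st$rescaled_kurtosis, th$rescaled_kurtosis,
                   st$se$rescaled_kurtosis)
  expect_within_se(st$cv^2, th$cv2, 2 * st$cv * st$se$cv)
})

test_that("colored-noise SCC: positive, geometric, correct limits, sim oracle", {
  par <- colored_params_from_shape(0.05, 5, mean_isi = 10)
  sc <- scc_colored(1:10, par)
  expect_true(all(sc > 0))
  ratios <- sc[-1] / sc[-10]
  expect_equal(ratios, rep(exp(-1 / 5), 9), tolerance = 1e-10)
  # white-noise limit: coefficients vanish ~ rho/2 as rho -> 0
  tiny <- vapply(c(0.1, 0.01, 0.001), function(r)
    scc_colored(1, colored_params_from_shape(0.05, r)), 0)
  expect_true(all(diff(tiny) < 0))
  expect_lt(tiny[3], 1e-3)
  expect_error(scc_colored(0, par), "lag")
  st <- serial_correlation(
    as_isi_sample(simulate_pif_colored(par, 4e5, seed = 92)), 3)
  for (k in 1:3)
    expect_within_se(st$scc[k], sc[k], st$se[k], label = sprintf("lag %d", k))
})

test_that("limit cycle solves its defining conditions; SCC signs and oracle", {
  cfg <- pif_config_standard(N = Inf, D = 0, tau_a = 10)
  lc <- limit_cycle(cfg)
  # threshold condition: mu T - x0 tau (1 - beta) = theta
  expect_equal(cfg$base_drive * lc$period -
                 lc$x0 * lc$tau_a * (1 - lc$beta), cfg$threshold,
               tolerance = 1e-12)
  # periodicity condition: x0 (1 - beta) = jump
  expect_equal(lc$x0 * (1 - lc$beta), lc$jump, tolerance = 1e-12)
  expect_equal(lc$period, 1 / stationary_rate_adapted(cfg), tolerance = 1e-12)
  # no adaptation: T* = theta/mu, x0 = 0, SCC identically zero
  cfg0 <- pif_config(0.1, 0, channel_kinetics(Inf, 100, 1),
                     white_noise_intensity = 1e-4)
  expect_equal(limit_cycle(cfg0)$x0, 0)
  expect_identical(scc_deterministic(1:5, cfg0), rep(0, 5))
  # odd lags negative over a (Delta, rho) grid
  for (tau in c(2, 10, 50, 200)) for (Dl in c(0.2, 0.8, 2)) {
    cfgg <- pif_config_standard(N = Inf, tau_a = tau, adaptation_strength = Dl,
                                base_drive = 0.1 * (1 + Dl))
    expect_true(all(scc_deterministic(c(1, 3, 5), cfgg) < 0),
                label = sprintf("tau=%g Delta=%g", tau, Dl))
  }
  # matches the small-D white-noise simulation at rho = 1
  st <- serial_correlation(
    as_isi_sample(simulate_pif_white(pif_config_standard(N = Inf, D = 2e-4,
                                                         tau_a = 10),
                                     4e5, seed = 93)), 2)
  th <- scc_deterministic(1:2, cfg)
  for (k in 1:2)
    expect_within_se(st$scc[k], th[k], st$se[k], label = sprintf("lag %d", k))
})

test_that("deterministic SCC does not depend on the noise intensity", {
  cfg_lo <- pif_config_standard(N = Inf, D = 1e-4, tau_a = 10)
  cfg_hi <- pif_config_standard(N = Inf, D = 8e-4, tau_a = 10)
  expect_identical(scc_deterministic(1:3, cfg_lo),
                   scc_deterministic(1:3, cfg_hi))
  s_lo <- serial_correlation(
    as_isi_sample(simulate_pif_white(cfg_lo, 2e5, seed = 94)), 1)
  s_hi <- serial_correlation(
    as_isi_sample(simulate_pif_white(cfg_hi, 2e5, seed = 95)), 1)
  expect_within_se(s_lo$scc[1], s_hi$scc[1],
                   sqrt(s_lo$se[1]^2 + s_hi$se[1]^2))
})

test_that("step-response theory is consistent and matches the PSTH", {
  cfg <- pif_config_standard(N = 300)
  step <- c(250, 0.05)
  # t -> infinity: adapted rate of the post-step configuration
  cfg_post <- pif_config_standard(N = 300, base_drive = 0.18 + 0.05)
  expect_equal(rate_step_response(1e6, cfg, step),
               stationary_rate_adapted(cfg_post), tolerance = 1e-10)
  # degree of adaptation from the theoretical curve equals alpha
  r0 <- rate_step_response(0, cfg, step)
  r_on <- rate_step_response(step[1] + 1e-9, cfg, step)
  r_inf <- rate_step_response(1e6, cfg, step)
  expect_equal((r_inf - r0) / (r_on - r0), adaptation_degree(cfg),
               tolerance = 1e-9)
  # pointwise agreement with the trial-averaged simulation within 3-4 SE
  sr <- simulate_step_response(cfg, step, n_trials = 250, seed = 96)
  th <- rate_step_response(sr$psth$t, cfg, step)
  z <- abs(sr$psth$rate - th) / pmax(sr$psth$se, 1e-6)
  expect_lt(stats::quantile(z, 0.99), 4)
})
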