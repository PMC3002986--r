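# channel_population module: kinetics, exact Gillespie, OU fluctuations,
# channel-noise intensity

test_that("rates_from_activation reproduces the first-order kinetics", {
  r <- rates_from_activation(1, 100)
  expect_equal(r$opening_rate, 0.01)
  expect_equal(r$closing_rate, 0)
  r <- rates_from_activation(0, 100)
  expect_equal(r$opening_rate, 0)
  expect_equal(r$closing_rate, 0.01)
  for (tau in c(3, 50, 400)) {
    r <- rates_from_activation(0.5, tau)
    expect_equal(r$opening_rate, r$closing_rate)
    expect_equal(r$opening_rate + r$closing_rate, 1 / tau)
  }
  expect_error(rates_from_activation(0.5, -1), "tau_a")
  expect_error(rates_from_activation(1.2, 10), "p_inf")
})

test_that("Gillespie stationary law matches the binomial oracle", {
  kin <- channel_kinetics(1000, tau_a = 10, pulse_duration = 1)
  sched <- data.frame(t_start = 0, p_inf = 0.5)
  traj <- simulate_two_state_gillespie(kin, sched, n_open_init = 500,
                                       t_end = 20000, seed = 42)
  # conservation is structural: counts stay in [0, N]
  expect_true(all(traj$n_open >= 0 & traj$n_open <= 1000))
  # time-averaged open fraction ~ p = 0.5 within 3 SE; the count decorrelates
  # over tau_a, so the effective sample size is ~ t_end / (2 tau_a)
  frac <- channel_mean_fraction(traj)
  se <- sqrt(0.5 * 0.5 / 1000) * sqrt(2 * 10 / 20000)
  expect_within_se(frac, 0.5, se)
  # empirical variance of the count near the binomial value N p (1-p) = 250
  tt <- c(traj$times, traj$window[2])
  w <- diff(tt)
  vbar <- sum((traj$n_open - 1000 * frac)^2 * w) / sum(w)
  expect_gt(vbar, 250 * 0.85)
  expect_lt(vbar, 250 * 1.15)
})

test_that("all-closed population with p_inf = 0 stays identically zero", {
  kin <- channel_kinetics(50, 10, 1)
  traj <- simulate_two_state_gillespie(kin, data.frame(t_start = 0, p_inf = 0),
                                       0, 100, seed = 1)
  expect_identical(length(traj$times), 1L)
  expect_identical(traj$n_open, 0L)
})

test_that("single-channel waiting time to first opening is exponential(tau_a)", {
  kin <- channel_kinetics(1, tau_a = 7, pulse_duration = 1)
  sched <- data.frame(t_start = 0, p_inf = 1)
  n_rep <- 4000
  waits <- vapply(seq_len(n_rep), function(i) {
    tr <- simulate_two_state_gillespie(kin, sched, 0, t_end = 200, seed = 100 + i)
    tr$times[2]
  }, 0)
  expect_within_se(mean(waits), 7, 7 / sqrt(n_rep))
})

test_that("empirical occupancy matches the master-equation oracle (N <= 5)", {
  skip_if_not_installed("Matrix")
  N <- 4
  tau <- 5
  sched <- data.frame(t_start = c(0, 6), p_inf = c(0.8, 0.2))
  t_probe <- 10
  n_rep <- 3000
  kin <- channel_kinetics(N, tau, 1)
  counts <- integer(N + 1)
  for (i in seq_len(n_rep)) {
    tr <- simulate_two_state_gillespie(kin, sched, 0, t_probe, seed = 5000 + i)
    n_at <- channel_count_at(tr, t_probe - 1e-9)
    counts[n_at + 1] <- counts[n_at + 1] + 1L
  }
  p_th <- master_equation_occupancy(N, tau, sched, 0, t_probe)
  for (n in 0:N) {
    se <- sqrt(p_th[n + 1] * (1 - p_th[n + 1]) / n_rep)
    expect_within_se(counts[n + 1] / n_rep, p_th[n + 1], pmax(se, 1e-4),
                     label = sprintf("P(n=%d)", n))
  }
})

test_that("Gillespie open-fraction increments over long windows are Gaussian", {
  kin <- channel_kinetics(1000, tau_a = 10, pulse_duration = 1)
  traj <- simulate_two_state_gillespie(kin,
                                       data.frame(t_start = 0, p_inf = 0.5),
                                       500, t_end = 5000, seed = 9)
  grid <- seq(0, 5000, by = 5)  # window >> mean event spacing (~0.01 ms)
  counts <- channel_count_at(traj, grid)
  inc <- diff(counts) / 1000
  expect_gt(stats::shapiro.test(inc)$p.value, 0.01)
})

test_that("unsorted schedules and bad initial counts are rejected", {
  kin <- channel_kinetics(10, 10, 1)
  expect_error(simulate_two_state_gillespie(
    kin, data.frame(t_start = c(0, 5, 3), p_inf = c(0, 1, 0)), 0, 10, 1),
    "increasing")
  expect_error(simulate_two_state_gillespie(
    kin, data.frame(t_start = 0, p_inf = 0.5), 11, 10, 1), "n_open_init")
})

test_that("OU fluctuation has exact stationary moments and autocorrelation", {
  tau <- 10
  s2 <- 0.25
  p <- simulate_ou_fluctuation(s2, tau, dt = 0.5, t_end = 60000, seed = 3)
  n <- length(p$values)
  n_eff <- n * 0.5 / (2 * tau)
  expect_within_se(mean(p$values), 0, sqrt(s2 / n_eff))
  expect_within_se(stats::var(p$values), s2, s2 * sqrt(2 / n_eff))
  lag <- round(tau / 0.5)
  ac <- mean(p$values[seq_len(n - lag)] * p$values[(lag + 1):n])
  expect_within_se(ac, s2 * exp(-1), s2 * sqrt(2 / n_eff))
  # zero-variance path is identically zero
  p0 <- simulate_ou_fluctuation(0, tau, 0.5, 100, seed = 4)
  expect_true(all(p0$values == 0))
  expect_error(simulate_ou_fluctuation(1, tau, dt = -0.1, 100, 1), "dt")
  expect_error(simulate_ou_fluctuation(1, tau, dt = 2, 100, 1), "tau_a / 10")
})

test_that("channel noise variance is inversely proportional to N", {
  kin1 <- channel_kinetics(500, 100, 1)
  kin2 <- channel_kinetics(1000, 100, 1)
  c1 <- channel_noise_intensity(kin1, 0.1, adaptation_strength = 0.8)
  c2 <- channel_noise_intensity(kin2, 0.1, adaptation_strength = 0.8)
  expect_equal(c1$noise_variance / c2$noise_variance, 2, tolerance = 1e-12)
  kin_inf <- channel_kinetics(Inf, 100, 1)
  ci <- channel_noise_intensity(kin_inf, 0.1, adaptation_strength = 0.8)
  expect_identical(ci$noise_variance, 0)
  expect_identical(ci$noise_intensity, 0)
})

test_that("additive-noise validity holds at the standard parameter set", {
  # reconstructed additive-noise condition: relative fluctuation of the noise
  # strength << 1 at the reference configuration (N = 1000)
  cfg <- pif_config_standard()
  cni <- channel_noise_intensity(cfg$kinetics, stationary_rate_adapted(cfg),
                                 cfg$adaptation_strength, cfg$threshold)
  expect_lt(cni$additive_validity_ratio, 0.1)
  # and it degrades as 1/sqrt(N)
  cfg2 <- pif_config_standard(N = 10)
  cni2 <- channel_noise_intensity(cfg2$kinetics, stationary_rate_adapted(cfg2),
                                  cfg2$adaptation_strength, cfg2$threshold)
  expect_equal(cni2$additive_validity_ratio / cni$additive_validity_ratio,
               sqrt(100), tolerance = 1e-8)
})
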