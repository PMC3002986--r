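# adaptive_pif module: nondimensionalization, effective parameters, simulator
# variants, step response

test_that("nondimensionalization round-trips and is scale invariant", {
  cfg <- pif_config_standard(N = 400, D = 5e-4)
  nd <- nondimensionalize(cfg)
  expect_identical(nd$threshold_ref, 1)
  expect_identical(nd$reset_ref, 0)
  back <- dimensionalize(nd, threshold = cfg$threshold,
                         tau_a = cfg$kinetics$tau_a)
  expect_equal(back$base_drive, cfg$base_drive, tolerance = 1e-12)
  expect_equal(back$adaptation_strength, cfg$adaptation_strength,
               tolerance = 1e-12)
  expect_equal(back$white_noise_intensity, cfg$white_noise_intensity,
               tolerance = 1e-12)
  expect_equal(back$kinetics$pulse_duration, cfg$kinetics$pulse_duration,
               tolerance = 1e-12)
  # scaling mu, Delta down and tau_a up by a common factor leaves the
  # nondimensional parameters (except the pulse ratio, fixed here too) intact
  k <- 2.5
  cfg2 <- pif_config(cfg$base_drive / k, cfg$adaptation_strength / k,
                     channel_kinetics(400, cfg$kinetics$tau_a * k,
                                      cfg$kinetics$pulse_duration * k),
                     white_noise_intensity = cfg$white_noise_intensity / k)
  nd2 <- nondimensionalize(cfg2)
  for (f in c("mu_hat", "delta_drive_hat", "pulse_hat", "d_white_hat",
              "d_channel_hat"))
    expect_equal(nd2[[f]], nd[[f]], tolerance = 1e-10, label = f)
})

test_that("stationary rate theory: zero adaptation, monotonicity, guards", {
  kin <- channel_kinetics(100, 100, 1)
  cfg0 <- pif_config(0.2, 0, kin)
  expect_equal(stationary_rate_adapted(cfg0), 0.2)
  rates <- vapply(seq(0, 3, by = 0.3), function(D_adapt) {
    stationary_rate_adapted(pif_config(0.2, D_adapt, kin))
  }, 0)
  expect_true(all(diff(rates) < 0))
  expect_error(pif_config(0.05, 1, channel_kinetics(100, 100, 1, 0.2)),
               "non-firing")
})

test_that("effective colored parameters: alpha limits and epsilon monotone in N", {
  cfg0 <- pif_config(0.2, 0, channel_kinetics(100, 100, 1))
  e0 <- effective_colored_params(cfg0)
  expect_identical(e0$alpha, 1)
  expect_equal(e0$mu_eff, 0.2)
  eps <- vapply(c(25, 50, 100, 400, 1600), function(N)
    effective_colored_params(pif_config_standard(N = N))$epsilon, 0)
  expect_true(all(diff(eps) < 0))
  # rho is tau_eff times the stationary rate
  ec <- effective_colored_params(pif_config_standard())
  expect_equal(ec$rho, ec$tau_eff * 0.1, tolerance = 1e-12)
  expect_warning(eff_colored_params(0.1, 0.05, 30), "epsilon")
})

test_that("deterministic limit is exactly periodic at the theoretical rate", {
  cfg <- pif_config_standard(N = Inf, D = 0)
  tr <- simulate_pif_white(cfg, 4000, seed = 1)
  isi <- diff(tr$times[tr$times > 1500])
  expect_lt(stats::sd(isi) / mean(isi), 1e-8)
  expect_equal(mean(isi), 1 / stationary_rate_adapted(cfg), tolerance = 1e-8)
})

test_that("long-run rate equals the mean-adaptation theory for every variant", {
  r_th <- stationary_rate_adapted(pif_config_standard())
  rate_of <- function(train) {
    isi <- as_isi_sample(train)
    c(1 / mean(isi), stats::sd(isi) / mean(isi) / sqrt(length(isi)))
  }
  runs <- list(
    channel = rate_of(simulate_pif_channel(pif_config_standard(N = 200),
                                           6e4, seed = 11)),
    diffusion = rate_of(simulate_pif_diffusion(pif_config_standard(N = 200),
                                               6e4, seed = 12)),
    white = rate_of(simulate_pif_white(pif_config_standard(N = Inf, D = 1e-3),
                                       6e4, seed = 13)),
    mixed = rate_of(simulate_pif_channel(pif_config_standard(N = 200, D = 1e-3),
                                         6e4, seed = 14)))
  for (nm in names(runs)) {
    r <- runs[[nm]]
    se_rate <- r[1]^2 * r[2] * 10  # delta method on mean ISI
    expect_within_se(r[1], r_th, pmax(3e-4, se_rate), n_se = 3, label = nm)
  }
  # colored reduction fires at the same rate (mean ISI invariance)
  ec <- effective_colored_params(pif_config_standard(N = 200))
  rc <- rate_of(simulate_pif_colored(ec, 6e4, seed = 15))
  expect_within_se(rc[1], r_th, 3e-4, label = "colored")
})

test_that("small channel numbers produce discrete multimodal ISI histograms", {
  cfg <- pif_config_standard(N = 10)
  tr <- simulate_pif_channel(cfg, 1.2e5, seed = 21)
  isi <- as.numeric(as_isi_sample(tr))
  # fine equal-width bins resolve the discrete atoms of the ISI density
  isi <- isi[isi <= stats::quantile(isi, 0.995)]
  edges <- seq(0, max(isi) + 1, length.out = 300)
  hist <- isi_histogram(isi_sample(isi), binning = edges)
  expect_gte(count_isih_modes(hist), 3)
})

test_that("noiseless colored model is exactly periodic", {
  p <- eff_colored_params(mu_eff = 0.1, sigma2_eff = 0, tau_eff = 50)
  tr <- simulate_pif_colored(p, 500, seed = 1)
  expect_equal(diff(tr$times), rep(10, length(tr$times) - 1),
               tolerance = 1e-12)
})

test_that("halving dt leaves CV and lag-1 SCC within MC error", {
  cfg1 <- pif_config_standard(N = Inf, D = 1e-3, tau_a = 10)
  cfg2 <- pif_config_standard(N = Inf, D = 1e-3, tau_a = 10, dt = cfg1$dt / 2)
  st1 <- isi_stats(as_isi_sample(simulate_pif_white(cfg1, 1.2e5, seed = 31)),
                   n_boot = 60)
  st2 <- isi_stats(as_isi_sample(simulate_pif_white(cfg2, 1.2e5, seed = 32)),
                   n_boot = 60)
  expect_within_se(st1$cv, st2$cv, sqrt(st1$se$cv^2 + st2$se$cv^2))
  expect_within_se(st1$scc[1], st2$scc[1],
                   sqrt(st1$se$scc[1]^2 + st2$se$scc[1]^2))
})

test_that("variant convergence: channel -> diffusion as N grows", {
  gap <- vapply(c(20, 1000), function(N) {
    cfg <- pif_config_standard(N = N)
    c1 <- isi_shape(as_isi_sample(simulate_pif_channel(cfg, 4e4, seed = 41)))
    c2 <- isi_shape(as_isi_sample(simulate_pif_diffusion(cfg, 4e4, seed = 42)))
    abs(c1$cv - c2$cv) / c2$cv
  }, 0)
  expect_lt(gap[2], 0.06)
})

test_that("step response: flat without a step; measured alpha matches theory", {
  cfg <- pif_config_standard(N = 300)
  sr0 <- simulate_step_response(cfg, step = c(200, 0), n_trials = 120,
                                seed = 51, t_end = 500)
  r_th <- stationary_rate_adapted(cfg)
  expect_true(all(abs(sr0$psth$rate - r_th) <
                    pmax(4 * sr0$psth$se, 0.25 * r_th)))
  sr <- simulate_step_response(cfg, step = c(250, 0.05), n_trials = 250,
                               seed = 52)
  alpha <- adaptation_degree(cfg)
  expect_lt(abs(sr$decay_constant - alpha * 100) / (alpha * 100), 0.15)
  expect_lt(abs(sr$adaptation_degree - alpha), 0.1)
  expect_error(simulate_step_response(cfg, step = c(-5, 0.1), 120, 1),
               "window")
  expect_error(simulate_step_response(cfg, step = c(10, 0.1), 10, 1),
               "n_trials")
})

test_that("overlapping spike pulses trigger the restart-rule warning", {
  # drive so strong that ISIs fall below the pulse duration
  cfg <- pif_config(3, 0.1, channel_kinetics(50, 100, 1))
  expect_warning(simulate_pif_channel(cfg, 200, seed = 61), "overlap")
})
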