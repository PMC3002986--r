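# Independent oracles used across the suite.  These are deliberately written
# without touching the package's own code paths wherever the test compares
# implementation against oracle.

# inverse-Gaussian sampler (Michael-Schucany-Haas transformation)
r_invgauss <- function(n, mean, shape) {
  nu <- stats::rnorm(n)^2
  x <- mean + mean^2 * nu / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * nu + mean^2 * nu^2)
  u <- stats::runif(n)
  ifelse(u < mean / (mean + x), x, mean^2 / x)
}

# stationary AR(1) surrogate with marginal mean/sd and coefficient a
r_ar1 <- function(n, a, mean = 1, sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  x0 <- stats::rnorm(1, sd = sd)
  mean + as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
}

# occupancy distribution of the two-state master equation at a probe time,
# via the matrix exponential of the tridiagonal generator (Matrix::expm)
master_equation_occupancy <- function(N, tau_a, schedule, n0, t_probe) {
  p_of <- function(t) schedule$p_inf[findInterval(t, schedule$t_start)]
  gen <- function(p) {
    Q <- matrix(0, N + 1, N + 1)
    for (n in 0:N) {
      up <- (N - n) * p / tau_a
      dn <- n * (1 - p) / tau_a
      if (n < N) Q[n + 1, n + 2] <- up
      if (n > 0) Q[n + 1, n + 1 - 1] <- dn
      Q[n + 1, n + 1] <- -(up + dn)
    }
    Q
  }
  probs <- rep(0, N + 1)
  probs[n0 + 1] <- 1
  brk <- sort(unique(c(schedule$t_start[schedule$t_start > 0], t_probe)))
  brk <- brk[brk <= t_probe]
  t_cur <- 0
  for (tb in brk) {
    p <- p_of(t_cur + 1e-12)
    probs <- as.numeric(probs %*% as.matrix(Matrix::expm(gen(p) * (tb - t_cur))))
    t_cur <- tb
  }
  probs
}

# plain (biased, plug-in) sample statistics used as cross-checks
plugin_skewness <- function(x) {
  d <- x - mean(x)
  mean(d^3) / mean(d^2)^1.5
}

# simple Poisson spike-train surrogate on a window
r_poisson_train <- function(rate, window, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate * diff(window))
  adaptisi::spike_train(sort(stats::runif(n, window[1], window[2])),
                        window = window)
}

expect_within_se <- function(value, target, se, n_se = 3,
                             label = deparse(substitute(value))) {
  expect_lt(abs(value - target), n_se * se,
            label = sprintf("%s = %g vs target %g (%g SE = %g)",
                            label, value, target, n_se, n_se * se))
}
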