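#' Interspike-interval sample
#'
#' @param intervals positive interval durations, in observed order.
#' @return object of class `isi_sample` (numeric vector).
#' @export
isi_sample <- function(intervals) {
  intervals <- as.numeric(intervals)
  if (length(intervals) && any(!is.finite(intervals) | intervals <= 0))
    stop_param("all interspike intervals must be positive and finite")
  structure(intervals, class = "isi_sample")
}

as_intervals <- function(sample) {
  if (inherits(sample, "spike_train")) sample <- as_isi_sample(sample)
  if (inherits(sample, "isi_sample")) return(as.numeric(sample))
  as.numeric(isi_sample(sample))
}

#' Unbiased cumulant estimators (k-statistics) of an ISI sample
#'
#' Returns the first four cumulants: mean, variance, third cumulant (sets the
#' skewness) and fourth cumulant (sets the excess kurtosis), using the
#' unbiased k-statistics rather than plug-in moments (whose bias in
#' \eqn{\kappa_3,\kappa_4} is substantial at a few thousand intervals).
#'
#' @param sample an [isi_sample()], [spike_train()] or numeric vector.
#' @return named numeric vector `c(kappa1, kappa2, kappa3, kappa4)`.
#' @export
isi_cumulants <- function(sample) {
  x <- as_intervals(sample)
  n <- length(x)
  if (n < 8)
    stop_param("at least 8 intervals are required for the fourth cumulant ",
               "(got ", n, ")")
  xb <- mean(x)
  d <- x - xb
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  k2 <- n * m2 / (n - 1)
  k3 <- n^2 * m3 / ((n - 1) * (n - 2))
  k4 <- n^2 * ((n + 1) * m4 - 3 * (n - 1) * m2^2) /
    ((n - 1) * (n - 2) * (n - 3))
  c(kappa1 = xb, kappa2 = k2, kappa3 = k3, kappa4 = k4)
}

#' Coefficient of variation and rescaled shape measures of an ISI sample
#'
#' The rescaled skewness and rescaled kurtosis normalize the ordinary skewness
#' \eqn{\gamma_1 = \kappa_3/\kappa_2^{3/2}} and excess kurtosis
#' \eqn{\gamma_2 = \kappa_4/\kappa_2^2} by their inverse-Gaussian values at the
#' same CV (\eqn{\gamma_1^{IG} = 3\,CV}, \eqn{\gamma_2^{IG} = 15\,CV^2}):
#' \deqn{\tilde S = \frac{\gamma_1}{3\,CV}, \qquad
#'       \tilde K = \frac{\gamma_2}{15\,CV^2},}
#' so both equal 1 for inverse-Gaussian data.  Values above 1 indicate an ISI
#' density that is more skewed / more peaked with a heavier tail than the IG.
#'
#' @inheritParams isi_cumulants
#' @return list with `cv`, `rescaled_skewness`, `rescaled_kurtosis` (plus the
#'   plain `skewness` and `kurtosis_excess`).
#' @export
isi_shape <- function(sample) {
  k <- isi_cumulants(sample)
  if (k[["kappa2"]] <= 0)
    stop_param("degenerate sample: zero interval variance, ",
               "shape measures are undefined")
  cv <- sqrt(k[["kappa2"]]) / k[["kappa1"]]
  g1 <- k[["kappa3"]] / k[["kappa2"]]^1.5
  g2 <- k[["kappa4"]] / k[["kappa2"]]^2
  list(cv = cv, skewness = g1, kurtosis_excess = g2,
       rescaled_skewness = g1 / (3 * cv),
       rescaled_kurtosis = g2 / (15 * cv^2))
}

#' Serial correlation coefficients of the ISI sequence
#'
#' Stationary-sequence estimator: a single pooled mean and variance over the
#' sequence,
#' \eqn{\rho_k = \sum_i (I_i - \bar I)(I_{i+k} - \bar I) / \sum_i (I_i-\bar I)^2}.
#' Standard errors come from a circular block bootstrap with block length
#' `max(10, 2 x decorrelation lag)` (decorrelation lag: first lag at which
#' \eqn{|\rho_k|} drops below 1/e).
#'
#' @inheritParams isi_cumulants
#' @param k_max maximum lag; must satisfy `k_max < n / 10`.
#' @param n_boot bootstrap replicates (default 200; 0 skips the bootstrap).
#' @param block_len bootstrap block length override.
#' @return list with `lag`, `scc`, `se`, `block_len`.
#' @export
serial_correlation <- function(sample, k_max, n_boot = 200, block_len = NULL) {
  x <- as_intervals(sample)
  n <- length(x)
  if (k_max < 1) stop_param("`k_max` must be >= 1")
  if (n < 10 * k_max)
    stop_param("need at least 10 * k_max = ", 10 * k_max,
               " intervals for lags up to ", k_max, " (got ", n, ")")
  scc <- scc_estimate(x, k_max)
  se <- rep(NA_real_, k_max)
  bl <- NULL
  if (n_boot > 0) {
    bl <- block_len %||% max(10, 2 * decorrelation_lag(x))
    reps <- matrix(0, n_boot, k_max)
    for (b in seq_len(n_boot))
      reps[b, ] <- scc_estimate(circular_block_resample(x, bl), k_max)
    se <- apply(reps, 2, stats::sd)
  }
  list(lag = seq_len(k_max), scc = scc, se = se, block_len = bl)
}

scc_estimate <- function(x, k_max) {
  n <- length(x)
  d <- x - mean(x)
  v <- sum(d * d)
  if (v <= 0) return(rep(NA_real_, k_max))
  vapply(seq_len(k_max), function(k)
    sum(d[seq_len(n - k)] * d[(k + 1):n]) / v, 0)
}

decorrelation_lag <- function(x, max_lag = 100L) {
  km <- min(max_lag, floor(length(x) / 10) - 1L)
  if (km < 1L) return(1L)
  r <- scc_estimate(x, km)
  below <- which(abs(r) < exp(-1))
  if (length(below)) below[1] else km
}

circular_block_resample <- function(x, block_len) {
  n <- length(x)
  nb <- ceiling(n / block_len)
  starts <- sample.int(n, nb, replace = TRUE)
  idx <- (rep(starts, each = block_len) +
            rep(seq_len(block_len) - 1L, times = nb) - 1L) %% n + 1L
  x[idx[seq_len(n)]]
}

#' Full ISI summary statistics with bootstrap standard errors
#'
#' Mean, CV, rescaled skewness/kurtosis and the serial correlation
#' coefficients up to `k_max`, each with a circular-block-bootstrap standard
#' error (blocks preserve the serial dependence that an ordinary bootstrap
#' would destroy).
#'
#' @inheritParams serial_correlation
#' @return object of class `isi_stats`.
#' @export
isi_stats <- function(sample, k_max = 10, n_boot = 200, block_len = NULL) {
  x <- as_intervals(sample)
  n <- length(x)
  sh <- isi_shape(x)
  point <- c(mean = mean(x), cv = sh$cv,
             rescaled_skewness = sh$rescaled_skewness,
             rescaled_kurtosis = sh$rescaled_kurtosis)
  km <- min(k_max, max(1L, floor(n / 10) - 1L))
  sc <- serial_correlation(x, km, n_boot = 0)
  bl <- block_len %||% max(10, 2 * decorrelation_lag(x))
  se <- rep(NA_real_, 4L); scc_se <- rep(NA_real_, km)
  if (n_boot > 0) {
    reps <- matrix(0, n_boot, 4L + km)
    for (b in seq_len(n_boot)) {
      xb <- circular_block_resample(x, bl)
      shb <- isi_shape(xb)
      reps[b, ] <- c(mean(xb), shb$cv, shb$rescaled_skewness,
                     shb$rescaled_kurtosis, scc_estimate(xb, km))
    }
    sds <- apply(reps, 2, stats::sd)
    se <- sds[1:4]
    scc_se <- sds[-(1:4)]
  }
  structure(list(n = n, mean = point[["mean"]], cv = point[["cv"]],
                 skewness = sh$skewness, kurtosis_excess = sh$kurtosis_excess,
                 rescaled_skewness = point[["rescaled_skewness"]],
                 rescaled_kurtosis = point[["rescaled_kurtosis"]],
                 se = list(mean = se[1], cv = se[2], rescaled_skewness = se[3],
                           rescaled_kurtosis = se[4], scc = scc_se),
                 scc = sc$scc, scc_lag = sc$lag, block_len = bl),
            class = "isi_stats")
}

#' @export
print.isi_stats <- function(x, ...) {
  cat(sprintf("ISI statistics (n = %d)\n", x$n))
  cat(sprintf("  mean %.5g +- %.2g   CV %.4g +- %.2g\n",
              x$mean, x$se$mean, x$cv, x$se$cv))
  cat(sprintf("  rescaled skewness %.4g +- %.2g   rescaled kurtosis %.4g +- %.2g\n",
              x$rescaled_skewness, x$se$rescaled_skewness,
              x$rescaled_kurtosis, x$se$rescaled_kurtosis))
  k <- min(5L, length(x$scc))
  cat("  SCC lags 1..", k, ": ",
      paste(sprintf("%.3f", x$scc[seq_len(k)]), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Normalized ISI histogram (density estimate)
#'
#' @inheritParams isi_cumulants
#' @param binning `"fd"` (Freedman-Diaconis, default) or a numeric vector of
#'   explicit bin edges.
#' @return list with `breaks`, `mids`, `density`, `counts`; the density
#'   integrates to 1 over the bins.
#' @export
isi_histogram <- function(sample, binning = "fd") {
  x <- as_intervals(sample)
  if (length(x) < 100)
    stop_param("at least 100 intervals are required for a histogram (got ",
               length(x), ")")
  h <- if (is.numeric(binning))
    graphics::hist(x, breaks = binning, plot = FALSE)
  else graphics::hist(x, breaks = "FD", plot = FALSE)
  list(breaks = h$breaks, mids = h$mids, density = h$density,
       counts = h$counts)
}

#' L1 distance between an ISI histogram and a theoretical density
#'
#' Integrates `|hist density - density_fn|` over the histogram support plus the
#' theoretical mass outside it, i.e. the total-variation-style L1 distance.
#'
#' @param hist output of [isi_histogram()].
#' @param density_fn vectorized density function of the interval.
#' @export
isih_l1 <- function(hist, density_fn) {
  w <- diff(hist$breaks)
  ## average the theoretical density over each bin (5-point rule)
  th <- vapply(seq_along(w), function(i) {
    s <- seq(hist$breaks[i], hist$breaks[i + 1], length.out = 5)
    mean(density_fn(s))
  }, 0)
  inside <- sum(abs(hist$density - th) * w)
  total_th <- sum(th * w)
  inside + max(0, 1 - total_th)
}

#' Count significant local maxima of an ISI histogram
#'
#' A bin is a mode when it exceeds both neighbours and is above
#' `floor_frac` of the global maximum (noise floor).  Used to detect the
#' discrete multi-peaked ISI histograms of small channel populations.
#'
#' @param hist output of [isi_histogram()].
#' @param floor_frac noise floor as a fraction of the peak (default 0.02).
#' @export
count_isih_modes <- function(hist, floor_frac = 0.02) {
  d <- hist$density
  n <- length(d)
  if (n < 3) return(as.integer(n > 0))
  floorv <- floor_frac * max(d)
  pad <- c(-Inf, d, -Inf)   # boundary bins can carry a mode (discrete atoms)
  sum(pad[2:(n + 1)] > pad[1:n] & pad[2:(n + 1)] >= pad[3:(n + 2)] &
        pad[2:(n + 1)] > floorv)
}

#' Trial-averaged time-dependent firing rate (PSTH)
#'
#' @param trials list of [spike_train()] objects sharing the same window.
#' @param binwidth bin width (ms).
#' @return object of class `psth`: list with bin centers `t`, `rate`, per-bin
#'   standard error `se` (across trials), `binwidth`, `n_trials`.  The rate
#'   integrates to the mean spike count per trial.
#' @export
time_dependent_rate <- function(trials, binwidth) {
  if (length(trials) < 2) stop_param("need at least 2 trials")
  if (!all(vapply(trials, inherits, TRUE, "spike_train")))
    stop_param("`trials` must be a list of spike_train objects")
  w <- trials[[1]]$window
  same <- vapply(trials, function(tr) isTRUE(all.equal(tr$window, w)), TRUE)
  if (!all(same)) stop_param("all trials must share the same window")
  check_scalar(binwidth, "binwidth", lower = .Machine$double.xmin)
  edges <- seq(w[1], w[2], by = binwidth)
  if (edges[length(edges)] < w[2]) edges <- c(edges, w[2])
  nb <- length(edges) - 1L
  counts <- vapply(trials, function(tr) {
    if (!length(tr$times)) return(numeric(nb))
    tabulate(findInterval(tr$times, edges, rightmost.closed = TRUE), nb)
  }, numeric(nb))
  wbin <- diff(edges)
  rate_trial <- counts / wbin
  rate <- rowMeans(rate_trial)
  se <- apply(rate_trial, 1, stats::sd) / sqrt(length(trials))
  structure(list(t = (edges[-1] + edges[-length(edges)]) / 2, rate = rate,
                 se = se, binwidth = binwidth, edges = edges,
                 n_trials = length(trials)), class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins of %g ms, %d trials, mean rate %.4g/ms\n",
              length(x$t), x$binwidth, x$n_trials, mean(x$rate)))
  invisible(x)
}

#' Export ISI statistics as JSON / a histogram as CSV
#'
#' @param stats an [isi_stats()] object.
#' @param path output file.
#' @param provenance optional named list stored under `"provenance"`.
#' @export
write_isi_stats <- function(stats, path, provenance = NULL) {
  stopifnot(inherits(stats, "isi_stats"))
  write_json_file(c(unclass(stats), list(provenance = provenance)), path)
}

#' @rdname write_isi_stats
#' @param hist output of [isi_histogram()].
#' @export
write_isi_histogram <- function(hist, path) {
  n <- length(hist$density)
  utils::write.csv(data.frame(bin_left = hist$breaks[seq_len(n)],
                              bin_right = hist$breaks[-1],
                              density = hist$density),
                   path, row.names = FALSE)
  invisible(path)
}
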