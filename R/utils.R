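## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_param("`", name, "` must be a single finite number")
  if (!allow_inf && !is.finite(x))
    stop_param("`", name, "` must be finite")
  if (x < lower || x > upper)
    stop_param("`", name, "` must be in [", lower, ", ", upper, "], got ", x)
  invisible(x)
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_param("`seed` is required for every stochastic operation ",
               "(a single integer)")
  as.integer(seed)
}

set_sim_seed <- function(seed) {
  set.seed(check_seed(seed))
}

## derive a reproducible per-trial seed below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

## Var[ int_0^s eta ] / (sigma^2 tau^2) for a stationary OU process with unit
## correlation time, evaluated stably (series below the cancellation regime)
ou_int_var <- function(s) {
  ifelse(s < 0.02,
         s^2 * (1 - s / 3 + s^2 / 12 - s^3 / 60),
         2 * (s - 1 + exp(-s)))
}

## Var[ int_0^s eta ] / sigma^2 when eta starts at a known value (zero-mean
## conditional variance); series-protected
ou_int_var0 <- function(s) {
  ifelse(s < 0.02,
         (2 / 3) * s^3 * (1 - 0.75 * s + 0.35 * s^2 - (31 / 240) * s^3),
         2 * s - 3 + 4 * exp(-s) - exp(-2 * s))
}

simpson_weights <- function(n, h) {
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
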