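#' Spike trains
#'
#' An ordered set of spike times together with its observation window; the
#' universal output of all simulators in this package.
#'
#' @param times strictly increasing spike times.
#' @param window numeric length-2 observation window `[t_start, t_end]`.
#' @param units time units tag (default "ms").
#' @param config optional configuration object attached as provenance.
#' @param seed optional RNG seed attached as provenance.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, window, units = "ms", config = NULL,
                        seed = NULL) {
  times <- as.numeric(times)
  if (length(times) && is.unsorted(times, strictly = TRUE))
    stop_param("spike times must be strictly increasing")
  if (length(window) != 2L || window[2] <= window[1])
    stop_param("`window` must be c(t_start, t_end) with t_end > t_start")
  if (length(times) && (times[1] < window[1] || times[length(times)] > window[2]))
    stop_param("all spike times must lie inside the observation window")
  structure(list(times = times, window = as.numeric(window), units = units,
                 config = config, seed = seed),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Spike train: %d spikes on [%g, %g] %s (rate %.4g/%s)\n",
              n, x$window[1], x$window[2], x$units,
              n / diff(x$window), x$units))
  invisible(x)
}

#' Interspike intervals of a spike train
#'
#' By default the non-stationary transient is removed: spikes before
#' `max(10 tau_a, time of the 21st spike)` are discarded (whichever is longer),
#' so that the mean adaptation has equilibrated.  `tau_a` is taken from the
#' attached configuration when present.
#'
#' @param train a [spike_train()].
#' @param transient `"auto"` (default) or `"none"`.
#' @param tau_a adaptation time constant used by the `"auto"` rule; default
#'   from the train's config, else 0.
#' @return An [isi_sample()].
#' @export
as_isi_sample <- function(train, transient = c("auto", "none"), tau_a = NULL) {
  stopifnot(inherits(train, "spike_train"))
  transient <- match.arg(transient)
  tt <- train$times
  if (transient == "auto" && length(tt) > 21L) {
    if (is.null(tau_a)) {
      cfg <- train$config
      tau_a <- if (!is.null(cfg$kinetics)) cfg$kinetics$tau_a
               else cfg$tau_eff %||% cfg$tau_a %||% 0
    }
    t_cut <- max(train$window[1] + 10 * tau_a, tt[21L])
    tt <- tt[tt >= t_cut]
  }
  isi_sample(diff(tt))
}

#' Write / read spike trains as plain text
#'
#' One spike time per line; header comment lines (`#`) carry the units and the
#' observation window.  A JSON sidecar `<path>.json` stores the configuration
#' and seed when available.
#'
#' @param train a [spike_train()].
#' @param path output file.
#' @export
write_spike_train <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# units: %s", train$units),
               sprintf("# window: %.17g %.17g", train$window[1],
                       train$window[2]),
               sprintf("%.17g", train$times)), con)
  if (!is.null(train$config) || !is.null(train$seed))
    write_json_file(list(config = unclass_deep(train$config),
                         seed = train$seed),
                    paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  units <- sub("^# units: ", "", grep("^# units:", lines, value = TRUE))
  win <- scan(text = sub("^# window: ", "",
                         grep("^# window:", lines, value = TRUE)),
              quiet = TRUE)
  times <- as.numeric(lines[!hdr & nzchar(lines)])
  spike_train(times, window = win,
              units = if (length(units)) units else "ms")
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
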