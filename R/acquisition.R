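# Capture trigger over a stream of scale readings.
#
# The scale is read every 0.2 s; when 4 consecutive readings all lie within
# the population weight range and their spread (max - min) is strictly less
# than 0.2 kg, a pig is judged to be standing quietly on the platform and a
# capture is fired.

#' Trigger configuration
#'
#' @param window number of consecutive readings examined (>= 2).
#' @param max_spread_kg stability threshold; the window spread must be
#'   strictly below this.
#' @param population_range_kg closed interval of plausible pig weights.
#' @param sampling_interval_s scale read period.
#' @param refractory_readings number of readings after a capture during
#'   which no new capture fires (prevents duplicate captures of one stable
#'   plateau); defaults to the window size.
#' @return an object of class `trigger_config`.
#' @export
trigger_config <- function(window = 4L, max_spread_kg = 0.2,
                           population_range_kg = c(16.5, 117),
                           sampling_interval_s = 0.2,
                           refractory_readings = window) {
  stopifnot(window >= 2, max_spread_kg > 0,
            population_range_kg[1] < population_range_kg[2])
  structure(list(window = as.integer(window), max_spread_kg = max_spread_kg,
                 population_range_kg = population_range_kg,
                 sampling_interval_s = sampling_interval_s,
                 refractory_readings = as.integer(refractory_readings)),
            class = "trigger_config")
}

#' Capture decision for one window of readings
#'
#' @param last_readings numeric vector of exactly `config$window` weights
#'   (kg), oldest first.
#' @param config a [trigger_config()].
#' @return `TRUE` iff every reading lies in the population range (closed
#'   interval) and the spread is strictly less than `max_spread_kg`.
#' @export
should_capture <- function(last_readings, config = trigger_config()) {
  if (length(last_readings) != config$window)
    stop("expected exactly ", config$window, " readings, got ", length(last_readings))
  if (any(!is.finite(last_readings))) stop("non-finite weight reading")
  rng <- config$population_range_kg
  all(last_readings >= rng[1] & last_readings <= rng[2]) &&
    (max(last_readings) - min(last_readings)) < config$max_spread_kg
}

#' Scan a reading stream for capture events
#'
#' Slides a window of `config$window` readings over the stream; whenever
#' [should_capture()] is true at the window's last reading and at least
#' `refractory_readings` readings have passed since the previous capture, a
#' capture event is emitted at that reading's timestamp.
#'
#' @param readings data frame with columns `timestamp_ms` (non-decreasing)
#'   and `weight_kg`, or a numeric weight vector (timestamps are then
#'   derived from `sampling_interval_s`).
#' @param config a [trigger_config()].
#' @return data frame of capture events with columns `index` (position of
#'   the window's last reading), `timestamp_ms` and `weight_kg`.
#' @export
process_stream <- function(readings, config = trigger_config()) {
  if (is.numeric(readings))
    readings <- data.frame(
      timestamp_ms = round(seq_along(readings) * config$sampling_interval_s * 1000),
      weight_kg = readings)
  stopifnot(all(c("timestamp_ms", "weight_kg") %in% names(readings)))
  ts <- readings$timestamp_ms
  if (is.unsorted(ts)) stop("timestamps must be non-decreasing")
  w <- readings$weight_kg
  n <- length(w)
  events <- list()
  last_capture <- -Inf
  if (n >= config$window) {
    for (i in config$window:n) {
      if (i - last_capture < config$refractory_readings) next
      win <- w[(i - config$window + 1L):i]
      if (should_capture(win, config)) {
        events[[length(events) + 1L]] <-
          data.frame(index = i, timestamp_ms = ts[i], weight_kg = mean(win))
        last_capture <- i
      }
    }
  }
  if (!length(events))
    return(data.frame(index = integer(), timestamp_ms = numeric(),
                      weight_kg = numeric()))
  do.call(rbind, events)
}
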