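#' Uniformly sampled single-channel series
#'
#' @param values numeric vector of equidistant samples.
#' @param channel channel id, one of `"BBI"`, `"SBP"`, `"DBP"`.
#' @param sample_rate sampling rate in Hz (default 2).
#' @param normalized logical; `TRUE` after [znormalize()].
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, channel = c("BBI", "SBP", "DBP"),
                           sample_rate = 2, normalized = FALSE) {
  channel <- match.arg(channel)
  structure(list(values = as.numeric(values), channel = channel,
                 sample_rate = sample_rate, normalized = isTRUE(normalized)),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %s: %d samples @ %g Hz%s\n", x$channel,
              length(x$values), x$sample_rate,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Adaptive artifact filtering of beat series
#'
#' Flags beats whose value deviates from a causal running location estimate
#' by more than `lambda_sd` running scale units (plus a small
#' basic-variability floor proportional to the running level, so that
#' physiological noise in an otherwise clean recording is not flagged), and
#' replaces flagged beats by linear interpolation between the nearest
#' unflagged neighbours. The running statistics are the median and the MAD
#' over the trailing `window` raw beats, per channel: robust location/scale
#' keep seldom-occurring ectopic beats from inflating the local variance
#' estimate, without any feedback that could cascade. A beat flagged in any
#' channel is treated as an artifact beat in all channels.
#'
#' @param series a [beat_series].
#' @param lambda_sd positive deviation threshold in running standard
#'   deviations (default 3).
#' @param window trailing window length in beats (default 20, minimum 3).
#' @param base_frac basic-variability floor as a fraction of the running mean
#'   added to the tolerated deviation (default 0.05).
#' @return A list with `series` (a new [beat_series] with interpolated values
#'   and updated `artifact_flags`) and `artifact_fraction` (flagged beats over
#'   total beats). Records with a fraction above 0.05 are conventionally
#'   excluded from cohort analyses; see [generate_cohort()].
#' @export
filter_artifacts <- function(series, lambda_sd = 3, window = 20,
                             base_frac = 0.05) {
  stopifnot(inherits(series, "beat_series"))
  if (window < 3) stop("window must be at least 3 beats", call. = FALSE)
  if (lambda_sd <= 0) stop("lambda_sd must be positive", call. = FALSE)
  n <- length(series$bbi)
  if (n < window)
    stop("series shorter than the filter window", call. = FALSE)

  flag_channel <- function(x) {
    flags <- rep(FALSE, n)
    for (i in 2:n) {
      lo <- max(1L, i - window)
      seg <- x[lo:(i - 1L)]
      m <- stats::median(seg)   # robust against spikes inside the window
      s <- stats::mad(seg)
      if (is.na(s)) s <- 0
      tol <- lambda_sd * s + base_frac * abs(m)
      if (abs(x[i] - m) > tol) flags[i] <- TRUE
    }
    flags
  }

  flags <- flag_channel(series$bbi) | flag_channel(series$sbp) |
    flag_channel(series$dbp)
  if (all(flags))
    stop("degenerate input: every beat flagged as artifact", call. = FALSE)

  interp <- function(x) {
    if (!any(flags)) return(x)
    ok <- which(!flags)
    # rule = 2: constant extension when flagged beats lead/trail the record
    stats::approx(ok, x[ok], xout = seq_len(n), rule = 2)$y
  }

  out <- beat_series(bbi = interp(series$bbi), sbp = interp(series$sbp),
                     dbp = interp(series$dbp),
                     subject_id = series$subject_id, group = series$group,
                     artifact_flags = flags)
  list(series = out, artifact_fraction = sum(flags) / n)
}

#' Resample a beat-series channel to a uniform 2 Hz grid
#'
#' Beat timestamps are reconstructed from the cumulative BBI (beat n occurs at
#' the sum of the first n intervals, converted ms to s). The chosen channel is
#' linearly interpolated at t = 0, 0.5, 1.0, ... up to the last beat time,
#' giving `floor(duration * fs) + 1` samples; before the first beat the first
#' value is extended.
#'
#' @param series a [beat_series].
#' @param channel `"BBI"`, `"SBP"` or `"DBP"`.
#' @param fs target sampling rate in Hz, default 2.
#' @return A [uniform_series].
#' @export
resample_2hz <- function(series, channel = c("BBI", "SBP", "DBP"), fs = 2) {
  stopifnot(inherits(series, "beat_series"))
  channel <- match.arg(channel)
  if (length(series$bbi) < 2L)
    stop("at least two beats required for resampling", call. = FALSE)
  t_beat <- cumsum(series$bbi) / 1000
  x <- switch(channel, BBI = series$bbi, SBP = series$sbp, DBP = series$dbp)
  grid <- seq(0, floor(t_beat[length(t_beat)] * fs) / fs, by = 1 / fs)
  vals <- stats::approx(t_beat, x, xout = grid, rule = 2)$y
  uniform_series(vals, channel = channel, sample_rate = fs)
}

#' Z-normalize a uniform series to zero mean and unit variance
#'
#' Subtracts the mean and divides by the population standard deviation
#' (divisor N), so the output has exactly unit variance under the population
#' convention. Idempotent up to numerical tolerance.
#'
#' @param series a [uniform_series].
#' @return A [uniform_series] with `normalized = TRUE`.
#' @export
znormalize <- function(series) {
  stopifnot(inherits(series, "uniform_series"))
  x <- series$values
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0)
    stop("zero-variance input cannot be normalized", call. = FALSE)
  uniform_series((x - m) / s, channel = series$channel,
                 sample_rate = series$sample_rate, normalized = TRUE)
}
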