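#' Time-domain variability indices
#'
#' Computes on a beat-value series: `meanNN`; `sdNN` (sample sd, divisor
#' N-1); `rmssd`, the root mean square of successive differences; and
#' `pNN50`, the proportion of adjacent pairs differing by more than
#' `nn50_threshold` (50 channel units by convention) among the N-1 pairs.
#'
#' @param x numeric beat-value sequence, length >= 2.
#' @param nn50_threshold absolute successive-difference threshold in channel
#'   units (default 50).
#' @return Named vector `meanNN`, `sdNN`, `rmssd`, `pNN50`.
#' @export
time_domain_indices <- function(x, nn50_threshold = 50) {
  if (length(x) < 2L)
    stop("at least two beats required", call. = FALSE)
  d <- diff(x)
  c(meanNN = mean(x), sdNN = stats::sd(x),
    rmssd = sqrt(mean(d^2)),
    pNN50 = sum(abs(d) > nn50_threshold) / length(d))
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: the series is split into segments of
#' `seg_len` samples with 50% overlap, each segment is mean-detrended and
#' Hann-windowed, and the one-sided periodograms are averaged. The density is
#' scaled so that its integral over frequency equals the windowed signal
#' variance (units: channel-units squared per Hz).
#'
#' @param x numeric vector of uniform samples.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length (default 256 samples).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs = 2, seg_len = 256L, overlap = 0.5) {
  n <- length(x)
  if (n < seg_len)
    stop("series shorter than one segment", call. = FALSE)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  norm <- sum(w^2)
  acc <- numeric(seg_len %/% 2 + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2 / (norm * fs)
    half <- sp[seq_len(seg_len %/% 2 + 1L)]
    # fold two-sided spectrum into one-sided density
    half[2:(seg_len %/% 2)] <- 2 * half[2:(seg_len %/% 2)]
    acc <- acc + half
  }
  list(freq = (seq_len(seg_len %/% 2 + 1L) - 1L) * fs / seg_len,
       psd = acc / length(starts))
}

band_power <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq < hi
  if (!any(sel)) return(0)
  sum(psd[sel]) * (freq[2] - freq[1])
}

#' Frequency-domain variability indices
#'
#' Band powers of the Welch PSD of a uniformly resampled (2 Hz) series:
#' VLF 0.0033-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz, plus `LF/HF` and
#' the normalized powers `LFn = LF/(LF+HF)`, `HFn = HF/(LF+HF)`.
#'
#' @param series a [uniform_series] (not z-normalized, so powers keep the
#'   channel's squared units), at least 5 min of samples.
#' @param seg_len Welch segment length, default 256.
#' @return Named vector `VLF`, `LF`, `HF`, `LF/HF`, `LFn`, `HFn`.
#' @export
frequency_domain_indices <- function(series, seg_len = 256L) {
  stopifnot(inherits(series, "uniform_series"))
  x <- series$values
  fs <- series$sample_rate
  if (length(x) < 5 * 60 * fs)
    stop("at least 5 minutes of samples required", call. = FALSE)
  ps <- welch_psd(x, fs = fs, seg_len = seg_len)
  vlf <- band_power(ps$freq, ps$psd, 0.0033, 0.04)
  lf <- band_power(ps$freq, ps$psd, 0.04, 0.15)
  hf <- band_power(ps$freq, ps$psd, 0.15, 0.4)
  tot <- lf + hf
  c(VLF = vlf, LF = lf, HF = hf,
    `LF/HF` = if (hf > 0) lf / hf else NA_real_,
    LFn = if (tot > 0) lf / tot else NA_real_,
    HFn = if (tot > 0) hf / tot else NA_real_)
}

#' Standard HRV/BPV feature vector for all three channels
#'
#' Per channel (`BBI`, `SYS`, `DIA`): the four time-domain indices and the
#' three core band indices `LF`, `HF`, `LF/HF` (21 core indices), plus the
#' supplementary `VLF`, `LFn`, `HFn`.
#'
#' @param series a [beat_series] (ideally artifact-filtered).
#' @return Named numeric vector of 30 features (21 core + 9 supplementary).
#' @export
standard_features <- function(series) {
  stopifnot(inherits(series, "beat_series"))
  chans <- list(BBI = "BBI", SYS = "SBP", DIA = "DBP")
  out <- numeric(0)
  for (nm in names(chans)) {
    x <- switch(chans[[nm]], BBI = series$bbi, SBP = series$sbp,
                DBP = series$dbp)
    td <- time_domain_indices(x)
    fd <- frequency_domain_indices(resample_2hz(series, chans[[nm]]))
    v <- c(td["meanNN"], td["sdNN"], td["rmssd"], td["pNN50"],
           fd["LF"], fd["HF"], fd["LF/HF"], fd["VLF"], fd["LFn"], fd["HFn"])
    names(v) <- paste0(nm, "_", c("meanNN", "sdNN", "rmssd", "pNN50",
                                  "LF", "HF", "LF/HF", "VLF", "LFn", "HFn"))
    out <- c(out, v)
  }
  out
}
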