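#' Fit a multichannel autoregressive (MAR) model with SBC order selection
#'
#' Least-squares estimation of an m-channel AR(p) model for each candidate
#' order `1..p_max`, on a common effective sample (the first `p_max` samples
#' are used only as presample), selecting the order that minimizes Schwarz's
#' Bayesian Criterion
#' \deqn{SBC(p) = \log\det\hat\Sigma_p + m^2 p \, \log(n_{eff}) / n_{eff}.}
#'
#' @param x numeric matrix, one column per channel (rows = time), or a list
#'   of [uniform_series] of equal length.
#' @param p_max maximum candidate order.
#' @param intercept include an intercept term (default TRUE; harmless on
#'   z-normalized input).
#' @return An object of class `mar_model`: `dim`, `order`, `coeffs` (list of
#'   p m x m matrices; element `A[i, j]` is the influence of channel j at the
#'   given lag on channel i), `intercept`, `noise_cov`, `sbc` (vector over
#'   candidate orders), `stable`, `n_eff`.
#' @export
fit_mar <- function(x, p_max = 20L, intercept = TRUE) {
  x <- as_channel_matrix(x)
  m <- ncol(x); n <- nrow(x)
  n_eff <- n - p_max
  if (n_eff <= p_max * m + 1L)
    stop("series too short for the requested maximum order", call. = FALSE)
  Y <- x[(p_max + 1):n, , drop = FALSE]
  # lagged design, lag r in columns ((r-1)m+1):(rm)
  Z <- matrix(0, n_eff, p_max * m)
  for (r in seq_len(p_max))
    Z[, ((r - 1) * m + 1):(r * m)] <- x[(p_max + 1 - r):(n - r), ,
                                        drop = FALSE]
  sbc <- numeric(p_max)
  fits <- vector("list", p_max)
  for (p in seq_len(p_max)) {
    Zp <- Z[, seq_len(p * m), drop = FALSE]
    if (intercept) Zp <- cbind(1, Zp)
    fit <- tryCatch(stats::lm.fit(Zp, Y), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients)))
      stop("rank-deficient regressor matrix in MAR fit", call. = FALSE)
    res <- fit$residuals
    sigma <- crossprod(res) / n_eff
    ld <- determinant(sigma, logarithm = TRUE)
    sbc[p] <- as.numeric(ld$modulus) + m * m * p * log(n_eff) / n_eff
    fits[[p]] <- fit
  }
  p_opt <- which.min(sbc)
  fit <- fits[[p_opt]]
  B <- fit$coefficients
  ic <- if (intercept) B[1, ] else rep(0, m)
  Bc <- if (intercept) B[-1, , drop = FALSE] else B
  coeffs <- lapply(seq_len(p_opt), function(r)
    t(Bc[((r - 1) * m + 1):(r * m), , drop = FALSE]))
  res <- fit$residuals
  noise_cov <- crossprod(res) / (n_eff - nrow(B))
  stable <- mar_spectral_radius(coeffs, m) < 1
  if (!stable)
    warning("selected MAR model is unstable (spectral radius >= 1)",
            call. = FALSE)
  structure(list(dim = m, order = p_opt, coeffs = coeffs, intercept = ic,
                 noise_cov = noise_cov, sbc = sbc, stable = stable,
                 n_eff = n_eff),
            class = "mar_model")
}

mar_spectral_radius <- function(coeffs, m) {
  p <- length(coeffs)
  comp <- matrix(0, m * p, m * p)
  for (r in seq_len(p)) comp[1:m, ((r - 1) * m + 1):(r * m)] <- coeffs[[r]]
  if (p > 1) comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

as_channel_matrix <- function(x) {
  if (is.list(x) && all(vapply(x, inherits, logical(1), "uniform_series"))) {
    lens <- vapply(x, function(s) length(s$values), integer(1))
    if (length(unique(lens)) != 1L)
      stop("all channels must have equal length", call. = FALSE)
    x <- do.call(cbind, lapply(x, function(s) s$values))
  }
  as.matrix(x)
}

#' Partial directed coherence of a MAR model
#'
#' Column-normalized PDC: with the spectral coefficient matrix
#' \deqn{\bar A(f) = I - \sum_{r=1}^p A_r e^{-i 2 \pi f r / f_s},}
#' the coupling from source channel j to target i is
#' \deqn{\pi_{i \leftarrow j}(f) = |\bar A_{ij}(f)| /
#'   \sqrt{\sum_k |\bar A_{kj}(f)|^2},}
#' so each source column satisfies \eqn{\sum_i \pi_{ij}^2 = 1} at every
#' frequency.
#'
#' @param model a [fit_mar()] result.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return Array `(freq, target, source)` of PDC values in [0, 1].
#' @export
mar_pdc <- function(model, freqs, fs = 2) {
  m <- model$dim
  out <- array(NA_real_, c(length(freqs), m, m))
  for (fi in seq_along(freqs)) {
    Af <- diag(m) + 0i
    for (r in seq_along(model$coeffs))
      Af <- Af - model$coeffs[[r]] * exp(-2i * pi * freqs[fi] * r / fs)
    den <- sqrt(colSums(Mod(Af)^2))
    out[fi, , ] <- sweep(Mod(Af), 2, den, "/")
  }
  out
}

#' Time-variant PDC over sliding windows
#'
#' Splits the channels into windows of `window_len` samples advancing by
#' `window_shift`, fits a MAR model per window ([fit_mar()]), and evaluates
#' the column-normalized PDC on `n_freq` equidistant bins over
#' `[0, fs/2]`. Windows whose fit fails are skipped and recorded.
#'
#' @param x channel matrix or list of [uniform_series] (z-normalized input
#'   is assumed for coupling analysis).
#' @param window_len window length in samples (default 600 = 5 min at 2 Hz).
#' @param window_shift shift between windows (default 300, 50% overlap).
#' @param p_max maximum MAR order per window.
#' @param n_freq number of frequency bins.
#' @param fs sampling rate in Hz.
#' @return An object of class `tvpdc_field`: `pdc` array
#'   `(window, freq, target, source)`, `freqs`, `windows` (start indices),
#'   `skipped`, `fs`.
#' @export
tvpdc <- function(x, window_len = 600L, window_shift = 300L, p_max = 20L,
                  n_freq = 64L, fs = 2) {
  x <- as_channel_matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < window_len) stop("series shorter than one window", call. = FALSE)
  if (window_shift < 1L) stop("window_shift must be >= 1", call. = FALSE)
  starts <- seq(1L, n - window_len + 1L, by = window_shift)
  freqs <- seq(0, fs / 2, length.out = n_freq)
  pdc <- array(NA_real_, c(length(starts), n_freq, m, m))
  skipped <- integer(0)
  for (w in seq_along(starts)) {
    seg <- x[starts[w]:(starts[w] + window_len - 1L), , drop = FALSE]
    model <- tryCatch(
      suppressWarnings(fit_mar(seg, p_max = p_max)),
      error = function(e) NULL)
    if (is.null(model)) { skipped <- c(skipped, w); next }
    pdc[w, , , ] <- mar_pdc(model, freqs, fs = fs)
  }
  if (length(skipped) == length(starts))
    stop("every window failed to fit", call. = FALSE)
  structure(list(pdc = pdc, freqs = freqs, windows = starts,
                 window_len = window_len, window_shift = window_shift,
                 skipped = skipped, fs = fs),
            class = "tvpdc_field")
}

#' Quantized coupling direction (normalized factor NF)
#'
#' Maps the window- and frequency-averaged directional couplings
#' (`a_bar` forward x -> y, `b_bar` backward y -> x) to the normalized
#' factor: 2 if the forward mean dominates with ratio > 5, 1 for ratio in
#' (2, 5], 0 for ratio <= 2; mirrored with negative sign when the backward
#' mean dominates (negative NF marks y as the driver). Both means zero is
#' flagged `"no coupling"`; equal positive means `"equal influence"`.
#'
#' @param a_bar forward mean coupling (x -> y), >= 0.
#' @param b_bar backward mean coupling (y -> x), >= 0.
#' @return Integer in \{-2, -1, 0, 1, 2\} with attribute `"flag"` (one of
#'   `"none"`, `"no coupling"`, `"equal influence"`).
#' @export
#' @examples
#' nf_quantize(0.6, 0.1)  # ratio 6 -> 2, strong unidirectional
nf_quantize <- function(a_bar, b_bar) {
  stopifnot(a_bar >= 0, b_bar >= 0)
  flag <- "none"
  if (a_bar == 0 && b_bar == 0) {
    nf <- 0L; flag <- "no coupling"
  } else if (a_bar == b_bar) {
    nf <- 0L; flag <- "equal influence"
  } else if (a_bar > b_bar) {
    ratio <- if (b_bar == 0) Inf else a_bar / b_bar
    nf <- if (ratio > 5) 2L else if (ratio > 2) 1L else 0L
  } else {
    ratio <- if (a_bar == 0) Inf else b_bar / a_bar
    nf <- if (ratio > 5) -2L else if (ratio > 2) -1L else 0L
  }
  attr(nf, "flag") <- flag
  nf
}

#' Coupling summary (coupling factor, NF, area strengths) for a channel pair
#'
#' Averages the tvPDC over all windows and frequencies in each direction:
#' `a_bar` = mean forward (x -> y), `b_bar` = mean backward. The coupling
#' factor is `a_bar / b_bar`, quantized to the normalized factor by
#' [nf_quantize()]. The area coupling strengths are the same directional
#' means (per-window frequency averages, averaged across windows), bounded
#' in [0, 1].
#'
#' @param field a [tvpdc()] result.
#' @param x index (or name position) of the driving channel of the forward
#'   direction.
#' @param y index of the target channel of the forward direction.
#' @return An object of class `coupling_summary`: `a_bar`, `b_bar`, `cf`,
#'   `nf`, `nf_flag`, `area_xy`, `area_yx`.
#' @export
coupling_summary <- function(field, x, y) {
  stopifnot(inherits(field, "tvpdc_field"))
  ok <- setdiff(seq_along(field$windows), field$skipped)
  fwd <- field$pdc[ok, , y, x, drop = FALSE]  # pi_{y <- x}: x drives y
  bwd <- field$pdc[ok, , x, y, drop = FALSE]
  a_bar <- mean(fwd); b_bar <- mean(bwd)
  nf <- nf_quantize(a_bar, b_bar)
  structure(list(a_bar = a_bar, b_bar = b_bar,
                 cf = if (b_bar > 0) a_bar / b_bar else Inf,
                 nf = as.integer(nf), nf_flag = attr(nf, "flag"),
                 area_xy = a_bar, area_yx = b_bar),
            class = "coupling_summary")
}

#' NSTPDC feature vector for all three couplings
#'
#' Runs one trivariate tvPDC on z-normalized, 2 Hz-resampled BBI/SBP/DBP
#' series and summarizes the three pairs (cs, cd, ds; the third channel acts
#' as covariate), giving 9 indices: `NSTPDCxy_NF`, `NSTPDCxy_Area_x-y`,
#' `NSTPDCxy_Area_y-x`.
#'
#' @param series a [beat_series] (ideally artifact-filtered).
#' @param window_len,window_shift,p_max,n_freq see [tvpdc()].
#' @return Named numeric vector of 9 features.
#' @export
nstpdc_features <- function(series, window_len = 600L, window_shift = 300L,
                            p_max = 20L, n_freq = 64L) {
  chans <- lapply(c("BBI", "SBP", "DBP"), function(ch)
    znormalize(resample_2hz(series, ch)))
  n <- length(chans[[1]]$values)
  wl <- min(window_len, n)
  pm <- min(p_max, max(2L, (wl - 2L) %/% (10L * 3L)))
  field <- tvpdc(chans, window_len = wl, window_shift = window_shift,
                 p_max = pm, n_freq = n_freq)
  # channel order: 1 = BBI (c), 2 = SBP (s), 3 = DBP (d)
  pairs <- list(cs = c(1L, 2L), cd = c(1L, 3L), ds = c(3L, 2L))
  out <- numeric(0)
  for (tag in names(pairs)) {
    pr <- pairs[[tag]]
    cs <- coupling_summary(field, pr[1], pr[2])
    ch <- strsplit(tag, "")[[1]]
    v <- c(cs$nf, cs$area_xy, cs$area_yx)
    names(v) <- c(paste0("NSTPDC", tag, "_NF"),
                  paste0("NSTPDC", tag, "_Area_", ch[1], "-", ch[2]),
                  paste0("NSTPDC", tag, "_Area_", ch[2], "-", ch[1]))
    out <- c(out, v)
  }
  out
}
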