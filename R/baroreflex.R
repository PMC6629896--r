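#' Detect baroreflex sequences (dual sequence method)
#'
#' Scans SBP for maximal monotone runs of at least `min_len` beats whose
#' per-step change exceeds `sbp_thresh` (1 mmHg), paired — with a `delay` of
#' one beat — with a BBI run whose per-step change exceeds `bbi_thresh`
#' (5 ms) in the same direction. Runs with both channels increasing are
#' bradycardic (the classical spontaneous baroreflex response), both
#' decreasing tachycardic. Each sequence's slope is the least-squares
#' regression of the BBI run on the SBP run, in ms/mmHg.
#'
#' @param series a [beat_series].
#' @param delay BBI lag behind SBP in beats (default 1).
#' @param min_len minimal run length in beats (default 3).
#' @param sbp_thresh per-step SBP change threshold in mmHg (default 1).
#' @param bbi_thresh per-step BBI change threshold in ms (default 5).
#' @param min_r optional minimal absolute Pearson correlation within a
#'   sequence (classical sequence method uses 0.85); `NULL` (default)
#'   disables the check.
#' @return An object of class `brs_sequences`: lists `bradycardic` and
#'   `tachycardic` of per-sequence records (`sbp`, `bbi`, `slope`, `start`),
#'   plus the detection parameters.
#' @export
detect_sequences <- function(series, delay = 1L, min_len = 3L,
                             sbp_thresh = 1, bbi_thresh = 5, min_r = NULL) {
  stopifnot(inherits(series, "beat_series"))
  n <- length(series$bbi)
  if (n < min_len + delay)
    stop("series too short for sequence detection", call. = FALSE)
  dsbp <- diff(series$sbp)
  dbbi <- diff(series$bbi)
  out <- list(bradycardic = list(), tachycardic = list())
  for (dir in c(1, -1)) {
    # steps where both channels move in direction `dir` beyond threshold,
    # BBI taken with the one-beat delay
    ok_sbp <- dir * dsbp > sbp_thresh
    step_idx <- seq_len(n - 1L - delay)
    ok <- ok_sbp[step_idx] & (dir * dbbi[step_idx + delay] > bbi_thresh)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= (min_len - 1L))) {
      i0 <- starts[k]; i1 <- ends[k] + 1L    # beats i0 .. i1 in SBP
      sbp_run <- series$sbp[i0:i1]
      bbi_run <- series$bbi[(i0 + delay):(i1 + delay)]
      if (!is.null(min_r) &&
          abs(stats::cor(sbp_run, bbi_run)) < min_r) next
      slope <- stats::cov(sbp_run, bbi_run) / stats::var(sbp_run)
      rec <- list(sbp = sbp_run, bbi = bbi_run, slope = slope, start = i0)
      if (dir == 1) out$bradycardic <- c(out$bradycardic, list(rec))
      else out$tachycardic <- c(out$tachycardic, list(rec))
    }
  }
  structure(c(out, list(delay = delay, min_len = min_len,
                        sbp_thresh = sbp_thresh, bbi_thresh = bbi_thresh)),
            class = "brs_sequences")
}

#' Baroreflex sensitivity indices from detected sequences
#'
#' `bslope` aggregates the bradycardic sequence slopes, `tslope` the
#' tachycardic ones; missing (`NA`) when no sequence of the kind was found.
#'
#' @param seqs a [detect_sequences()] result.
#' @param slope_agg aggregate across sequences: `"mean"` (default, standard
#'   sequence-method convention) or `"max"`.
#' @return An object of class `brs_result`: `bslope`, `tslope` (ms/mmHg),
#'   `n_brady`, `n_tachy`.
#' @export
brs_indices <- function(seqs, slope_agg = c("mean", "max")) {
  stopifnot(inherits(seqs, "brs_sequences"))
  slope_agg <- match.arg(slope_agg)
  agg <- function(lst) {
    if (length(lst) == 0L) return(NA_real_)
    s <- vapply(lst, function(r) r$slope, numeric(1))
    if (slope_agg == "mean") mean(s) else max(s)
  }
  structure(list(bslope = agg(seqs$bradycardic),
                 tslope = agg(seqs$tachycardic),
                 n_brady = length(seqs$bradycardic),
                 n_tachy = length(seqs$tachycardic)),
            class = "brs_result")
}

#' DSM feature vector
#' @param series a [beat_series].
#' @param ... passed to [detect_sequences()].
#' @return Named vector `bslope`, `tslope` (NA when undefined).
#' @export
dsm_features <- function(series, ...) {
  r <- brs_indices(detect_sequences(series, ...))
  c(bslope = r$bslope, tslope = r$tslope)
}
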