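#' Extract the full feature vector for one subject
#'
#' Runs artifact filtering, then all characterization methods on the
#' filtered beat series: HRJSD (81 indices per coupling), binary JSD (65 per
#' coupling), SPPA (168 per coupling), univariate PPA (3 per channel),
#' NSTPDC (9), standard HRV/BPV indices (21 core + 9 supplementary) and the
#' dual sequence method (2). Couplings are `cs` (BBI-SBP), `cd` (BBI-DBP)
#' and `ds` (DBP-SBP).
#'
#' @param series a [beat_series].
#' @param l_bbi,l_bp HRJSD equilibrium thresholds (5 ms, 1 mmHg).
#' @param lambda_sd,window artifact-filter parameters (see
#'   [filter_artifacts()]).
#' @param nstpdc_window,nstpdc_shift,nstpdc_pmax NSTPDC windowing (see
#'   [nstpdc_features()]).
#' @return Named numeric vector; attribute `"artifact_fraction"` carries the
#'   filtered artifact proportion.
#' @export
extract_features <- function(series, l_bbi = 5, l_bp = 1, lambda_sd = 3,
                             window = 20, nstpdc_window = 600L,
                             nstpdc_shift = 300L, nstpdc_pmax = 20L) {
  filt <- filter_artifacts(series, lambda_sd = lambda_sd, window = window)
  s <- filt$series
  pairs <- list(cs = list(s$bbi, s$sbp, l_bbi, l_bp),
                cd = list(s$bbi, s$dbp, l_bbi, l_bp),
                ds = list(s$dbp, s$sbp, l_bp, l_bp))
  out <- numeric(0)
  for (tag in names(pairs)) {
    pr <- pairs[[tag]]
    out <- c(out, hrjsd_features(pr[[1]], pr[[2]], tag, pr[[3]], pr[[4]]),
             jsd_features(pr[[1]], pr[[2]], tag),
             sppa_features(pr[[1]], pr[[2]], tag))
  }
  out <- c(out,
           ppa_features(s$bbi, "c"), ppa_features(s$sbp, "s"),
           ppa_features(s$dbp, "d"),
           nstpdc_features(s, window_len = nstpdc_window,
                           window_shift = nstpdc_shift,
                           p_max = nstpdc_pmax),
           standard_features(s),
           dsm_features(s))
  attr(out, "artifact_fraction") <- filt$artifact_fraction
  out
}

#' Build the cohort feature table
#'
#' Applies [extract_features()] to every subject and assembles the
#' subjects-by-indices table. Subjects whose artifact fraction exceeds
#' `max_artifact_fraction` are excluded (mirroring the usual rejection of
#' recordings with more than 5% ectopic beats or artifacts).
#'
#' @param cohort a `synthetic_cohort` or list of [beat_series].
#' @param max_artifact_fraction exclusion threshold, default 0.05.
#' @param ... passed to [extract_features()].
#' @param verbose print progress.
#' @return A `data.frame` with columns `subject_id`, `group`, then one
#'   column per index (names kept verbatim, `check.names = FALSE`).
#'   Attribute `"excluded"` lists excluded subject ids.
#' @export
cohort_features <- function(cohort, max_artifact_fraction = 0.05,
                            verbose = FALSE, ...) {
  subjects <- if (inherits(cohort, "synthetic_cohort")) cohort$subjects
              else cohort
  rows <- list(); excluded <- character(0)
  for (s in subjects) {
    fv <- extract_features(s, ...)
    if (attr(fv, "artifact_fraction") > max_artifact_fraction) {
      excluded <- c(excluded, s$subject_id)
      next
    }
    if (verbose) message("features: ", s$subject_id)
    rows[[length(rows) + 1L]] <-
      c(list(subject_id = s$subject_id, group = s$group), as.list(fv))
  }
  if (length(rows) == 0L)
    stop("no subject passed the artifact-fraction criterion", call. = FALSE)
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  attr(df, "excluded") <- excluded
  df
}
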