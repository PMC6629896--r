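#' Group profile for the synthetic cardiovascular generator
#'
#' A profile fixes the stationary means and standard deviations of the three
#' beat-aligned channels together with the autoregressive memory and the two
#' directed coupling arms: the baroreflex arm (SBP driving BBI, ms/mmHg) and
#' the mechanical arm (BBI driving SBP, mmHg/ms). The generator calibrates the
#' innovation noise so that the *stationary* BBI and SBP standard deviations
#' match `sd_bbi` and `sd_sbp` (see [generate_subject()]).
#'
#' @param name group label (`"CON"`, `"IDC_LR"`, `"IDC_HR"` or `"UNKNOWN"`).
#' @param mu_bbi,sd_bbi mean and stationary sd of BBI in ms.
#' @param mu_sbp,sd_sbp mean and stationary sd of SBP in mmHg.
#' @param mu_dbp,sd_dbp mean and residual sd of DBP in mmHg.
#' @param ar_bbi,ar_sbp AR(1) coefficients in (-1, 1).
#' @param gain_baroreflex baroreflex arm SBP -> BBI in ms/mmHg.
#' @param gain_mechanical mechanical arm BBI -> SBP in mmHg/ms.
#' @param dia_link unitless coefficient coupling DBP to the same-beat SBP
#'   deviation.
#' @param resp_freq,resp_amp respiratory modulation of SBP: frequency (Hz)
#'   and amplitude (mmHg).
#' @param ectopic_rate proportion of beats replaced by ectopy (halved BBI),
#'   in [0, 0.5).
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(name = "UNKNOWN", mu_bbi = 900, sd_bbi = 40,
                          mu_sbp = 120, sd_sbp = 4, mu_dbp = 60, sd_dbp = 2.5,
                          ar_bbi = 0.6, ar_sbp = 0.65,
                          gain_baroreflex = 4, gain_mechanical = 0.005,
                          dia_link = 0.45, resp_freq = 0.25, resp_amp = 1.5,
                          ectopic_rate = 0.005) {
  if (sd_bbi <= 0 || sd_sbp <= 0 || sd_dbp < 0)
    stop("standard deviations must be positive", call. = FALSE)
  if (abs(ar_bbi) >= 1 || abs(ar_sbp) >= 1)
    stop("AR coefficients must lie in (-1, 1)", call. = FALSE)
  if (ectopic_rate < 0 || ectopic_rate >= 0.5)
    stop("ectopic_rate must lie in [0, 0.5)", call. = FALSE)
  structure(list(name = name, mu_bbi = mu_bbi, sd_bbi = sd_bbi,
                 mu_sbp = mu_sbp, sd_sbp = sd_sbp, mu_dbp = mu_dbp,
                 sd_dbp = sd_dbp, ar_bbi = ar_bbi, ar_sbp = ar_sbp,
                 gain_baroreflex = gain_baroreflex,
                 gain_mechanical = gain_mechanical, dia_link = dia_link,
                 resp_freq = resp_freq, resp_amp = resp_amp,
                 ectopic_rate = ectopic_rate),
            class = "group_profile")
}

#' Shipped default group profiles
#'
#' Three profiles emulating a healthy control group (CON) and dilated
#' cardiomyopathy patients at low (IDC_LR) and high (IDC_HR) risk of sudden
#' cardiac death. Channel means and standard deviations follow the magnitudes
#' reported for such cohorts (BBI mean about 884/907/828 ms, BBI sd about
#' 48/37/33 ms for CON/LR/HR); HRV decreases and short-term BPV increases with
#' risk. The baroreflex gain decreases CON -> LR -> HR while the cardiac ->
#' pressure arm strengthens, so that directed-coupling estimators see a
#' pressure-driven cardiac rhythm in controls and a cardiac-driven pressure in
#' high-risk profiles. The coupling gains are declared generator defaults,
#' not literature measurements.
#'
#' @return Named list of three [group_profile] objects: `CON`, `IDC_LR`,
#'   `IDC_HR`.
#' @export
default_profiles <- function() {
  list(
    CON = group_profile(name = "CON", mu_bbi = 884, sd_bbi = 48,
                        mu_sbp = 122.5, sd_sbp = 4, mu_dbp = 60.6,
                        sd_dbp = 2.5, ar_bbi = 0.6, ar_sbp = 0.65,
                        gain_baroreflex = 5, gain_mechanical = 0.004,
                        ectopic_rate = 0.005),
    IDC_LR = group_profile(name = "IDC_LR", mu_bbi = 907, sd_bbi = 37,
                           mu_sbp = 112.6, sd_sbp = 4.5, mu_dbp = 58.5,
                           sd_dbp = 2.5, ar_bbi = 0.55, ar_sbp = 0.65,
                           gain_baroreflex = 3.5, gain_mechanical = 0.012,
                           ectopic_rate = 0.005),
    IDC_HR = group_profile(name = "IDC_HR", mu_bbi = 828, sd_bbi = 33,
                           mu_sbp = 121.3, sd_sbp = 6, mu_dbp = 61.5,
                           sd_dbp = 2.5, ar_bbi = 0.8, ar_sbp = 0.6,
                           gain_baroreflex = 0.8, gain_mechanical = 0.05,
                           ectopic_rate = 0.01)
  )
}

# Innovation variances (q_bbi, q_sbp) making the stationary covariance of the
# coupled bivariate recursion match the profile's target sds, via the
# discrete Lyapunov equation S = A S A' + Q with diagonal Q. Linear in the
# unknowns (s12, q1, q2) once s11 and s22 are fixed at their targets.
lyapunov_innovations <- function(profile) {
  a11 <- profile$ar_bbi; a12 <- profile$gain_baroreflex
  a21 <- profile$gain_mechanical; a22 <- profile$ar_sbp
  A <- matrix(c(a11, a21, a12, a22), 2, 2)
  rho <- max(abs(eigen(A, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf(
      "unstable recursion: spectral radius %.3f >= 1 for profile %s",
      rho, profile$name), call. = FALSE)
  s11 <- profile$sd_bbi^2; s22 <- profile$sd_sbp^2
  denom <- 1 - (a11 * a22 + a12 * a21)
  s12 <- (a11 * a21 * s11 + a12 * a22 * s22) / denom
  q1 <- (1 - a11^2) * s11 - 2 * a11 * a12 * s12 - a12^2 * s22
  q2 <- (1 - a22^2) * s22 - 2 * a21 * a22 * s12 - a21^2 * s11
  if (q1 <= 0 || q2 <= 0)
    stop(sprintf(paste0(
      "coupling gains too strong for the requested stationary variances ",
      "in profile %s (innovation variances %.2f, %.2f)"),
      profile$name, q1, q2), call. = FALSE)
  list(q_bbi = q1, q_sbp = q2, spectral_radius = rho)
}

#' Generate one synthetic subject
#'
#' Simulates coupled BBI/SBP/DBP beat series from a linear stochastic
#' difference-equation model:
#' \deqn{SBP_n = \mu_s + a_s (SBP_{n-1}-\mu_s) + g_m (BBI_{n-1}-\mu_b) +
#'   A_r \sin(2\pi f_r t_n) + \epsilon_s}
#' \deqn{BBI_n = \mu_b + a_b (BBI_{n-1}-\mu_b) + g_b (SBP_{n-1}-\mu_s) +
#'   \epsilon_b}
#' \deqn{DBP_n = \mu_d + c (SBP_n - \mu_s) + \epsilon_d}
#' Innovation variances are calibrated (discrete Lyapunov equation) so the
#' stationary BBI and SBP standard deviations equal the profile targets.
#' Ectopic beats are injected by halving the BBI at randomly chosen beats at
#' rate `ectopic_rate`. The invariant SBP > DBP is enforced by clipping with
#' a warning if the simulation ever violates it.
#'
#' @param profile a [group_profile].
#' @param n_beats number of beats (>= 100).
#' @param seed integer seed; generation is fully reproducible.
#' @param subject_id subject identifier.
#' @param burn_in beats discarded before recording, to reach stationarity.
#' @return A [beat_series].
#' @export
generate_subject <- function(profile, n_beats = 1800, seed = 1,
                             subject_id = "S1", burn_in = 200) {
  stopifnot(inherits(profile, "group_profile"))
  if (n_beats < 100) stop("n_beats must be at least 100", call. = FALSE)
  q <- lyapunov_innovations(profile)
  ntot <- n_beats + burn_in
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eb <- stats::rnorm(ntot, 0, sqrt(q$q_bbi))
  es <- stats::rnorm(ntot, 0, sqrt(q$q_sbp))
  ed <- stats::rnorm(ntot, 0, profile$sd_dbp)

  bbi <- numeric(ntot); sbp <- numeric(ntot)
  db <- 0; ds <- 0    # deviations from channel means
  t_n <- 0
  for (i in seq_len(ntot)) {
    ds_new <- profile$ar_sbp * ds + profile$gain_mechanical * db +
      profile$resp_amp * sin(2 * pi * profile$resp_freq * t_n) + es[i]
    db_new <- profile$ar_bbi * db + profile$gain_baroreflex * ds + eb[i]
    db <- db_new; ds <- ds_new
    bbi[i] <- profile$mu_bbi + db
    sbp[i] <- profile$mu_sbp + ds
    t_n <- t_n + bbi[i] / 1000
  }
  bbi <- pmax(bbi, 200)  # guard against non-physical intervals
  dbp <- profile$mu_dbp + profile$dia_link * (sbp - profile$mu_sbp) + ed

  keep <- (burn_in + 1L):ntot
  bbi <- bbi[keep]; sbp <- sbp[keep]; dbp <- dbp[keep]

  if (profile$ectopic_rate > 0) {
    n_ect <- stats::rbinom(1, n_beats, profile$ectopic_rate)
    if (n_ect > 0) {
      at <- sample(seq_len(n_beats), n_ect)
      bbi[at] <- bbi[at] / 2
    }
  }
  if (any(sbp <= dbp)) {
    warning("sbp <= dbp produced by simulation; clipping dbp", call. = FALSE)
    dbp <- pmin(dbp, sbp - 5)
  }
  beat_series(bbi = bbi, sbp = sbp, dbp = dbp, subject_id = subject_id,
              group = if (profile$name %in% c("CON", "IDC_LR", "IDC_HR"))
                profile$name else "UNKNOWN")
}

#' Generate a seeded synthetic cohort
#'
#' Each subject gets a deterministic seed derived from the master seed, so the
#' same call always reproduces the identical cohort. A small relative
#' between-subject jitter is applied to the profile means, sds and coupling
#' gains so subjects within a group are not replicates of one process.
#'
#' @param profiles list of [group_profile] objects (e.g. [default_profiles()]).
#' @param n_per_group subjects per profile (>= 1).
#' @param n_beats beats per subject.
#' @param seed master integer seed.
#' @param jitter relative between-subject variation of profile parameters
#'   (default 0.05).
#' @return An object of class `synthetic_cohort`: list with `subjects` (list
#'   of [beat_series]), `seed`, and `profiles`.
#' @export
generate_cohort <- function(profiles, n_per_group = 20, n_beats = 1800,
                            seed = 1, jitter = 0.05) {
  if (length(profiles) < 1L) stop("at least one profile required",
                                  call. = FALSE)
  if (n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  subjects <- list()
  idx <- 0L
  for (gi in seq_along(profiles)) {
    prof <- profiles[[gi]]
    for (si in seq_len(n_per_group)) {
      idx <- idx + 1L
      sub_seed <- (seed * 1000L + idx) %% .Machine$integer.max
      prof_i <- jitter_profile(prof, sub_seed, jitter)
      subjects[[idx]] <- generate_subject(
        prof_i, n_beats = n_beats, seed = sub_seed,
        subject_id = sprintf("%s_%02d", prof$name, si))
    }
  }
  structure(list(subjects = subjects, seed = seed, profiles = profiles),
            class = "synthetic_cohort")
}

jitter_profile <- function(profile, seed, jitter) {
  if (jitter <= 0) return(profile)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 7L)
  z <- stats::rnorm(7)
  p <- profile
  p$mu_bbi <- p$mu_bbi * exp(z[1] * jitter / 2)
  p$mu_sbp <- p$mu_sbp * exp(z[2] * jitter / 2)
  p$mu_dbp <- p$mu_dbp * exp(z[3] * jitter / 2)
  p$sd_bbi <- p$sd_bbi * exp(z[4] * jitter)
  p$sd_sbp <- p$sd_sbp * exp(z[5] * jitter)
  # gain jitter is shrunk toward the base profile if the drawn combination
  # would make the requested stationary variances infeasible
  shrink <- 1
  for (k in 1:12) {
    p$gain_baroreflex <- profile$gain_baroreflex * exp(z[6] * jitter * shrink)
    p$gain_mechanical <- profile$gain_mechanical * exp(z[7] * jitter * shrink)
    ok <- tryCatch({ lyapunov_innovations(p); TRUE },
                   error = function(e) FALSE)
    if (ok) break
    shrink <- shrink / 2
  }
  ok <- tryCatch({ lyapunov_innovations(p); TRUE }, error = function(e) FALSE)
  if (!ok) {  # keep jittered means, fall back to base dynamics
    p$sd_bbi <- profile$sd_bbi; p$sd_sbp <- profile$sd_sbp
    p$gain_baroreflex <- profile$gain_baroreflex
    p$gain_mechanical <- profile$gain_mechanical
  }
  p
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  groups <- table(vapply(x$subjects, function(s) s$group, character(1)))
  cat(sprintf("<synthetic_cohort> %d subjects (seed %d): %s\n",
              length(x$subjects), x$seed,
              paste(names(groups), groups, sep = "=", collapse = ", ")))
  invisible(x)
}

# Save/restore the global RNG state so seeded generation does not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
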