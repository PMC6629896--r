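# Simulate a stable bivariate AR(2) with known coefficients
sim_ar2 <- function(n, seed) {
  set.seed(seed)
  A1 <- matrix(c(0.5, 0.1, -0.2, 0.4), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.3, 0, 0.1, 0.2), 2, 2, byrow = TRUE)
  x <- matrix(0, n, 2)
  e <- matrix(rnorm(2 * n), n, 2)
  for (t in 3:n) x[t, ] <- A1 %*% x[t - 1, ] + A2 %*% x[t - 2, ] + e[t, ]
  list(x = x, A1 = A1, A2 = A2)
}

test_that("SBC selects the true order and LS recovers the coefficients", {
  # coverage across replicates: ~95% of coefficient estimates should fall
  # within 2 standard errors of the truth, and none far outside
  z_all <- c()
  for (seed in c(21, 101, 202)) {
    sim <- sim_ar2(4000, seed = seed)
    m <- fit_mar(sim$x, p_max = 8)
    expect_equal(m$order, 2L)
    expect_true(m$stable)
    # oracle: per-equation stats::lm on the same lagged design gives both
    # the coefficient estimates and their standard errors
    x <- sim$x; n <- nrow(x)
    d <- data.frame(y1 = x[3:n, 1], y2 = x[3:n, 2],
                    x1l1 = x[2:(n - 1), 1], x2l1 = x[2:(n - 1), 2],
                    x1l2 = x[1:(n - 2), 1], x2l2 = x[1:(n - 2), 2])
    for (eq in 1:2) {
      fit <- lm(reformulate(c("x1l1", "x2l1", "x1l2", "x2l2"),
                            paste0("y", eq)), data = d)
      cf <- coef(summary(fit))
      truth <- c(sim$A1[eq, ], sim$A2[eq, ])
      z_all <- c(z_all, (cf[-1, "Estimate"] - truth) / cf[-1, "Std. Error"])
      # package LS agrees with the lm oracle (different presample handling)
      mine <- c(m$coeffs[[1]][eq, ], m$coeffs[[2]][eq, ])
      expect_equal(unname(mine), unname(cf[-1, "Estimate"]),
                   tolerance = 0.02)
    }
  }
  expect_gte(mean(abs(z_all) < 2), 0.8)
  expect_true(all(abs(z_all) < 4))
})

test_that("white noise yields near-zero coefficients", {
  set.seed(22)
  x <- matrix(rnorm(4000), 2000, 2)
  m <- suppressWarnings(fit_mar(x, p_max = 5))
  se <- 1 / sqrt(m$n_eff)
  for (A in m$coeffs) expect_true(all(abs(A) < 3.5 * se))
})

test_that("PDC columns are normalized and reveal directed structure", {
  # trivariate system where only channel 1 drives channel 2
  set.seed(23)
  n <- 3000
  x <- matrix(0, n, 3)
  e <- matrix(rnorm(3 * n), n, 3)
  for (t in 2:n) {
    x[t, 1] <- 0.5 * x[t - 1, 1] + e[t, 1]
    x[t, 2] <- 0.4 * x[t - 1, 2] + 0.5 * x[t - 1, 1] + e[t, 2]
    x[t, 3] <- 0.3 * x[t - 1, 3] + e[t, 3]
  }
  m <- fit_mar(x, p_max = 5)
  pdc <- mar_pdc(m, seq(0, 1, length.out = 32), fs = 2)
  norms <- apply(pdc, c(1, 3), function(v) sum(v^2))
  expect_true(all(abs(norms - 1) < 1e-6))
  expect_gt(mean(pdc[, 2, 1]), 0.3)    # 1 -> 2 strong
  expect_lt(mean(pdc[, 1, 2]), 0.1)    # 2 -> 1 absent
})

test_that("a single full-length window reproduces the static PDC", {
  set.seed(24)
  sim <- sim_ar2(1200, seed = 24)
  field <- tvpdc(sim$x, window_len = 1200L, window_shift = 600L,
                 p_max = 6, n_freq = 16)
  m <- fit_mar(sim$x, p_max = 6)
  static <- mar_pdc(m, field$freqs, fs = 2)
  expect_equal(dim(field$pdc)[1], 1L)
  expect_equal(field$pdc[1, , , ], static, tolerance = 1e-12)
})

test_that("NF quantization reproduces every branch", {
  nf <- function(a, b) as.integer(nf_quantize(a, b))
  expect_identical(nf(0.6, 0.1), 2L)    # ratio 6
  expect_identical(nf(0.3, 0.1), 1L)    # ratio 3
  expect_identical(nf(0.5, 0.1), 1L)    # ratio exactly 5: boundary -> 1
  expect_identical(nf(0.2, 0.1), 0L)    # ratio 2: boundary -> 0
  expect_identical(nf(0.1, 0.3), -1L)   # backward dominant, ratio 3
  expect_identical(nf(0.1, 0.6), -2L)
  z <- nf_quantize(0, 0)
  expect_identical(as.integer(z), 0L)
  expect_identical(attr(z, "flag"), "no coupling")
  e <- nf_quantize(0.4, 0.4)
  expect_identical(as.integer(e), 0L)
  expect_identical(attr(e, "flag"), "equal influence")
  expect_identical(nf(0.4, 0), 2L)      # ratio +Inf
})

test_that("coupling_summary orients forward and backward correctly", {
  # hand-built field: constant pdc with strong 2<-1 flow
  pdc <- array(0, c(2, 4, 3, 3))
  pdc[, , 2, 1] <- 0.6   # target 2, source 1
  pdc[, , 1, 2] <- 0.1
  field <- structure(list(pdc = pdc, freqs = seq(0, 1, length.out = 4),
                          windows = c(1, 300), skipped = integer(0),
                          fs = 2), class = "tvpdc_field")
  cs <- coupling_summary(field, 1, 2)
  expect_equal(cs$a_bar, 0.6)
  expect_equal(cs$b_bar, 0.1)
  expect_identical(cs$nf, 2L)
  expect_equal(cs$area_xy, 0.6)
  rev <- coupling_summary(field, 2, 1)
  expect_identical(rev$nf, -2L)
})

test_that("NF direction follows a dominant baroreflex arm and flips", {
  brs_prof <- group_profile(mu_bbi = 900, sd_bbi = 60, mu_sbp = 120,
                            sd_sbp = 4, ar_bbi = 0.4, ar_sbp = 0.65,
                            gain_baroreflex = 6, gain_mechanical = 0,
                            dia_link = 0.3, resp_amp = 1, ectopic_rate = 0)
  nf_sign <- vapply(1:6, function(sd) {
    f <- nstpdc_features(generate_subject(brs_prof, 1500, seed = sd))
    unname(f["NSTPDCcs_NF"])
  }, numeric(1))
  expect_true(all(nf_sign < 0))   # SBP is the driver
  # reversed gains: the cardiac arm dominates; the directional asymmetry
  # flips (forward area above backward) and NF is never negative
  mech_prof <- group_profile(mu_bbi = 900, sd_bbi = 30, mu_sbp = 120,
                             sd_sbp = 8, ar_bbi = 0.3, ar_sbp = 0.4,
                             gain_baroreflex = 0, gain_mechanical = 0.10,
                             dia_link = 0.3, resp_amp = 1, ectopic_rate = 0)
  res <- vapply(1:6, function(sd) {
    f <- nstpdc_features(generate_subject(mech_prof, 1500, seed = sd))
    c(unname(f["NSTPDCcs_NF"]),
      unname(f["NSTPDCcs_Area_c-s"] - f["NSTPDCcs_Area_s-c"]))
  }, numeric(2))
  expect_true(all(res[1, ] >= 0))
  expect_true(all(res[2, ] > 0))
})

test_that("areas are bounded and window errors are handled", {
  set.seed(26)
  sim <- sim_ar2(700, seed = 26)
  field <- tvpdc(sim$x, window_len = 300L, window_shift = 200L, p_max = 4,
                 n_freq = 8)
  expect_true(all(field$pdc >= 0 & field$pdc <= 1, na.rm = TRUE))
  expect_error(tvpdc(sim$x[1:100, ], window_len = 300L), "shorter")
  expect_error(tvpdc(sim$x, window_len = 300L, window_shift = 0L),
               "window_shift")
})
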