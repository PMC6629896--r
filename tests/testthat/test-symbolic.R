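test_that("ternary symbolization follows the threshold rule", {
  s <- symbolize(c(800, 810, 807, 797), mode = "ternary", threshold = 5)
  expect_identical(s$symbols, c(2L, 1L, 0L))
  expect_identical(symbolize(rep(5, 10), "ternary", 0)$symbols,
                   rep(1L, 9L))
  expect_identical(symbolize(rep(5, 10), "binary")$symbols, rep(0L, 9L))
  expect_error(symbolize(1, "ternary", 5), "at least two")
  expect_error(symbolize(c(1, 2), "ternary", -1), "non-negative")
})

test_that("binary symbols equal the sign-indicator oracle", {
  set.seed(2)
  x <- cumsum(rnorm(200))
  s <- symbolize(x, "binary")
  oracle <- as.integer(vapply(seq_len(199),
                              function(i) x[i + 1] - x[i] > 0, logical(1)))
  expect_identical(s$symbols, oracle)
})

test_that("equilibrium symbol count is monotone in the threshold", {
  set.seed(5)
  x <- 800 + cumsum(rnorm(300, 0, 6))
  counts <- vapply(c(0, 1, 2, 5, 10, 20), function(l)
    sum(symbolize(x, "ternary", l)$symbols == 1L), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("joint word matrices have the right combinatorial structure", {
  set.seed(3)
  x <- rnorm(100); y <- rnorm(100)
  mt <- joint_word_distribution(symbolize(x, "ternary", 0.5),
                                symbolize(y, "ternary", 0.5))
  expect_identical(dim(mt$probs), c(27L, 27L))
  expect_identical(length(mt$probs), 729L)
  expect_equal(sum(mt$probs), 1, tolerance = 1e-12)
  expect_equal(sum(mt$counts), 99 - 3 + 1)   # overlapping words, stride 1
  mb <- joint_word_distribution(symbolize(x, "binary"),
                                symbolize(y, "binary"))
  expect_identical(dim(mb$probs), c(8L, 8L))
  # single-word case: all mass in one cell
  s <- symbolize(c(1, 2, 3, 4), "binary")
  m1 <- joint_word_distribution(s, s)
  expect_equal(sum(m1$counts), 1)
  expect_equal(m1$probs["111", "111"], 1)
  expect_error(joint_word_distribution(symbolize(x, "binary"),
                                       symbolize(y, "ternary", 1)),
               "alphabet")
})

test_that("swapping the sequences transposes both matrices", {
  set.seed(9)
  s1 <- symbolize(rnorm(80), "ternary", 0.3)
  s2 <- symbolize(rnorm(80), "ternary", 0.3)
  m12 <- joint_word_distribution(s1, s2)
  m21 <- joint_word_distribution(s2, s1)
  expect_identical(m12$counts, t(m21$counts))
  f12 <- family_distribution(m12)
  f21 <- family_distribution(m21)
  expect_equal(f12$probs, t(f21$probs))
})

test_that("the eight families partition the 27 ternary words", {
  words <- apply(expand.grid(0:2, 0:2, 0:2), 1, paste0, collapse = "")
  fams <- vapply(words, family_of, character(1))
  expect_length(words, 27)
  expect_identical(sort(unique(unname(fams))), sort(family_levels()))
  sizes <- table(factor(fams, levels = family_levels()))
  expect_identical(as.integer(sizes), c(1L, 1L, 1L, 8L, 8L, 2L, 3L, 3L))
  expect_identical(family_of("000"), "E0")
  expect_identical(family_of("202"), "LA1")
  expect_identical(family_of("120"), "P")
  expect_identical(family_of("012"), "V")
  expect_error(family_of("03"), "not a ternary")
})

test_that("family grouping matches a brute-force regroup oracle", {
  set.seed(4)
  s1 <- symbolize(cumsum(rnorm(300)), "ternary", 0.5)
  s2 <- symbolize(cumsum(rnorm(300)), "ternary", 0.5)
  m <- joint_word_distribution(s1, s2)
  fm <- family_distribution(m)
  # oracle: loop over all 27 x 27 word pairs, accumulate per family pair
  oracle <- matrix(0, 8, 8, dimnames = list(family_levels(),
                                            family_levels()))
  for (w1 in rownames(m$probs))
    for (w2 in colnames(m$probs))
      oracle[family_of(w1), family_of(w2)] <-
        oracle[family_of(w1), family_of(w2)] + m$probs[w1, w2]
  expect_equal(fm$probs, oracle, tolerance = 1e-12)
  expect_equal(unname(fm$marginals_ch1), unname(rowSums(oracle)),
               tolerance = 1e-12)
  expect_equal(sum(fm$probs), 1, tolerance = 1e-12)
})

test_that("family entropy behaves on point-mass and uniform inputs", {
  pm <- matrix(0, 27, 27, dimnames = list(names(hrjsd_families()),
                                          names(hrjsd_families())))
  pm["000", "111"] <- 1
  m <- structure(list(counts = pm, probs = pm, word_length = 3L,
                      alphabet_size = 3L), class = "joint_word_matrix")
  fm <- family_distribution(m)
  expect_equal(fm$probs["E0", "E1"], 1)
  expect_equal(fm$entropy, 0)
  # uniform over the 64 family cells: entropy log2(64) = 6 bits
  u <- matrix(0, 27, 27, dimnames = dimnames(pm))
  fam <- vapply(rownames(u), family_of, character(1))
  sizes <- table(fam)[fam]
  for (i in 1:27) for (j in 1:27)
    u[i, j] <- (1 / 64) / (as.numeric(sizes[i]) * as.numeric(sizes[j]))
  mu <- structure(list(counts = u, probs = u, word_length = 3L,
                       alphabet_size = 3L), class = "joint_word_matrix")
  expect_equal(family_distribution(mu)$entropy, 6, tolerance = 1e-12)
})

test_that("hrjsd feature vector has 81 named entries that sum coherently", {
  set.seed(6)
  x <- 800 + cumsum(rnorm(400, 0, 8))
  y <- 120 + cumsum(rnorm(400, 0, 1.5))
  fv <- hrjsd_features(x, y, "cs", 5, 1)
  expect_length(fv, 81)
  expect_true("HRJSDShcs" %in% names(fv))
  expect_equal(sum(fv[grepl("^HRJSDcs_", names(fv))]), 1, tolerance = 1e-9)
  expect_equal(sum(fv[grepl("-E0c$|-E1c$|-E2c$|-LU1c$|-LD1c$|-LA1c$|-Pc$|-Vc$",
                            names(fv))]), 1, tolerance = 1e-9)
  jv <- jsd_features(x, y, "cs")
  expect_length(jv, 65)
  expect_equal(sum(jv[grepl("^JSDcs_", names(jv))]), 1, tolerance = 1e-9)
})
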