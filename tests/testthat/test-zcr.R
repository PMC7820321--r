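test_that("mean amplitude follows the abs and signed conventions", {
  expect_equal(mean_amplitude(c(1, 1, 1, 1)), 1)
  expect_equal(mean_amplitude(c(-2, 2, -2, 2)), 2)
  expect_equal(mean_amplitude(c(-2, 2, -2, 2), mode = "signed"), 0)
  x <- withr::with_seed(7, rnorm(500))
  expect_equal(mean_amplitude(x), sum(abs(x)) / 500)
  expect_error(mean_amplitude(numeric(0)), "non-empty")
})

test_that("elevation shifts by a constant alpha * E", {
  expect_equal(elevate(c(1, -1), alpha = 0, E = 10), c(1, -1))
  expect_equal(elevate(c(1, -1), alpha = 1, E = 1), c(2, 0))
  x <- withr::with_seed(8, rnorm(100))
  expect_equal(elevate(x, 2.5, 3), x + 7.5)
})

test_that("sign-change counting treats exact zeros as transparent", {
  expect_equal(count_sign_changes(c(1, -1, 1, -1)), 3)
  expect_equal(count_sign_changes(c(1, 0, -1)), 1)
  expect_equal(count_sign_changes(c(1, 0, 1)), 0)
  expect_equal(count_sign_changes(c(0, 0, 1, -1)), 1)
  expect_equal(count_sign_changes(c(0, 0)), 0)
  expect_equal(count_sign_changes(c(-1, 0, 0, 1, 0, -1)), 2)
  expect_error(count_sign_changes(5), "length >= 2")

  # brute-force oracle on seeded windows containing exact zeros
  withr::with_seed(21, {
    for (rep in 1:20) {
      w <- sample(c(-2, -1, 0, 1, 2), 40, replace = TRUE)
      expect_equal(count_sign_changes(w), oracle_sign_changes(w))
    }
  })
})

test_that("sliding ZCR implements Z = m/W x 100 with centred windows", {
  # alternating-sign window: m = 3 crossings over W = 4 points
  expect_equal(sliding_zcr(c(1, -1, 1, -1), fs = 1, window_s = 4),
               rep(75, 4))
  expect_equal(sliding_zcr(rep(1, 50), fs = 10, window_s = 2), rep(0, 50))
  expect_error(sliding_zcr(rnorm(10), fs = 10, window_s = 40), "shorter")
})

test_that("fast sliding ZCR equals the per-window brute-force recount", {
  x <- withr::with_seed(31, rnorm(2000))
  fs <- 10
  w <- 80  # window_s = 8
  z <- sliding_zcr(x, fs, window_s = 8)
  expect_true(all(z >= 0 & z <= 100))
  positions <- withr::with_seed(32, sample(2000, 40))
  for (t in positions)
    expect_equal(z[t], oracle_zcr_at(x, t, w))
})

test_that("elevation above the noise amplitude silences the sliding ZCR", {
  x <- withr::with_seed(41, runif(500, -0.4, 0.4))
  E <- 1
  elevated <- elevate(x, alpha = 1, E = E)  # everywhere > 0.6
  expect_equal(sliding_zcr(elevated, fs = 10, window_s = 5), rep(0, 500))
})

test_that("unit normalisation maps to [0, 1] with the degenerate-constant rule", {
  expect_equal(normalize_unit(c(0, 50, 100)), c(0, 0.5, 1))
  expect_equal(normalize_unit(rep(7, 10)), rep(0, 10))
  withr::with_seed(51, {
    for (rep in 1:10) {
      z <- rnorm(100, sd = 10)
      out <- normalize_unit(z)
      expect_equal(min(out), 0)
      expect_equal(max(out), 1)
    }
  })
})

test_that("power weighting attenuates, preserves order, and fixes 0 and 1", {
  expect_equal(zcr_power(c(0, 1), gamma = 5), c(0, 1))
  expect_equal(zcr_power(0.5, gamma = 3), 0.125)
  z <- withr::with_seed(61, runif(200))
  p3 <- zcr_power(z, 3)
  p4 <- zcr_power(z, 4)
  expect_true(all(p3 <= z))
  expect_true(all(p4 <= p3))
  interior <- z > 0 & z < 1
  expect_true(all(p4[interior] < p3[interior]))
  # order preservation
  o <- order(z)
  expect_equal(order(p3), o)
  expect_error(zcr_power(c(0.5, 1.2), 3), "\\[0, 1\\]")
  expect_error(zcr_power(c(0.5), 1), "gamma")
})

test_that("modulation is the pointwise product and shrinks under unit weights", {
  x <- withr::with_seed(71, rnorm(100))
  expect_equal(modulate(x, rep(1, 100)), x)
  expect_equal(modulate(x, rep(0, 100)), rep(0, 100))
  w <- withr::with_seed(72, runif(100))
  out <- modulate(x, w)
  expect_true(all(abs(out) <= abs(x)))
  expect_true(all(sign(out[w > 0]) == sign(x[w > 0])))
  expect_error(modulate(x, w[-1]), "lengths differ")
})

test_that("zcr_modulate composes the stages exactly", {
  fs <- 10
  x <- withr::with_seed(81, {
    base <- rnorm(1200, sd = 0.1)
    burst <- exp(-((seq_len(1200) / fs - 60)^2) / (2 * 6^2)) *
      sin(2 * pi * 0.8 * seq_len(1200) / fs)
    base + 5 * burst
  })
  cfg <- zcr_config(alpha = 1.5, gamma = 3.5, window_s = 8)
  out <- zcr_modulate(x, fs, cfg)

  E <- mean(abs(x))
  z <- sliding_zcr(x + 1.5 * E, fs, 8)
  expected <- x * (normalize_unit(z))^3.5
  expect_equal(out, expected)

  # weight is concentrated on the burst: quiet-region output is ~0
  quiet <- c(1:200, 1000:1200)
  expect_lt(max(abs(out[quiet])), 0.05 * max(abs(out)))
})
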