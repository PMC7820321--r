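test_that("matching applies the tolerance window inclusively and one-to-one", {
  m <- match_events(100, 119, tol_s = 20)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))

  m <- match_events(100, 121, tol_s = 20)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 1, 1))

  m <- match_events(100, 120, tol_s = 20)  # inclusive boundary
  expect_equal(m$tp, 1)

  # a single label cannot validate two detections
  m <- match_events(c(95, 105), 100, tol_s = 20)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 0))
})

test_that("greedy tie-break prefers the earlier peak", {
  m <- match_events(c(90, 110), 100, tol_s = 20)
  expect_equal(m$pairs$peak_s, 90)
  m2 <- match_events(c(104, 96), 100, tol_s = 20)
  expect_equal(m2$pairs$peak_s, 96)
})

test_that("matching counts are conserved and shift-invariant", {
  withr::with_seed(123, {
    for (rep in 1:10) {
      peaks <- sort(runif(sample(0:6, 1), 0, 600))
      labels <- sort(runif(sample(0:6, 1), 0, 600))
      m <- match_events(peaks, labels, tol_s = 25)
      expect_equal(m$tp + m$fp, length(peaks))
      expect_equal(m$tp + m$fn, length(labels))
      shifted <- match_events(peaks + 1000, labels + 1000, tol_s = 25)
      expect_equal(shifted$tp, m$tp)
    }
  })
})

test_that("greedy matching attains the maximum on well-separated event sets", {
  # when events within each list are more than 2 * tol apart (the clinical
  # regime: contraction peaks are minutes apart, tol = 20 s), every peak
  # conflicts with at most one label, so the greedy pairing provably equals
  # the maximum-cardinality matching; verified against exhaustive search
  withr::with_seed(456, {
    for (rep in 1:10) {
      n_p <- sample(2:6, 1)
      n_l <- sample(2:6, 1)
      peaks <- cumsum(runif(n_p, 70, 200))
      labels <- cumsum(runif(n_l, 70, 200)) + runif(1, -40, 40)
      m <- match_events(peaks, labels, tol_s = 30)
      expect_equal(m$tp, oracle_max_matching(peaks, labels, 30))
    }
  })
})

test_that("greedy matching is bounded by the maximum matching on dense sets", {
  # on dense instances greedy-by-smallest-gap is a 2-approximation of the
  # maximum-cardinality matching, never more than it
  withr::with_seed(457, {
    for (rep in 1:10) {
      peaks <- sort(round(runif(sample(2:6, 1), 0, 200), 3))
      labels <- sort(round(runif(sample(2:6, 1), 0, 200), 3))
      m <- match_events(peaks, labels, tol_s = 30)
      best <- oracle_max_matching(peaks, labels, 30)
      expect_lte(m$tp, best)
      expect_gte(2 * m$tp, best)
    }
  })
})

test_that("zero tolerance edge: only exact coincidences count", {
  m <- match_events(c(10, 20, 30), c(20, 40), tol_s = 1e-12)
  expect_equal(m$tp, 1)
})

test_that("sensitivity and PPV reproduce the clinical benchmark counts", {
  ehg <- sensitivity_ppv(tp = 396, fp = 29, fn = 55)
  expect_equal(round(100 * ehg$sensitivity, 2), 87.80)
  expect_equal(round(100 * ehg$ppv, 2), 93.18)

  toco <- sensitivity_ppv(tp = 379, fp = 38, fn = 72)
  expect_equal(round(100 * toco$sensitivity, 2), 84.04)
  expect_equal(round(100 * toco$ppv, 2), 90.89)

  perfect <- sensitivity_ppv(10, 0, 0)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$ppv, 1)

  degenerate <- sensitivity_ppv(0, 0, 0)
  expect_equal(degenerate$sensitivity, 0)
  expect_setequal(degenerate$undefined, c("sensitivity", "ppv"))

  g <- glance(ehg)
  expect_equal(g$score, (ehg$sensitivity + ehg$ppv) / 2)
  expect_equal(nrow(tidy(ehg)), 2)
})

test_that("clinical parameters summarise counts, frequency and intervals", {
  events <- tibble::tibble(
    source = "EHG", onset_s = c(80, 280, 480), peak_s = c(100, 300, 500),
    end_s = c(130, 330, 530), peak_amplitude = 1, duration_s = c(40, 45, 50))
  p <- uc_parameters(events, recording_len_s = 1800)
  expect_equal(p$count, 3)
  expect_equal(p$freq_per_10min, 1)
  expect_equal(p$intervals_s, c(200, 200))
  expect_equal(p$mean_interval_s, 200)
  expect_equal(p$mean_duration_s, 45)

  empty <- uc_parameters(events[0, ], 1800)
  expect_equal(empty$count, 0)
  expect_equal(empty$freq_per_10min, 0)
  expect_equal(length(empty$intervals_s), 0)

  single <- uc_parameters(events[1, ], 1800)
  expect_equal(single$count, 1)
  expect_equal(length(single$intervals_s), 0)
  expect_true(is.na(single$sd_duration_s))

  expect_error(uc_parameters(events, 0), "positive")
  expect_equal(tidy(p)$count, 3)
})

test_that("parameter comparison delegates to the rank-sum test", {
  a <- uc_parameters(tibble::tibble(
    source = "EHG", onset_s = 1:5 * 100, peak_s = 1:5 * 100 + 20,
    end_s = 1:5 * 100 + 50, peak_amplitude = 1,
    duration_s = c(30, 35, 40, 45, 50)), 1800)
  b <- uc_parameters(tibble::tibble(
    source = "TOCO", onset_s = 1:5 * 100, peak_s = 1:5 * 100 + 25,
    end_s = 1:5 * 100 + 50, peak_amplitude = 1,
    duration_s = c(32, 36, 41, 44, 52)), 1800)
  cmp <- compare_uc_parameters(a, b)
  expect_equal(cmp$parameter, c("duration_s", "interval_s"))
  ref <- stats::wilcox.test(a$durations_s, b$durations_s, exact = FALSE)
  expect_equal(cmp$p_value[1], ref$p.value)
})

test_that("a one-point sweep equals a direct evaluation and scores correctly", {
  fx <- simulate_recording(sim_config(seed = 13, n_ucs = 4, fs = 50,
                                      duration_s = 900))
  fixtures <- list(list(recording = fx$recording,
                        annotations = fx$annotations))
  sw <- sweep_parameter(fixtures, "alpha", grid = 1.5)
  expect_equal(nrow(sw), 1)

  det <- detect_contractions(fx$recording, keep_signals = FALSE)
  direct <- evaluate_detection(det, fx$annotations)
  expect_equal(sw$tp, direct$tp)
  expect_equal(sw$fp, direct$fp)
  expect_equal(sw$fn, direct$fn)
  expect_equal(sw$sensitivity, direct$sensitivity)
  expect_equal(sw$score, (sw$sensitivity + sw$ppv) / 2)

  sw2 <- sweep_parameter(fixtures, "gamma", grid = c(2, 3.5))
  expect_equal(sw2$score, (sw2$sensitivity + sw2$ppv) / 2)
  expect_s3_class(autoplot(sw2), "ggplot")
})
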