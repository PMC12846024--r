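fs <- 1000

test_that("filter magnitude responses match the transfer-function oracle at 0, 5, 50 Hz", {
  cfg <- filter_config()
  flt <- design_filters(cfg, fs)
  steady_gain <- function(b, a, f) {
    # measure steady-state amplitude of a filtered sinusoid, last 2 s of 10 s
    t <- seq(0, 10, by = 1 / fs)
    y <- as.numeric(signal::filter(b, a, sin(2 * pi * f * t)))
    max(abs(y[t > 8]))
  }
  with(flt$highpass, {
    # DC: a constant decays below 1% within a bounded settling time
    y <- as.numeric(signal::filter(b, a, rep(1, 5 * fs)))
    expect_lt(max(abs(y[(2 * fs):(5 * fs)])), 0.01)
    # independent oracle: |H| evaluated from the coefficients
    expect_equal(steady_gain(b, a, 5),
                 filter_response_magnitude(b, a, 5, fs), tolerance = 1e-3)
    expect_lt(abs(filter_response_magnitude(b, a, 0, fs)), 1e-12)
  })
  with(flt$notch, {
    h50 <- filter_response_magnitude(b, a, 50, fs)
    expect_lt(h50, 1e-10)  # zeros on the unit circle at the center
    y <- as.numeric(signal::filter(b, a, sin(2 * pi * 50 * seq(0, 20, by = 1 / fs))))
    expect_lt(max(abs(tail(y, 2 * fs))), 0.01)
    expect_equal(steady_gain(b, a, 5),
                 filter_response_magnitude(b, a, 5, fs), tolerance = 1e-3)
  })
  # a 5 Hz sinusoid passes the whole cascade within 5% of unit amplitude
  x <- matrix(sin(2 * pi * 5 * seq(0, 10, by = 1 / fs)), ncol = 1)
  y <- apply_digital_filters(x, cfg, fs)
  expect_equal(max(abs(y[(8 * fs):(10 * fs), 1])), 1, tolerance = 0.05)
})

test_that("filtering rejects non-finite input and preserves length", {
  x <- matrix(rnorm(2000), ncol = 2)
  y <- apply_digital_filters(x, filter_config(), fs)
  expect_equal(dim(y), dim(x))
  x[5, 1] <- NA
  expect_error(apply_digital_filters(x, filter_config(), fs), "non-finite")
})

test_that("block-average downsampling matches the loop oracle exactly", {
  expect_equal(downsample_signal(rep(3.7, 100), 10), rep(3.7, 10))
  expect_equal(downsample_signal(1:10, 10), 5.5)
  expect_length(downsample_signal(rnorm(1000), 10), 100)
  withr::with_seed(2, {
    x <- rnorm(1037)  # trailing partial block is truncated
    got <- downsample_signal(x, 10)
    oracle <- vapply(seq_len(103), function(i) {
      s <- 0
      for (j in 1:10) s <- s + x[(i - 1) * 10 + j]
      s / 10
    }, numeric(1))
    expect_identical(length(got), 103L)
    expect_equal(got, oracle, tolerance = 1e-15)
  })
  expect_error(downsample_signal(1:10, 0), "block")
})

test_that("thresholds follow mean + k*sd of |rest| per channel with a positive floor", {
  cfg <- filter_config()
  withr::with_seed(4, {
    rest <- cbind(rnorm(500, 0, 0.05), rnorm(500, 0, 0.2))
    thr <- estimate_thresholds(rest, cfg, fs = 100)
    # brute-force re-evaluation of the same formula
    for (ch in 1:2) {
      a <- abs(rest[, ch])
      expect_equal(thr$theta[ch], mean(a) + 5 * sd(a), tolerance = 1e-12)
    }
    expect_true(thr$theta[1] != thr$theta[2])
    # each channel depends only on itself
    thr2 <- estimate_thresholds(cbind(rest[, 1], rnorm(500, 0, 3)), cfg, 100)
    expect_equal(thr2$theta[1], thr$theta[1])
  })
  z <- estimate_thresholds(matrix(0, 400, 2), cfg, fs = 100)
  expect_equal(z$theta, rep(cfg$threshold_floor, 2))
  expect_error(estimate_thresholds(matrix(0, 100, 2), cfg, fs = 100),
               "too short")
})

test_that("onset detection matches a linear-scan first-crossing oracle with refractory", {
  theta <- c(0.5, 0.4)
  x <- matrix(0, 300, 2)
  expect_equal(nrow(detect_onsets(x, theta)), 0)

  # single step on channel 2 at index 57
  x2 <- x; x2[57:70, 2] <- 2 * theta[2]
  ev <- detect_onsets(x2, theta, refractory = 1, fs = 100)
  expect_equal(ev$nd, 57)
  expect_equal(ev$channel, 2)

  # both channels cross (ch1 at 40, ch2 at 45): one event at the first
  x3 <- x; x3[40:60, 1] <- 1; x3[45:65, 2] <- 1
  ev3 <- detect_onsets(x3, theta, refractory = 1, fs = 100)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$nd, 40)
  expect_equal(ev3$channel, 1)

  # random signals against an independent scan oracle
  withr::with_seed(9, {
    for (rep_i in 1:20) {
      xr <- matrix(rnorm(600, 0, 0.3), ncol = 2)
      got <- detect_onsets(xr, theta, refractory = 0.2, fs = 100)$nd
      want <- integer(0); last <- -1e9
      for (i in seq_len(300)) {
        if ((abs(xr[i, 1]) > theta[1] || abs(xr[i, 2]) > theta[2]) &&
            i - last > 20) {
          want <- c(want, i); last <- i
        }
      }
      expect_equal(got, want[want >= 11 & want <= 291])
    }
  })
})

test_that("feature extraction concatenates 20 samples per channel, channel 1 first", {
  x <- cbind(rep(1, 100), rep(-1, 100))
  z <- extract_feature(x, 50)
  expect_length(z, 40)
  expect_equal(z, c(rep(1, 20), rep(-1, 20)))
  # the slice is [nd-10, nd+9] inclusive
  x2 <- cbind(seq_len(100), -seq_len(100))
  expect_equal(extract_feature(x2, 50)[1:20], 40:59)
  expect_error(extract_feature(x, 10), "out of bounds")
  expect_error(extract_feature(x, 92), "out of bounds")
})

test_that("the pipeline is deterministic and detects nearly all annotated trials", {
  rec <- generate_session(small_spec(trials = 10, seed = 21))
  f1 <- extract_trial_features(rec)
  f2 <- extract_trial_features(rec)
  expect_identical(f1, f2)
  expect_equal(ncol(feature_matrix(f1)), 40)
  # >= 95% of trials detected within +/-100 ms of the true onset
  m <- merge(f1, rec$annotations[, c("trial_id", "onset_s")], by = "trial_id")
  hit <- abs(m$t_detect_s - m$onset_s) <= 0.1
  expect_gte(sum(hit) / nrow(rec$annotations), 0.95)
})

test_that("one shared detection rule serves every motion category", {
  # relabeling a trial's category must not change its detected feature:
  # detection and extraction read only the signal, never the annotation class
  rec <- generate_session(small_spec(trials = 4, seed = 13))
  f1 <- extract_trial_features(rec)
  rec2 <- rec
  rec2$annotations$category <- withr::with_seed(1,
    sample(c("target", "unknown", "nontarget"),
           nrow(rec2$annotations), replace = TRUE))
  f2 <- extract_trial_features(rec2)
  expect_equal(feature_matrix(f1), feature_matrix(f2))
  expect_equal(f1$t_detect_s, f2$t_detect_s)
  expect_setequal(unique(f1$category), c("target", "unknown", "nontarget"))
})
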