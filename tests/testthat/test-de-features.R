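test_that("segmentation reproduces the trial and counts windows correctly", {
  fs <- 128
  sig <- matrix(rnorm(2 * 8064), nrow = 2)
  seg <- segment_trial(sig, fs, window_seconds = 1, baseline_seconds = 3)
  expect_length(seg$baseline, 3)
  expect_length(seg$stimulus, 60)
  expect_true(all(vapply(seg$stimulus, ncol, 0L) == 128))
  expect_equal(do.call(cbind, c(seg$baseline, seg$stimulus)), sig)

  tiny <- segment_trial(matrix(rnorm(256), 1), fs, 1, baseline_seconds = 1)
  expect_length(tiny$baseline, 1)
  expect_length(tiny$stimulus, 1)

  expect_error(segment_trial(matrix(rnorm(250), 1), fs, 1, 1), "divide")
  expect_error(segment_trial(matrix(rnorm(256), 1), fs, 2, 2), "stimulus")
})

test_that("differential entropy matches its Gaussian closed form", {
  # sigma^2 = 1/(2*pi*e) makes the entropy exactly zero
  x <- c(-1, 1) * sqrt(1 / (2 * pi * exp(1)))
  expect_equal(compute_de(x), 0, tolerance = 1e-12)
  # unit variance: 0.5 * (1 + log(2*pi))
  x1 <- c(-1, 1)
  expect_equal(compute_de(x1), 0.5 * log(2 * pi * exp(1)), tolerance = 1e-12)
  expect_equal(compute_de(x1), 1.41894, tolerance = 1e-5)
  # base-2 flag rescales by log2(e)
  expect_equal(compute_de(x1, base = 2), compute_de(x1) / log(2), tolerance = 1e-12)
})

test_that("plug-in DE converges to the true Gaussian entropy", {
  set.seed(99)
  x <- rnorm(10000, sd = 2)
  expect_equal(compute_de(x), 0.5 * log(2 * pi * exp(1) * 4), tolerance = 0.01)
})

test_that("DE is translation invariant and shifts by log|a| under scaling", {
  set.seed(3)
  x <- rnorm(128)
  expect_equal(compute_de(x + 17), compute_de(x), tolerance = 1e-10)
  for (a in c(0.5, 2, 7)) {
    expect_equal(compute_de(a * x), compute_de(x) + log(a), tolerance = 1e-10)
  }
  # strict monotonicity in variance
  expect_gt(compute_de(1.01 * x), compute_de(x))
})

test_that("degenerate segments raise identifying errors", {
  expect_error(compute_de(rep(0, 128)), "degenerate")
  expect_error(compute_de(rep(5, 128)), "degenerate")
  expect_error(compute_de(c(1)), "length")
})

test_that("baseline DE is the arithmetic mean over the three windows", {
  expect_equal(baseline_de(c(1, 2, 3)), 2)
  expect_equal(baseline_de(c(1.5, 1.5, 1.5)), 1.5)
  expect_error(baseline_de(c(1, 2)), "expected 3")
  # array input averages the leading (window) dimension only
  arr <- array(rnorm(3 * 4 * 2), dim = c(3, 4, 2))
  out <- baseline_de(arr)
  expect_equal(dim(out), c(4L, 2L))
  expect_equal(out[2, 1], mean(arr[, 2, 1]))
  # agrees with averaging three independent compute_de calls
  set.seed(12)
  wins <- replicate(3, rnorm(128, sd = 1.3), simplify = FALSE)
  des <- vapply(wins, compute_de, 0)
  expect_equal(baseline_de(des), mean(des))
})

test_that("extract_features has DEAP bookkeeping shapes and uses baseline subtraction", {
  feats <- small_features()     # 8 trials x 7 s at 128 Hz -> 4 stimulus windows
  expect_equal(dim(feats$values), c(8, 4, 4, 32))
  expect_true(all(is.finite(feats$values)))
  expect_true(feats$baseline_corrected)
  expect_equal(feats$bands, c("theta", "alpha", "beta", "gamma"))
})

test_that("class-neutral synthesis gives baseline-centred corrected DE", {
  subj <- small_subject(seed = 21, n_trials = 6, trial_seconds = 11,
                        band_class_gains = matrix(1, 4, 2))
  banded <- apply_band_filters(subj$recording)
  feats <- extract_features(banded)
  # no class effect and stimulus ~ baseline: corrected values centred near 0
  expect_lt(abs(mean(feats$values)), 0.05)
})

test_that("doubling stimulus amplitude in one band raises its DE by log 2", {
  # a recording whose content is a pure beta-band carrier (plus a tiny
  # broadband floor), so the beta filter output scales exactly with it
  fs <- 128; ns <- 7 * fs; nb <- 3 * fs
  flt <- design_bandpass(12, 30, fs)
  set.seed(22)
  mk <- function(stim_gain) {
    sig <- array(0, dim = c(2, 3, ns))
    for (tr in 1:2) for (ch in 1:3) {
      set.seed(1000 + 10 * tr + ch)
      carrier <- eegcae:::filter_series(flt, rnorm(ns + 256),
                                        zero_phase = FALSE)[-(1:256)]
      floor_noise <- rnorm(ns, sd = 0.02)
      gain <- if (tr == 2) stim_gain else 1
      carrier[(nb + 1):ns] <- gain * carrier[(nb + 1):ns]
      sig[tr, ch, ] <- carrier + floor_noise
    }
    trial_recording(sig, fs, c("F3", "Fz", "F4"), 3)
  }
  f0 <- extract_features(apply_band_filters(mk(1)))
  f2 <- extract_features(apply_band_filters(mk(2)))
  shift <- f2$values[2, , "beta", ] - f0$values[2, , "beta", ]
  expect_equal(mean(shift), log(2), tolerance = 0.02)
  # the untouched trial is unchanged
  expect_equal(f2$values[1, , , ], f0$values[1, , , ], tolerance = 1e-10)
})
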