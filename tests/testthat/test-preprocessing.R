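# Preprocessing: block-mean downsampling, EMG envelope chain, label
# alignment, feature assembly.

test_that("IMU downsampling is the non-overlapping block mean", {
  expect_equal(downsample_imu(c(1:10, 11:20)), c(5.5, 15.5))
  expect_equal(downsample_imu(rep(3.7, 1000)), rep(3.7, 100))
  # 60 s at 100 Hz -> 600 samples at 10 Hz
  expect_length(downsample_imu(rnorm(6000)), 600)
  # trailing partial block is dropped
  expect_length(downsample_imu(rnorm(105)), 10)
  expect_error(downsample_imu(numeric(0)), "too short")
})

test_that("EMG envelope recovers the rectified-sine mean of a pure tone", {
  fs <- 1000
  t <- seq(0, 30, by = 1 / fs)
  A <- 1.7
  x <- A * sin(2 * pi * 50 * t)
  env <- emg_envelope(x)
  steady <- env[50:250]    # steady-state, away from edges
  expect_lt(max(abs(steady - 2 * A / pi)) / (2 * A / pi), 0.05)
})

test_that("EMG envelope chain: rates, nonnegativity, degenerate input, length guard", {
  expect_equal(emg_envelope(rep(0, 10000)), rep(0, 100))
  expect_length(emg_envelope(rnorm(10000)), 100)
  expect_true(all(emg_envelope(rnorm(20000)) >= 0))
  expect_error(emg_envelope(rnorm(100)), "at least")
})

test_that("envelope filtering is zero-phase: time reversal commutes", {
  # taper the record ends so edge transients (which are not part of the
  # zero-phase property) stay small, then compare interior samples
  n <- 20000
  withr::with_seed(8, x <- rnorm(n))
  ramp <- 0.5 * (1 - cos(pi * seq_len(2000) / 2000))
  x[1:2000] <- x[1:2000] * ramp
  x[(n - 1999):n] <- x[(n - 1999):n] * rev(ramp)
  hp <- signal::butter(4, 20 / 500, type = "high")
  lp <- signal::butter(4, 2 / 500, type = "low")
  chain <- function(v) {
    w <- signal::filtfilt(hp, v)
    signal::filtfilt(lp, abs(w - mean(w)))
  }
  full1 <- chain(x)
  full2 <- rev(chain(rev(x)))
  core <- 3000:17000
  expect_lt(max(abs(full1[core] - full2[core])) /
              max(abs(full1[core])), 1e-6)
})

test_that("envelope low-pass attenuates content above 2 Hz by at least 20 dB", {
  withr::with_seed(9, x <- rnorm(60000))
  lp <- signal::butter(4, 2 / 500, type = "low")
  y <- signal::filtfilt(lp, x)
  spec <- Mod(stats::fft(y))^2
  freqs <- (seq_along(y) - 1) * 1000 / length(y)
  pass <- freqs > 0.1 & freqs < 1.5
  stopband <- freqs > 4 & freqs < 10
  atten_db <- 10 * log10(mean(spec[pass]) / mean(spec[stopband]))
  expect_gt(atten_db, 20)
})

test_that("EMG normalization divides by the reference and rejects bad references", {
  expect_equal(normalize_emg(c(4, 2, 0), 2), c(2, 1, 0))
  expect_equal(normalize_emg(rep(1.5, 10), 1.5), rep(1, 10))
  expect_error(normalize_emg(1:3, 0), "positive")
  expect_error(normalize_emg(1:3, -1), "positive")
})

test_that("labels follow the half-open interval convention at 10 Hz", {
  one <- tibble::tibble(start_s = 0, end_s = 8, class = factor("Stat", levels = activity_classes()$code))
  expect_equal(as.character(labels_at_10hz(one, 80)), rep("Stat", 80))

  two <- tibble::tibble(start_s = c(0, 1), end_s = c(1, 2),
                        class = factor(c("WRL", "Stat"), levels = activity_classes()$code))
  lab <- labels_at_10hz(two, 20)
  expect_equal(as.character(lab), c(rep("WRL", 10), rep("Stat", 10)))

  expect_error(labels_at_10hz(two, 21), "shorter")
  gap <- tibble::tibble(start_s = c(0, 1.5), end_s = c(1, 2.5),
                        class = factor(c("WRL", "Stat"), levels = activity_classes()$code))
  expect_error(labels_at_10hz(gap, 10), "gaps")
})

test_that("feature assembly yields the documented channel sets at 10 Hz", {
  co <- tiny_cohort()
  cfg <- attr(co, "config")
  rec <- co$recording[[1]]
  ann <- co$annotations[[1]]

  f1 <- tiny_features(1)[[1]]
  expect_equal(ncol(f1) - 2, 32)
  expect_equal(names(f1)[1:2], c("time_s", "label"))
  expect_equal(nrow(f1), floor(rec$duration_s * 10))
  expect_false(anyNA(f1))

  f4 <- assemble_features(rec, ann, sensor_combination(4), cfg)
  expect_equal(setdiff(names(f4), c("time_s", "label")),
               grep("^FA_", sladl:::imu_channels(), value = TRUE))

  # per-class sample counts match interval durations within 1 sample each
  counts <- table(f1$label)
  expected <- tapply(ann$end_s - ann$start_s, ann$class, sum) * 10
  expect_true(all(abs(counts - expected) <= nrow(ann)))

  # a recording without EMG cannot serve an EMG-requesting combination
  rec_no_emg <- rec
  rec_no_emg$emg <- rec_no_emg$emg["time_s"]
  expect_error(assemble_features(rec_no_emg, ann, sensor_combination(1), cfg),
               "no EMG")
  f2 <- assemble_features(rec_no_emg, ann, sensor_combination(2), cfg)
  expect_equal(ncol(f2) - 2, 30)
})

test_that("enabling EMG normalization rescales envelope channels by the posture reference", {
  co <- tiny_cohort()
  cfg <- attr(co, "config")
  prof <- co$profile[[1]]
  raw <- assemble_features(co$recording[[1]], co$annotations[[1]],
                           sensor_combination(1), cfg, prof)
  cfg$emg$normalize <- TRUE
  norm <- assemble_features(co$recording[[1]], co$annotations[[1]],
                            sensor_combination(1), cfg, prof)
  refs <- static_posture_reference(prof)
  expect_equal(norm$UA_emg_biceps, raw$UA_emg_biceps / refs[["biceps"]])
  expect_equal(norm$UA_emg_deltoid, raw$UA_emg_deltoid / refs[["deltoid"]])
  expect_error(assemble_features(co$recording[[1]], co$annotations[[1]],
                                 sensor_combination(1), cfg, profile = NULL),
               "no profile")
})
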