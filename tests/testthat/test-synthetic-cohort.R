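# Synthetic cohort generator: schedules, per-class signal signatures,
# annotation integrity, determinism, on-disk round trip.

test_that("schedules respect bounds, cover all classes and are seed-deterministic", {
  cfg <- default_config(schedule = list(min_s = 10, max_s = 10))
  s <- make_schedule(cfg, seed = 3)
  expect_equal(sum(s$duration_s), 80)
  expect_setequal(as.character(s$class), activity_classes()$code |> as.character())

  s1 <- make_schedule(default_config(), seed = 7)
  s2 <- make_schedule(default_config(), seed = 7)
  expect_identical(s1, s2)

  expect_error(make_schedule(default_config(schedule = list(min_s = 5, max_s = 4))),
               class = "sladl_config_error")
})

test_that("wheel gyroscope is active only for wheel-motion activities", {
  prof <- default_profile()
  cfg <- default_config()
  noise_floor <- cfg$noise$gyr * cfg$noise$separability

  stat <- synth_activity("Stat", prof, 30, cfg, seed = 21)
  expect_lt(max(abs(stat$imu$WCW_gyr_z)), 6 * noise_floor)

  drib <- synth_activity("Dribbling", prof, 20, cfg, seed = 22)
  w <- drib$imu$WCW_gyr_z
  expect_gt(max(abs(w)), 10 * noise_floor)
  # wheel back at standstill at the end of the bout
  n <- length(w)
  expect_lt(max(abs(w[(n - 10):n])), 6 * noise_floor)

  expect_error(synth_activity("Jogging", prof, 10, cfg), "unknown activity")
  expect_error(synth_activity("Stat", prof, 0, cfg), "positive")
})

test_that("arm cranking has its dominant arm-channel frequency at 1 Hz (60 rpm)", {
  prof <- default_profile()
  prof$freq_scale <- 1.0
  blk <- synth_activity("ArmCrank", prof, 60, default_config(), seed = 23)
  x <- blk$imu$FA_gyr_x
  spec <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (seq_along(x) - 1) / (length(x) / 100)
  band <- freqs > 0.1 & freqs < 50
  f_dom <- freqs[band][which.max(spec[band])]
  expect_lt(abs(f_dom - 1.0), 0.05)
})

test_that("participant recordings concatenate blocks with exact annotation coverage", {
  cfg <- tiny_config()
  prof <- default_profile()
  sched <- make_schedule(default_config(schedule = list(min_s = 10, max_s = 10)),
                         seed = 2)
  ps <- generate_participant(prof, sched, cfg, seed = 31)
  ann <- ps$annotations
  expect_equal(nrow(ann), 8)
  expect_equal(ann$start_s[1], 0)
  expect_equal(ann$start_s[-1], ann$end_s[-8])
  expect_equal(max(ann$end_s), ps$recording$duration_s)
  expect_equal(nrow(ps$recording$imu), ps$recording$duration_s * 100)
  expect_equal(nrow(ps$recording$emg), ps$recording$duration_s * 1000)

  ps2 <- generate_participant(prof, sched, cfg, seed = 31)
  expect_identical(ps, ps2)
})

test_that("cohorts have unique participants, are seed-deterministic, and reject n < 2", {
  co <- tiny_cohort()
  expect_equal(nrow(co), 3)
  expect_equal(anyDuplicated(co$participant_id), 0)

  co2 <- generate_cohort(3, tiny_config(), seed = 11)
  expect_identical(co$recording[[2]]$imu, co2$recording[[2]]$imu)

  co3 <- generate_cohort(2, tiny_config(), seed = 12)
  expect_false(identical(co3$recording[[1]]$imu[-1],
                         co2$recording[[1]]$imu[-1]))

  expect_error(generate_cohort(1), "at least two")
})

test_that("wheel-motion classes separate from the rest by a wide gyro margin", {
  co <- tiny_cohort()
  cfg <- attr(co, "config")
  ratios <- vapply(seq_len(nrow(co)), function(i) {
    f <- tiny_features()[[i]]
    w <- abs(f$WCW_gyr_z)
    on <- f$label %in% c("Dribbling", "WCprop")
    mean(w[on]) / mean(w[!on])
  }, numeric(1))
  expect_true(all(ratios >= 5))
})

test_that("equal scheduled durations give equal per-class sample counts (within rounding)", {
  cfg <- default_config(schedule = list(min_s = 6, max_s = 6))
  co <- generate_cohort(2, cfg, seed = 41)
  f <- assemble_features(co$recording[[1]], co$annotations[[1]],
                         sensor_combination(2), cfg)
  counts <- table(f$label)
  expect_true(all(abs(counts - 60) <= 1))
})

test_that("static posture references are returned as stored and recoverable from raw EMG", {
  prof <- default_profile()
  prof$emg_posture_refs <- c(biceps = 2.0, deltoid = 0.5)
  expect_equal(static_posture_reference(prof), c(biceps = 2.0, deltoid = 0.5))

  # envelope of the posture-hold signal, normalized by the reference, is ~1
  raw <- synth_posture_hold(prof, "biceps", duration = 20,
                            config = default_config(), seed = 6)
  env <- emg_envelope(raw)
  core <- env[20:180]   # away from filter edges
  expect_lt(abs(mean(normalize_emg(core, 2.0)) - 1), 0.05)
})

test_that("cohorts survive a disk round trip", {
  co <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$participant_id, co$participant_id)
  expect_equal(back$annotations[[3]]$class, co$annotations[[3]]$class)
  expect_equal(back$annotations[[3]]$end_s, co$annotations[[3]]$end_s,
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$recording[[1]]$imu),
               as.data.frame(co$recording[[1]]$imu), tolerance = 1e-12)
  expect_equal(back$profile[[2]]$emg_posture_refs,
               co$profile[[2]]$emg_posture_refs, tolerance = 1e-12)
})
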