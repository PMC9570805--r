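# Synthetic cohort generation: virtual participants performing the eight
# SL-ADL with the study's sensor setup (five IMU sites at 100 Hz, two EMG
# channels at 1000 Hz on the upper arm) and ground-truth annotations.

#' Sample a virtual participant profile
#'
#' Inter-participant execution variability is modelled as multiplicative
#' log-normal amplitude scales per modality, a movement-tempo scale and a
#' phase offset, plus per-muscle static-posture EMG reference levels.
#'
#' @param participant_id Identifier string.
#' @param config Cohort configuration, see [default_config()].
#' @return A list of class `sladl_profile`.
#' @export
new_profile <- function(participant_id, config = default_config()) {
  v <- config$variability
  structure(list(
    participant_id = participant_id,
    amp_acc = stats::rlnorm(1, 0, v$amp_sdlog),
    amp_gyr = stats::rlnorm(1, 0, v$amp_sdlog),
    amp_emg = stats::rlnorm(1, 0, v$amp_sdlog),
    freq_scale = runif(1, v$freq_lo, v$freq_hi),
    phase = runif(1, 0, 2 * pi),
    emg_posture_refs = c(
      biceps = stats::rlnorm(1, v$ref_meanlog, v$ref_sdlog),
      deltoid = stats::rlnorm(1, v$ref_meanlog, v$ref_sdlog)
    )
  ), class = "sladl_profile")
}

#' Static-posture EMG reference levels of a participant
#'
#' The two reference envelope levels (biceps long head, medial deltoid)
#' measured during standardized static postures while holding a 2 kg weight;
#' used to normalize EMG envelopes to dimensionless units when
#' `config$emg$normalize` is enabled.
#'
#' @param profile An `sladl_profile`.
#' @return Named numeric vector of length 2, strictly positive.
#' @export
static_posture_reference <- function(profile) {
  refs <- profile$emg_posture_refs
  stopifnot(all(refs > 0))
  refs
}

#' Randomized activity schedule
#'
#' One bout of each of the eight activity classes in randomized order, with
#' bout durations drawn uniformly from the configured bounds. The schedule
#' stands in for the concatenated experimental trials of a laboratory
#' session.
#'
#' @param config Cohort configuration ([default_config()]).
#' @param seed Optional integer; fixes the RNG for this call only.
#' @return A tibble with columns `class` (factor) and `duration_s`; total
#'   duration is `sum(duration_s)`.
#' @export
#' @examples
#' make_schedule(default_config(schedule = list(min_s = 10, max_s = 10)))
make_schedule <- function(config = default_config(), seed = NULL) {
  sc <- config$schedule
  if (!(sc$min_s > 0 && sc$max_s >= sc$min_s)) {
    abort_sladl("invalid schedule bounds: need 0 < min_s <= max_s",
                class = "sladl_config_error")
  }
  with_seed(seed, {
    classes <- rep(SLADL_CLASSES, sc$repeats %||% 1)
    classes <- sample(classes)
    tibble::tibble(
      class = factor(classes, levels = SLADL_CLASSES),
      duration_s = runif(length(classes), sc$min_s, sc$max_s)
    )
  })
}

# ---- waveform primitives ---------------------------------------------------

# n x 3 quadrature cycle spread over the axes (x leads, y in quadrature,
# z smaller and phase shifted) -- a cheap stand-in for 3-D limb cycling.
quad_cycle <- function(t, freq, amp, phase) {
  w <- 2 * pi * freq * t + phase
  cbind(amp * sin(w), 0.7 * amp * cos(w), 0.4 * amp * sin(w + pi / 3))
}

# Smooth envelope of transient events at roughly `period_s` spacing.
burst_envelope <- function(t, period_s, dur_s) {
  dur <- max(dur_s, 0.2)
  n_ev <- max(1L, floor((max(t) + period_s / 2) / period_s))
  centers <- (seq_len(n_ev) - 0.5) * period_s +
    runif(n_ev, -0.1 * period_s, 0.1 * period_s)
  env <- rep(0, length(t))
  for (ct in centers) env <- env + bump(t, ct, dur / 2)
  pmin(env, 1.2)
}

# Place a burst-modulated oscillation on the three axes of one modality.
burst_axes <- function(t, env, amp, freq, phase) {
  w <- 2 * pi * freq * t + phase
  cbind(amp * env * sin(w), 0.8 * amp * env * cos(w),
        0.5 * amp * env * sin(w + pi / 4))
}

# Static gravity decomposition per body-worn site and activity class
# (m/s^2): arm posture differs across activities, so the accelerometer DC
# component is itself informative, as in real recordings. The wheelchair
# frame orientation never changes; the wheel sensor sees rotating gravity
# while the wheel turns (handled separately via the wheel angle).
POSTURE_OFFSETS <- list(
  WRL       = list(Thor = c(0.5, -9.7, 0.8), UA = c(1.0, -9.6, 1.5),
                   FA = c(2.0, -9.3, 2.0)),
  Dribbling = list(Thor = c(0.5, -9.7, 0.8), UA = c(1.5, -9.4, 1.8),
                   FA = c(3.0, -9.0, 2.0)),
  WCprop    = list(Thor = c(0.7, -9.6, 0.9), UA = c(1.6, -9.4, 1.6),
                   FA = c(3.2, -8.9, 2.1)),
  MMH       = list(Thor = c(1.2, -9.6, 0.9), UA = c(5.0, -8.2, 1.5),
                   FA = c(7.0, -6.5, 1.5)),
  Desk      = list(Thor = c(0.5, -9.7, 0.8), UA = c(2.0, -9.5, 0.8),
                   FA = c(9.3, -2.5, 1.0)),
  Stat      = list(Thor = c(0.5, -9.7, 0.8), UA = c(0.3, -9.7, 0.5),
                   FA = c(1.0, -9.6, 1.0)),
  Transfer  = list(Thor = c(2.5, -9.3, 1.2), UA = c(4.0, -8.6, 2.5),
                   FA = c(5.0, -8.0, 2.5)),
  ArmCrank  = list(Thor = c(0.8, -9.6, 0.9), UA = c(6.5, -7.0, 1.5),
                   FA = c(8.5, -4.0, 2.0))
)

GRAVITY <- 9.81

# ---- per-class signal builders --------------------------------------------
# Each builder returns signal content WITHOUT additive noise:
#   imu: n x 30 matrix (imu_channels() order) at the IMU rate
#   env: n x 2 EMG envelope (mV-scale) at the IMU rate, tonus not included
build_block <- function(class, sig, prof, duration, fs) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  imu <- matrix(0, n, 30, dimnames = list(NULL, imu_channels()))
  env <- matrix(0, n, 2)
  omega <- rep(0, n)      # wheel angular velocity (deg/s)
  fsc <- prof$freq_scale
  ph <- prof$phase
  put <- function(site, mod, block) {
    cols <- paste(site, mod, c("x", "y", "z"), sep = "_")
    imu[, cols] <<- imu[, cols] + block
  }

  if (class == "WRL") {
    e <- burst_envelope(t, sig$event_period_s, sig$event_dur_s)
    f <- sig$osc_freq * fsc
    put("UA", "acc", burst_axes(t, e, sig$ua_acc, f, ph))
    put("FA", "acc", burst_axes(t, e, sig$fa_acc, f, ph + 0.5))
    put("Thor", "acc", burst_axes(t, e, sig$thor_acc, f, ph + 1))
    put("UA", "gyr", burst_axes(t, e, sig$ua_gyr, f, ph + 2))
    put("FA", "gyr", burst_axes(t, e, sig$fa_gyr, f, ph + 2.5))
    put("Thor", "gyr", burst_axes(t, e, sig$thor_gyr, f, ph + 3))
    env <- cbind(sig$emg[1] * e, sig$emg[2] * e)
  } else if (class == "Dribbling") {
    # alternating move/pause bouts; wheel gyro on during bouts only, and
    # forced back to zero over the final half second (standstill at end)
    moving <- rep(0, n)
    omega <- rep(0, n)
    pos <- 0
    s <- 1
    while (pos < duration) {
      blen <- runif(1, sig$bout_lo, sig$bout_hi)
      plen <- runif(1, sig$pause_lo, sig$pause_hi)
      i0 <- max(1L, floor(pos * fs) + 1L)
      i1 <- min(n, floor((pos + blen) * fs))
      if (i1 >= i0) {
        moving[i0:i1] <- 1
        omega[i0:i1] <- s * runif(1, sig$omega_lo, sig$omega_hi)
      }
      s <- -s
      pos <- pos + blen + plen
    }
    tail_i <- t > duration - 0.5
    moving[tail_i] <- 0
    omega[tail_i] <- 0
    moving <- smooth_edges(moving, round(0.3 * fs))
    omega <- smooth_edges(omega, round(0.3 * fs))
    f <- sig$push_freq * fsc
    imu[, "WCW_gyr_z"] <- omega
    imu[, "WCW_gyr_x"] <- 0.05 * omega
    put("FA", "acc", burst_axes(t, moving, sig$fa_acc, f, ph))
    put("UA", "acc", burst_axes(t, moving, sig$ua_acc, f, ph + 0.4))
    put("FA", "gyr", burst_axes(t, moving, sig$fa_gyr, f, ph + 1))
    put("UA", "gyr", burst_axes(t, moving, sig$ua_gyr, f, ph + 1.4))
    put("Thor", "acc", burst_axes(t, moving, sig$thor_acc, f, ph + 2))
    put("WC", "acc", burst_axes(t, moving, sig$wc_acc, 2 * f, ph))
    env <- cbind(sig$emg[1] * moving, sig$emg[2] * moving)
  } else if (class == "WCprop") {
    v <- sample(sig$speeds_mps, 1)
    omega0 <- v / sig$wheel_radius_m * 180 / pi   # deg/s
    f <- sig$push_freq * fsc
    ramp <- pmin(t / 1.0, 1) * pmin((duration - t) / 1.0, 1)
    omega <- ramp * (omega0 + sig$ripple * sin(2 * pi * f * t + ph))
    imu[, "WCW_gyr_z"] <- omega
    cyc <- 0.5 + 0.5 * sin(2 * pi * f * t + ph)    # push cycle modulation
    put("FA", "acc", quad_cycle(t, f, sig$fa_acc, ph))
    put("UA", "acc", quad_cycle(t, f, sig$ua_acc, ph + 0.6))
    put("Thor", "acc", quad_cycle(t, f, sig$thor_acc, ph + 1.2))
    put("FA", "gyr", quad_cycle(t, f, sig$fa_gyr, ph + 2))
    put("UA", "gyr", quad_cycle(t, f, sig$ua_gyr, ph + 2.6))
    put("Thor", "gyr", quad_cycle(t, f, sig$thor_gyr, ph + 3.2))
    put("WC", "acc", quad_cycle(t, 2 * f, sig$wc_acc, ph))
    env <- cbind(sig$emg[1] * cyc, sig$emg[2] * cyc)
  } else if (class == "MMH") {
    e <- burst_envelope(t, sig$cycle_s, sig$event_dur_s)
    f <- sig$osc_freq * fsc
    put("FA", "acc", burst_axes(t, e, sig$fa_acc, f, ph))
    put("UA", "acc", burst_axes(t, e, sig$ua_acc, f, ph + 0.5))
    put("Thor", "acc", burst_axes(t, e, sig$thor_acc, 0.5 * f, ph + 1))
    put("FA", "gyr", burst_axes(t, e, sig$fa_gyr, f, ph + 1.5))
    put("UA", "gyr", burst_axes(t, e, sig$ua_gyr, f, ph + 2))
    put("Thor", "gyr", burst_axes(t, e, sig$thor_gyr, 0.5 * f, ph + 2.5))
    env <- cbind(sig$emg[1] * e, sig$emg[2] * e)
  } else if (class == "Desk") {
    # continuous low-amplitude typing jitter on the forearm
    slow <- 0.6 + 0.4 * sin(2 * pi * 0.08 * t + ph)
    f <- sig$jitter_freq * fsc
    put("FA", "acc", burst_axes(t, slow, sig$fa_acc, f, ph))
    put("FA", "gyr", burst_axes(t, slow, sig$fa_gyr, f, ph + 1))
    put("UA", "acc", burst_axes(t, slow, sig$ua_acc, f, ph + 2))
    put("UA", "gyr", burst_axes(t, slow, sig$ua_gyr, f, ph + 3))
    env <- cbind(sig$emg[1] * slow, sig$emg[2] * slow)
  } else if (class == "Stat") {
    # near-silence with rare small hand adjustments
    e <- burst_envelope(t, sig$event_period_s, sig$event_dur_s)
    f <- sig$osc_freq * fsc
    put("FA", "acc", burst_axes(t, e, sig$fa_acc, f, ph))
    put("FA", "gyr", burst_axes(t, e, sig$fa_gyr, f, ph + 1))
    env <- cbind(sig$emg[1] * e, sig$emg[2] * e)
  } else if (class == "Transfer") {
    # the annotated interval spans reach -> lift-over -> settle, so activity
    # covers most of it: a broad main movement plus a settling adjustment
    e <- pmin(1.2, bump(t, 0.35 * duration, 0.16 * duration) +
                0.8 * bump(t, 0.75 * duration, 0.10 * duration))
    f <- sig$osc_freq * fsc
    put("Thor", "acc", burst_axes(t, e, sig$thor_acc, f, ph))
    put("Thor", "gyr", burst_axes(t, e, sig$thor_gyr, f, ph + 0.5))
    put("UA", "acc", burst_axes(t, e, sig$ua_acc, f, ph + 1))
    put("UA", "gyr", burst_axes(t, e, sig$ua_gyr, f, ph + 1.5))
    put("FA", "acc", burst_axes(t, e, sig$fa_acc, f, ph + 2))
    put("FA", "gyr", burst_axes(t, e, sig$fa_gyr, f, ph + 2.5))
    put("WC", "acc", burst_axes(t, e, sig$wc_acc, f, ph + 3))
    env <- cbind(sig$emg[1] * e, sig$emg[2] * e)
  } else if (class == "ArmCrank") {
    f <- sig$crank_freq * fsc   # 60 rpm nominal
    put("FA", "acc", quad_cycle(t, f, sig$fa_acc, ph))
    put("FA", "gyr", quad_cycle(t, f, sig$fa_gyr, ph + 0.5))
    put("UA", "acc", quad_cycle(t, f, sig$ua_acc, ph + 1))
    put("UA", "gyr", quad_cycle(t, f, sig$ua_gyr, ph + 1.5))
    put("Thor", "acc", quad_cycle(t, f, sig$thor_acc, ph + 2))
    put("Thor", "gyr", quad_cycle(t, f, sig$thor_gyr, ph + 2.5))
    cyc <- 0.5 + 0.5 * sin(2 * pi * f * t + ph)
    env <- cbind(sig$emg[1] * cyc, sig$emg[2] * cyc)
  } else {
    abort_sladl(paste0("unknown activity class: ", class))
  }

  # postural gravity components: per-class arm/trunk orientation with a
  # small per-bout execution-style variation; the frame sensor never moves,
  # the wheel sensor sees gravity rotating with the wheel angle
  po <- POSTURE_OFFSETS[[class]]
  for (site in names(po)) {
    off <- po[[site]] + rnorm(3, 0, 0.35)
    cols <- paste(site, "acc", c("x", "y", "z"), sep = "_")
    imu[, cols] <- imu[, cols] + matrix(off, n, 3, byrow = TRUE)
  }
  imu[, "WC_acc_y"] <- imu[, "WC_acc_y"] - GRAVITY
  if (any(omega != 0)) {
    theta <- cumsum(omega) * (pi / 180) / fs + runif(1, 0, 2 * pi)
    imu[, "WCW_acc_x"] <- imu[, "WCW_acc_x"] + GRAVITY * sin(theta)
    imu[, "WCW_acc_y"] <- imu[, "WCW_acc_y"] - GRAVITY * cos(theta)
  } else {
    imu[, "WCW_acc_y"] <- imu[, "WCW_acc_y"] - GRAVITY
  }
  list(imu = imu, env = env)
}

# Band-limited (20-450 Hz) stochastic EMG carrier, normalized so that the
# mean rectified value is 1; the envelope extraction chain then recovers the
# modulating envelope directly.
emg_carrier <- function(n, fs) {
  x <- rnorm(n)
  bp <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, x)
  x / mean(abs(x))
}

#' Synthesize one activity block
#'
#' Generates raw multichannel sensor data for a single bout of one activity:
#' 30 IMU channels at the native 100 Hz and two raw EMG channels at 1000 Hz,
#' honouring the activity's signature (wheel gyroscope active only for
#' Dribbling/WCprop, 1 Hz arm cycling for ArmCrank, transient bursts for
#' WRL/Transfer/MMH, near-silence for Desk/Stat) scaled by the participant
#' profile, with additive Gaussian noise.
#'
#' @param class Activity class code (one of `activity_classes()$code`).
#' @param profile Participant profile from [new_profile()].
#' @param duration Block duration in seconds.
#' @param config Cohort configuration.
#' @param seed Optional integer seed for this call.
#' @return List with elements `imu` (tibble: `time_s` + 30 channels) and
#'   `emg` (tibble: `time_s` + 2 channels).
#' @export
synth_activity <- function(class, profile, duration,
                           config = default_config(), seed = NULL) {
  class <- as.character(class)
  if (!class %in% SLADL_CLASSES) {
    abort_sladl(paste0("unknown activity class: ", class))
  }
  if (duration <= 0) abort_sladl("duration must be positive")
  with_seed(seed, {
    fs <- config$rates$imu
    fse <- config$rates$emg
    sig <- config$signatures[[class]]
    blk <- build_block(class, sig, profile, duration, fs)

    nz <- config$noise
    sep <- nz$separability
    n <- nrow(blk$imu)
    acc_cols <- grep("_acc_", colnames(blk$imu))
    gyr_cols <- grep("_gyr_", colnames(blk$imu))
    imu <- blk$imu
    imu[, acc_cols] <- profile$amp_acc * imu[, acc_cols] +
      matrix(rnorm(n * length(acc_cols), 0, nz$acc * sep), n)
    imu[, gyr_cols] <- profile$amp_gyr * imu[, gyr_cols] +
      matrix(rnorm(n * length(gyr_cols), 0, nz$gyr * sep), n)

    ne <- round(duration * fse)
    te <- (seq_len(ne) - 1) / fse
    t100 <- (seq_len(n) - 1) / fs
    emg <- matrix(0, ne, 2, dimnames = list(NULL, emg_channels()))
    for (m in 1:2) {
      env100 <- profile$amp_emg * blk$env[, m] + nz$emg_tonus
      env1000 <- approx(t100, env100, xout = te, rule = 2)$y
      emg[, m] <- env1000 * emg_carrier(ne, fse)
    }

    list(
      imu = tibble::as_tibble(cbind(time_s = t100, as.data.frame(imu))),
      emg = tibble::as_tibble(cbind(time_s = te, as.data.frame(emg)))
    )
  })
}

#' Synthesize a static-posture EMG reference hold
#'
#' Raw EMG for the standardized static posture used for normalization: the
#' carrier amplitude-modulated by the participant's constant reference
#' envelope level for that muscle. Running [emg_envelope()] on this signal
#' recovers approximately the reference level itself.
#'
#' @inheritParams synth_activity
#' @param muscle `"biceps"` or `"deltoid"`.
#' @return Numeric vector of raw EMG at the EMG rate.
#' @export
synth_posture_hold <- function(profile, muscle = c("biceps", "deltoid"),
                               duration = 10, config = default_config(),
                               seed = NULL) {
  muscle <- match.arg(muscle)
  ref <- static_posture_reference(profile)[[muscle]]
  with_seed(seed, {
    ne <- round(duration * config$rates$emg)
    ref * emg_carrier(ne, config$rates$emg)
  })
}

#' Generate one participant's recording and annotation track
#'
#' Concatenates [synth_activity()] blocks in schedule order; annotation
#' intervals coincide exactly with block boundaries, are contiguous,
#' non-overlapping and cover the full recording.
#'
#' @param profile Participant profile.
#' @param schedule Activity schedule from [make_schedule()].
#' @param config Cohort configuration.
#' @param seed Optional integer seed.
#' @return List with `recording` (class `sladl_recording`: tibbles `imu`,
#'   `emg` plus rates and duration) and `annotations` (tibble `start_s`,
#'   `end_s`, `class`).
#' @export
generate_participant <- function(profile, schedule,
                                 config = default_config(), seed = NULL) {
  with_seed(seed, {
    fs <- config$rates$imu
    fse <- config$rates$emg
    # snap durations to the IMU sample grid so blocks concatenate exactly
    dur <- round(schedule$duration_s * fs) / fs
    blocks <- purrr::map2(as.character(schedule$class), dur,
                          function(cl, d) synth_activity(cl, profile, d, config))
    imu <- dplyr::bind_rows(purrr::map(blocks, function(b) b$imu[-1]))
    emg <- dplyr::bind_rows(purrr::map(blocks, function(b) b$emg[-1]))
    imu <- dplyr::bind_cols(tibble::tibble(time_s = (seq_len(nrow(imu)) - 1) / fs), imu)
    emg <- dplyr::bind_cols(tibble::tibble(time_s = (seq_len(nrow(emg)) - 1) / fse), emg)
    ends <- cumsum(dur)
    annotations <- tibble::tibble(
      start_s = c(0, head(ends, -1)),
      end_s = ends,
      class = schedule$class
    )
    recording <- structure(list(
      imu = imu, emg = emg,
      fs_imu = fs, fs_emg = fse,
      duration_s = sum(dur)
    ), class = "sladl_recording")
    list(recording = recording, annotations = annotations)
  })
}

#' @export
print.sladl_recording <- function(x, ...) {
  cat("<sladl_recording: ", format(x$duration_s), " s, ",
      ncol(x$imu) - 1, " IMU channels @ ", x$fs_imu, " Hz, ",
      ncol(x$emg) - 1, " EMG channels @ ", x$fs_emg, " Hz>\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws `n_participants` virtual participants with distinct execution
#' profiles, an individual randomized activity schedule each, and full raw
#' recordings with ground-truth annotations. Regeneration with the same seed
#' and configuration is bit-identical.
#'
#' @param n_participants Number of participants (>= 2; the study cohort
#'   default is 10).
#' @param config Cohort configuration ([default_config()]).
#' @param seed Integer seed governing all randomness of the cohort.
#' @return A tibble of class `sladl_cohort` with columns `participant_id`,
#'   `profile`, `recording`, `annotations` (the last three are list
#'   columns), carrying the seed and config as attributes.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(2, default_config(schedule = list(min_s = 4, max_s = 5)),
#'                           seed = 1)
#' cohort$participant_id
#' }
generate_cohort <- function(n_participants = 10, config = default_config(),
                            seed = 1) {
  if (n_participants < 2) {
    abort_sladl("n_participants must be >= 2 (leave-one-subject-out needs at least two)")
  }
  rows <- with_seed(seed, {
    purrr::map(seq_len(n_participants), function(i) {
      id <- sprintf("P%02d", i)
      profile <- new_profile(id, config)
      schedule <- make_schedule(config)
      ps <- generate_participant(profile, schedule, config)
      tibble::tibble(
        participant_id = id,
        profile = list(profile),
        recording = list(ps$recording),
        annotations = list(ps$annotations)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  class(out) <- c("sladl_cohort", class(out))
  out
}
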