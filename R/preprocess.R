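# Preprocessing: 100 Hz IMU -> 10 Hz block means, 1000 Hz raw EMG ->
# 10 Hz smooth rectified envelope, label alignment, channel selection.

#' Downsample an IMU channel from 100 Hz to 10 Hz
#'
#' Moving-average downsampling implemented as non-overlapping block means:
#' output sample `k` is the mean of input samples `10k .. 10k+9` (0-based),
#' i.e. a moving-average filter whose window equals the decimation factor.
#'
#' @param x Numeric vector at the native rate.
#' @param factor Decimation factor (native rate / target rate; default 10).
#' @return Numeric vector of length `floor(length(x) / factor)`.
#' @export
#' @examples
#' downsample_imu(c(1:10, 11:20))  # 5.5, 15.5
downsample_imu <- function(x, factor = 10) {
  if (length(x) < factor) {
    abort_sladl(paste0("input too short: need at least ", factor, " samples"))
  }
  n_out <- floor(length(x) / factor)
  colMeans(matrix(x[seq_len(n_out * factor)], nrow = factor))
}

#' EMG envelope extraction configuration
#'
#' The filter chain applied to raw EMG: zero-phase (forward--backward)
#' 4th-order Butterworth high-pass at 20 Hz, offset correction (mean
#' subtraction), full-wave rectification, zero-phase 4th-order Butterworth
#' low-pass at 2 Hz, then decimation to the 10 Hz target rate. The stated
#' order is the design order of the single-pass filter; bidirectional
#' application doubles the effective attenuation.
#'
#' @param hp_cutoff High-pass cutoff in Hz.
#' @param lp_cutoff Low-pass cutoff in Hz.
#' @param filter_order Butterworth design order.
#' @param emg_rate Raw EMG sampling rate in Hz.
#' @param target_rate Output rate in Hz.
#' @return List of class `sladl_envelope_config`.
#' @export
envelope_config <- function(hp_cutoff = 20, lp_cutoff = 2, filter_order = 4,
                            emg_rate = 1000, target_rate = 10) {
  stopifnot(filter_order >= 1,
            hp_cutoff < emg_rate / 2, lp_cutoff < emg_rate / 2)
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 filter_order = filter_order, emg_rate = emg_rate,
                 target_rate = target_rate),
            class = "sladl_envelope_config")
}

#' Smooth rectified EMG envelope at 10 Hz
#'
#' Applies, in order: zero-phase high-pass (20 Hz), mean subtraction,
#' rectification, zero-phase low-pass (2 Hz), then takes every
#' `emg_rate / target_rate`-th sample (the envelope is band-limited far below
#' the post-decimation Nyquist, so no further anti-aliasing is required).
#' Small negative filter-ringing values are clamped to zero.
#'
#' @param x Raw EMG vector at `cfg$emg_rate`.
#' @param cfg An [envelope_config()].
#' @return Nonnegative envelope vector at `cfg$target_rate`.
#' @export
emg_envelope <- function(x, cfg = envelope_config()) {
  min_len <- 3 * cfg$filter_order * ceiling(cfg$emg_rate / cfg$lp_cutoff)
  if (length(x) < min_len) {
    abort_sladl(paste0("EMG input too short for stable zero-phase filtering: ",
                       "need at least ", min_len, " samples, got ", length(x)))
  }
  nyq <- cfg$emg_rate / 2
  hp <- signal::butter(cfg$filter_order, cfg$hp_cutoff / nyq, type = "high")
  lp <- signal::butter(cfg$filter_order, cfg$lp_cutoff / nyq, type = "low")
  y <- signal::filtfilt(hp, x)
  y <- y - mean(y)
  y <- abs(y)
  y <- signal::filtfilt(lp, y)
  dec <- round(cfg$emg_rate / cfg$target_rate)
  env <- y[seq(1, length(y), by = dec)]
  pmax(env, 0)
}

#' Normalize an EMG envelope by a static-posture reference level
#'
#' @param env Envelope vector.
#' @param ref Positive scalar reference level (see
#'   [static_posture_reference()]).
#' @return `env / ref` (dimensionless).
#' @export
normalize_emg <- function(env, ref) {
  if (!is.numeric(ref) || length(ref) != 1 || ref <= 0) {
    abort_sladl("EMG reference level must be a positive scalar")
  }
  env / ref
}

#' Per-sample labels at 10 Hz from an annotation track
#'
#' Sample `k` (0-based, time `k / 10` s) receives the class of the interval
#' containing its timestamp under the half-open convention `[start, end)`:
#' a sample exactly at an interval start belongs to the starting interval.
#'
#' @param track Annotation tibble (`start_s`, `end_s`, `class`), contiguous
#'   and non-overlapping.
#' @param n_samples Number of 10 Hz samples to label.
#' @param target_rate Label rate in Hz.
#' @return Factor vector of length `n_samples` with the 8 activity levels.
#' @export
labels_at_10hz <- function(track, n_samples, target_rate = 10) {
  track <- dplyr::arrange(track, .data$start_s)
  if (nrow(track) == 0) abort_sladl("empty annotation track")
  gaps <- abs(track$start_s[-1] - track$end_s[-nrow(track)])
  if (track$start_s[1] != 0 || any(gaps > 1e-9)) {
    abort_sladl("annotation track has gaps or overlaps; intervals must be contiguous from 0")
  }
  times <- (seq_len(n_samples) - 1) / target_rate
  # half-open intervals: the final timestamp must lie strictly inside
  if (max(times) >= track$end_s[nrow(track)] - 1e-9) {
    abort_sladl("annotation track shorter than the requested label span")
  }
  idx <- findInterval(times + 1e-9, track$start_s)
  factor(as.character(track$class[idx]), levels = SLADL_CLASSES)
}

#' Assemble the 10 Hz feature sequence for one participant
#'
#' Processes every channel of the requested sensor combination (IMU channels
#' via [downsample_imu()], EMG channels via [emg_envelope()], optionally
#' normalized by the static-posture references when `config$emg$normalize`
#' is set), aligns per-sample labels via [labels_at_10hz()], and truncates
#' all columns to the shortest channel. Following the model's sequence-input
#' convention, no normalization, centering or scaling is applied to the
#' feature matrix: units stay mixed (m/s^2, deg/s, mV-scale envelope).
#'
#' @param recording An `sladl_recording`.
#' @param track Annotation tibble for the same recording.
#' @param combination A [sensor_combination()] (or id accepted by it).
#' @param config Cohort configuration (EMG normalization flag, rates).
#' @param profile Participant profile; required only when EMG normalization
#'   is enabled.
#' @return A tibble of class `sladl_features`: `time_s`, `label`, then one
#'   column per channel in the combination's fixed order. The combination is
#'   attached as attribute `"combination"`.
#' @export
assemble_features <- function(recording, track, combination = sensor_combination(1),
                              config = default_config(), profile = NULL) {
  if (!inherits(combination, "sladl_combination")) {
    combination <- sensor_combination(combination)
  }
  want_emg <- any(combination$channels %in% emg_channels())
  if (want_emg && !all(emg_channels() %in% names(recording$emg))) {
    abort_sladl("combination requests EMG but the recording has no EMG channels")
  }
  dec <- round(recording$fs_imu / config$rates$target)
  cols <- list()
  for (ch in combination$channels) {
    if (ch %in% emg_channels()) {
      env <- emg_envelope(recording$emg[[ch]],
                          envelope_config(emg_rate = recording$fs_emg,
                                          target_rate = config$rates$target))
      if (isTRUE(config$emg$normalize)) {
        if (is.null(profile)) {
          abort_sladl("EMG normalization enabled but no profile supplied")
        }
        muscle <- if (grepl("biceps", ch)) "biceps" else "deltoid"
        env <- normalize_emg(env, static_posture_reference(profile)[[muscle]])
      }
      cols[[ch]] <- env
    } else {
      cols[[ch]] <- downsample_imu(recording$imu[[ch]], dec)
    }
  }
  n <- min(vapply(cols, length, integer(1)))
  cols <- purrr::map(cols, function(x) x[seq_len(n)])
  labels <- labels_at_10hz(track, n, config$rates$target)
  out <- tibble::as_tibble(c(
    list(time_s = (seq_len(n) - 1) / config$rates$target, label = labels),
    cols
  ))
  attr(out, "combination") <- combination
  class(out) <- c("sladl_features", class(out))
  out
}

# Feature tibble -> T x D matrix + integer labels for the model layer.
features_matrix <- function(features) {
  ch <- setdiff(names(features), c("time_s", "label", "participant_id"))
  X <- as.matrix(features[, ch])
  y <- as.integer(features$label) - 1L
  list(X = X, y = y, channels = ch)
}
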