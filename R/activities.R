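# Activity classes, sensor sites and channel layout.

# Canonical class order; every label vector in the package uses these levels.
SLADL_CLASSES <- c("WRL", "Dribbling", "WCprop", "MMH",
                   "Desk", "Stat", "Transfer", "ArmCrank")

SLADL_SITES <- c("WC", "WCW", "Thor", "UA", "FA")

#' The eight shoulder-loading activities of daily living
#'
#' Returns the fixed list of wheelchair-related shoulder-loading activity
#' classes (SL-ADL) that the classifier distinguishes, in the canonical order
#' used for label factors, confusion charts and model outputs.
#'
#' @return A tibble with columns `code` (factor, 8 levels) and `label`
#'   (display string).
#' @export
#' @examples
#' activity_classes()
activity_classes <- function() {
  tibble::tibble(
    code = factor(SLADL_CLASSES, levels = SLADL_CLASSES),
    label = c(
      "Weight relief lift",
      "Dribbling (short-range intermittent propulsion)",
      "Wheelchair propulsion on treadmill",
      "Manual material handling",
      "Deskwork",
      "Stationary sitting",
      "Transfer wheelchair/couch",
      "Arm crank ergometer work"
    )
  )
}

#' Wearable sensor sites
#'
#' Five sensor locations: wheelchair frame (WC), wheelchair wheel (WCW),
#' thorax (Thor), right upper arm (UA) and forearm (FA). Every site carries a
#' 3-axis accelerometer and 3-axis gyroscope at 100 Hz; the upper-arm unit
#' additionally records two bipolar surface EMG channels (biceps long head,
#' medial deltoid) at 1000 Hz.
#'
#' @return A tibble with columns `code`, `label` and `modalities` (list).
#' @export
sensor_sites <- function() {
  tibble::tibble(
    code = SLADL_SITES,
    label = c("wheelchair frame", "wheelchair wheel", "thorax",
              "right upper arm", "forearm"),
    modalities = list(
      c("accel3", "gyro3"), c("accel3", "gyro3"), c("accel3", "gyro3"),
      c("accel3", "gyro3", "emg2"), c("accel3", "gyro3")
    )
  )
}

# 30 IMU channel names in fixed column order (site-major, acc before gyro).
imu_channels <- function() {
  as.vector(vapply(SLADL_SITES, function(s) {
    paste(s, c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z"),
          sep = "_")
  }, character(6)))
}

emg_channels <- function() c("UA_emg_biceps", "UA_emg_deltoid")

#' Sensor combinations for the ablation study
#'
#' The four channel subsets compared in the ablation: C1 = all five IMUs plus
#' the two EMG envelopes (32 channels); C2 = all five IMUs, EMG omitted (30);
#' C3 = upper-arm IMU only (6); C4 = forearm IMU only (6).
#'
#' @param id Combination identifier: 1--4 or `"C1"`..`"C4"`.
#' @return An object of class `sladl_combination`: a list with `id` and the
#'   ordered `channels` the feature matrix will contain.
#' @export
#' @examples
#' sensor_combination(1)$id
#' length(sensor_combination("C4")$channels)
sensor_combination <- function(id) {
  if (is.numeric(id)) id <- paste0("C", id)
  id <- match.arg(id, c("C1", "C2", "C3", "C4"))
  channels <- switch(id,
    C1 = c(imu_channels(), emg_channels()),
    C2 = imu_channels(),
    C3 = grep("^UA_(acc|gyr)", imu_channels(), value = TRUE),
    C4 = grep("^FA_(acc|gyr)", imu_channels(), value = TRUE)
  )
  structure(list(id = id, channels = channels), class = "sladl_combination")
}

#' @export
print.sladl_combination <- function(x, ...) {
  cat("<sensor combination ", x$id, ": ", length(x$channels),
      " channels>\n", sep = "")
  invisible(x)
}
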