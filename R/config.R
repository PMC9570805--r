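# Cohort configuration: sampling rates, schedule bounds, noise levels,
# inter-participant variability and per-activity signature parameters.

#' Default cohort configuration
#'
#' Returns the full configuration used by the synthetic cohort generator.
#' Defaults reflect the study conditions: 10 participants, five sensor sites
#' at 100 Hz IMU / 1000 Hz EMG, one bout of each of the eight activities per
#' participant with durations drawn from `schedule$min_s`--`schedule$max_s`
#' seconds, and per-participant execution variability (log-normal amplitude
#' scaling, +/-10 % movement tempo, random phase).
#'
#' `noise$separability` is a single difficulty knob multiplying all additive
#' noise standard deviations; 1 is the calibrated default.
#'
#' @param ... Named overrides merged (shallowly, per top-level section) into
#'   the defaults, e.g. `default_config(n_participants = 4)`.
#' @return A nested list of class `sladl_config`.
#' @export
#' @examples
#' cfg <- default_config(n_participants = 4)
#' cfg$schedule$min_s
default_config <- function(...) {
  cfg <- list(
    n_participants = 10,
    rates = list(imu = 100, emg = 1000, target = 10),
    schedule = list(min_s = 8, max_s = 12, repeats = 1),
    noise = list(acc = 0.25, gyr = 2.0, emg_tonus = 0.02, separability = 1.0),
    variability = list(amp_sdlog = 0.15, freq_lo = 0.9, freq_hi = 1.1,
                       ref_meanlog = -0.5, ref_sdlog = 0.2),
    emg = list(normalize = FALSE),
    signatures = default_signatures()
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = c("sladl_config", "list"))
}

#' Read or write a cohort configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns an `sladl_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param config An `sladl_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Per-activity signal signatures
#'
#' Parametric templates encoding the qualitative contrasts that identify each
#' activity in the raw signals: the wheel gyroscope deviates from zero only
#' during wheel-motion activities (Dribbling, WCprop); arm cranking is a pure
#' 60 rpm (1 Hz) cycle on the arm channels; weight-relief lifts, transfers
#' and material handling are transient bursts on arm/thorax channels;
#' deskwork and stationary sitting are low amplitude. Amplitudes are in
#' m/s^2 (accelerometers), deg/s (gyroscopes) and mV-scale envelope units
#' (EMG).
#'
#' @return Named list (one element per activity class) of parameter lists.
#' @export
default_signatures <- function() {
  list(
    WRL = list(event_period_s = 5, event_dur_s = 2.2, osc_freq = 1.1,
               ua_acc = 2.5, fa_acc = 2.0, thor_acc = 0.6,
               ua_gyr = 45, fa_gyr = 50, thor_gyr = 8,
               emg = c(biceps = 0.6, deltoid = 0.9)),
    Dribbling = list(bout_lo = 2, bout_hi = 4, pause_lo = 1, pause_hi = 2,
                     omega_lo = 80, omega_hi = 150, push_freq = 1.2,
                     fa_acc = 1.8, ua_acc = 1.2, fa_gyr = 40, ua_gyr = 25,
                     thor_acc = 0.3, wc_acc = 0.3,
                     emg = c(biceps = 0.35, deltoid = 0.30)),
    WCprop = list(speeds_mps = c(0.56, 1.11), wheel_radius_m = 0.30,
                  push_freq = 1.0, ripple = 15,
                  fa_acc = 2.0, ua_acc = 1.3, thor_acc = 0.4,
                  fa_gyr = 45, ua_gyr = 30, thor_gyr = 5, wc_acc = 0.2,
                  emg = c(biceps = 0.30, deltoid = 0.40)),
    MMH = list(cycle_s = 3.5, event_dur_s = 1.6, osc_freq = 0.9,
               fa_acc = 2.2, ua_acc = 1.5, thor_acc = 0.9,
               fa_gyr = 60, ua_gyr = 35, thor_gyr = 10,
               emg = c(biceps = 0.70, deltoid = 0.60)),
    Desk = list(jitter_freq = 2.8, fa_acc = 0.35, fa_gyr = 6,
                ua_acc = 0.12, ua_gyr = 2,
                emg = c(biceps = 0.08, deltoid = 0.05)),
    Stat = list(event_period_s = 12, event_dur_s = 0.5, osc_freq = 1.0,
                fa_acc = 0.4, fa_gyr = 5,
                emg = c(biceps = 0.02, deltoid = 0.02)),
    Transfer = list(osc_freq = 0.5,
                    thor_acc = 3.0, thor_gyr = 35, ua_acc = 2.8, ua_gyr = 55,
                    fa_acc = 2.2, fa_gyr = 45, wc_acc = 0.4,
                    emg = c(biceps = 0.80, deltoid = 0.70)),
    ArmCrank = list(crank_freq = 1.0,
                    fa_acc = 2.5, fa_gyr = 70, ua_acc = 1.6, ua_gyr = 45,
                    thor_acc = 0.3, thor_gyr = 4,
                    emg = c(biceps = 0.45, deltoid = 0.35))
  )
}
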