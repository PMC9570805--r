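# On-disk cohort layout: one directory per participant holding per-site CSV
# files (column 1 = time in seconds, header row naming channels), the
# annotation track, and the participant profile as JSON.

#' Write a cohort to disk
#'
#' Layout: `<dir>/<participant_id>/` with `<SITE>.csv` per sensor site
#' (time plus that site's IMU channels), `UA_emg.csv` (1000 Hz EMG),
#' `annotations.csv` (`start_s,end_s,class`) and `profile.json`; the cohort
#' configuration and seed go to `<dir>/cohort.json`.
#'
#' @param cohort An `sladl_cohort`.
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(nrow(cohort))) {
    pdir <- file.path(dir, cohort$participant_id[k])
    dir.create(pdir, showWarnings = FALSE)
    rec <- cohort$recording[[k]]
    for (site in SLADL_SITES) {
      cols <- grep(paste0("^", site, "_(acc|gyr)_"), names(rec$imu),
                   value = TRUE)
      write.csv(rec$imu[, c("time_s", cols)],
                file.path(pdir, paste0(site, ".csv")), row.names = FALSE)
    }
    write.csv(rec$emg, file.path(pdir, "UA_emg.csv"), row.names = FALSE)
    write.csv(cohort$annotations[[k]], file.path(pdir, "annotations.csv"),
              row.names = FALSE)
    prof <- unclass(cohort$profile[[k]])
    # keep muscle names through JSON (atomic-vector names are dropped)
    prof$emg_posture_refs <- as.list(prof$emg_posture_refs)
    jsonlite::write_json(prof, file.path(pdir, "profile.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  meta <- list(seed = attr(cohort, "seed"),
               participant_ids = cohort$participant_id,
               config = unclass(attr(cohort, "config")))
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Inverse of [write_cohort()].
#'
#' @param dir Cohort directory.
#' @return An `sladl_cohort` tibble.
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort.json")
  if (!file.exists(meta_path)) {
    abort_sladl(paste0("not a cohort directory (missing cohort.json): ", dir))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  config <- do.call(default_config, meta$config)
  rows <- purrr::map(meta$participant_ids, function(id) {
    pdir <- file.path(dir, id)
    imu <- NULL
    for (site in SLADL_SITES) {
      d <- tibble::as_tibble(read.csv(file.path(pdir, paste0(site, ".csv"))))
      imu <- if (is.null(imu)) d else dplyr::bind_cols(imu, d[-1])
    }
    emg <- tibble::as_tibble(read.csv(file.path(pdir, "UA_emg.csv")))
    ann <- tibble::as_tibble(read.csv(file.path(pdir, "annotations.csv")))
    ann$class <- factor(ann$class, levels = SLADL_CLASSES)
    prof <- jsonlite::read_json(file.path(pdir, "profile.json"),
                                simplifyVector = TRUE)
    prof$emg_posture_refs <- unlist(prof$emg_posture_refs)
    class(prof) <- "sladl_profile"
    rec <- structure(list(
      imu = imu, emg = emg,
      fs_imu = config$rates$imu, fs_emg = config$rates$emg,
      duration_s = max(ann$end_s)
    ), class = "sladl_recording")
    tibble::tibble(participant_id = id, profile = list(prof),
                   recording = list(rec), annotations = list(ann))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- meta$seed
  attr(out, "config") <- config
  class(out) <- c("sladl_cohort", class(out))
  out
}
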