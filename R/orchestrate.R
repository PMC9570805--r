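# End-to-end entry points tying the stages together: simulate a cohort to
# disk, run the LOSO protocol over sensor combinations, and write reports
# plus a reproducibility manifest. Runs are resumable: folds whose outputs
# already exist on disk are skipped.

#' Simulate a cohort and write it to disk
#'
#' @param dir Output directory.
#' @param config Cohort configuration ([default_config()] or a YAML path
#'   accepted by [read_config()]).
#' @param seed Cohort seed.
#' @return The cohort, invisibly; side effect: the on-disk layout of
#'   [write_cohort()] plus a `manifest.json`.
#' @export
simulate_cohort <- function(dir, config = default_config(), seed = 1) {
  if (is.character(config)) config <- read_config(config)
  cohort <- generate_cohort(config$n_participants, config, seed)
  write_cohort(cohort, dir)
  files <- list.files(dir, recursive = TRUE)
  manifest <- list(
    stage = "simulate",
    seed = seed,
    n_participants = config$n_participants,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("sladl")),
    files = as.list(tools::md5sum(file.path(dir, files)) |>
                      setNames(files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Run the full study on a cohort
#'
#' Executes the LOSO training protocol for the requested sensor
#' combinations and writes, per combination: the pooled confusion chart
#' (CSV), tidy per-(participant, class) metrics (CSV) and per-fold
#' prediction timelines (CSV); plus the ablation summary table
#' (`summary.csv`) and a run manifest with seeds, early-stopping iterations
#' and per-repeat validation accuracies. Folds already present in the
#' output directory are not recomputed.
#'
#' @param cohort An `sladl_cohort`, or a cohort directory written by
#'   [simulate_cohort()].
#' @param out_dir Report directory.
#' @param combinations Combination ids to run (default all four).
#' @param cfg A [training_config()].
#' @param verbose Print progress.
#' @return Named list of `sladl_loso` results, invisibly.
#' @export
run_study <- function(cohort, out_dir, combinations = 1:4,
                      cfg = training_config(), verbose = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (cid in combinations) {
    comb <- sensor_combination(cid)
    cdir <- file.path(out_dir, comb$id)
    dir.create(cdir, showWarnings = FALSE)
    cache <- file.path(cdir, "folds.rds")
    if (file.exists(cache)) {
      res <- readRDS(cache)
      if (verbose) message("[", comb$id, "] reusing existing fold results")
    } else {
      res <- run_combination(cohort, comb, cfg, verbose = verbose)
      saveRDS(res, cache)
    }
    results[[comb$id]] <- res
    pooled <- confusion_chart(unlist_labels(res$y_true),
                              unlist_labels(res$y_pred))
    write.csv(as.data.frame(unclass(pooled)),
              file.path(cdir, "confusion.csv"))
    write.csv(tidy(res), file.path(cdir, "metrics.csv"), row.names = FALSE)
    for (k in seq_len(nrow(res))) {
      write.csv(export_timeline(res[k, ]),
                file.path(cdir, paste0("timeline_",
                                       res$val_participant_id[k], ".csv")),
                row.names = FALSE)
    }
    outputs <- setdiff(list.files(cdir), "manifest.json")
    manifest <- list(
      combination = comb$id,
      channels = comb$channels,
      training_config = unclass(cfg),
      files = as.list(tools::md5sum(file.path(cdir, outputs)) |>
                        setNames(outputs)),
      folds = purrr::map(seq_len(nrow(res)), function(k) list(
        val_participant_id = res$val_participant_id[k],
        best_repeat = res$best_repeat[k],
        val_accuracy = res$val_accuracy[k],
        stopped_at_iter = res$stopped_at_iter[k],
        repeat_accuracies = res$repeat_accuracies[[k]]
      ))
    )
    jsonlite::write_json(manifest, file.path(cdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  summary <- summarize_loso(results)
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(results)
}
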