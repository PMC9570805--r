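# Confusion charts and per-class performance measures
# (accuracy, sensitivity, precision, specificity), summary tables,
# precision distributions and prediction timelines.

#' Multiclass confusion chart
#'
#' Counts of true class (rows) versus predicted class (columns) over the
#' eight activity classes, in canonical class order.
#'
#' @param y_true,y_pred Equal-length factors (or vectors coercible to the
#'   activity levels).
#' @return An 8 x 8 integer matrix of class `sladl_confusion`.
#' @export
confusion_chart <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort_sladl("y_true and y_pred must have equal length")
  }
  y_true <- factor(as.character(y_true), levels = SLADL_CLASSES)
  y_pred <- factor(as.character(y_pred), levels = SLADL_CLASSES)
  m <- table(true = y_true, predicted = y_pred)
  m <- matrix(as.integer(m), nrow = length(SLADL_CLASSES),
              dimnames = list(true = SLADL_CLASSES,
                              predicted = SLADL_CLASSES))
  structure(m, class = c("sladl_confusion", "matrix"))
}

#' Per-class TP/FP/FN/TN counts from a confusion chart
#'
#' For class `c`: TP is the diagonal cell, FN the rest of row `c`, FP the
#' rest of column `c`, and TN everything else.
#'
#' @param chart An `sladl_confusion` (or plain square count matrix).
#' @param class Class code or index.
#' @return Named list with `TP`, `FP`, `FN`, `TN` (integers summing to the
#'   chart total).
#' @export
class_counts <- function(chart, class) {
  if (is.character(class)) class <- match(class, rownames(chart))
  total <- sum(chart)
  TP <- chart[class, class]
  FN <- sum(chart[class, ]) - TP
  FP <- sum(chart[, class]) - TP
  list(TP = TP, FP = FP, FN = FN, TN = total - TP - FN - FP)
}

#' Per-class performance measures from TP/FP/FN/TN counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' precision `TP/(TP+FP)` and specificity in its standard form
#' `TN/(TN+FP)`. A variant specificity with FN in the denominator,
#' `TN/(TN+FN)`, is reported alongside as `specificity_alt` for
#' transparency; in the heavily TN-dominated charts of this task the two
#' nearly coincide. Ratios with a zero denominator are returned as `NA` and
#' excluded from summaries.
#'
#' @param counts List with `TP`, `FP`, `FN`, `TN` (see [class_counts()]).
#' @return One-row tibble of the measures as fractions in `[0, 1]`.
#' @export
class_metrics <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    if (total == 0) abort_sladl("all-zero counts")
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    tibble::tibble(
      accuracy = (TP + TN) / total,
      sensitivity = ratio(TP, TP + FN),
      precision = ratio(TP, TP + FP),
      specificity = ratio(TN, TN + FP),
      specificity_alt = ratio(TN, TN + FN)
    )
  })
}

#' Row- or column-normalized confusion chart
#'
#' Row normalization expresses each row in percent of its total; the
#' diagonal then equals per-class sensitivity x 100. Column normalization
#' likewise yields per-class precision on the diagonal. Empty rows/columns
#' give `NA`.
#'
#' @param chart An `sladl_confusion`.
#' @param axis `"row"` or `"column"`.
#' @return Numeric matrix of percentages.
#' @export
normalize_chart <- function(chart, axis = c("row", "column")) {
  axis <- match.arg(axis)
  m <- unclass(chart) * 1.0
  if (axis == "row") {
    s <- rowSums(m)
    out <- sweep(m, 1, s, "/") * 100
    out[s == 0, ] <- NA_real_
  } else {
    s <- colSums(m)
    out <- sweep(m, 2, s, "/") * 100
    out[, s == 0] <- NA_real_
  }
  out
}

#' Per-participant, per-class metrics from a LOSO result
#'
#' One `MetricsRecord` per (validation participant, class): the held-out
#' participant's confusion chart is computed from the best network's
#' per-sample predictions and all per-class measures derived from it.
#'
#' @param x An `sladl_loso` from [run_combination()].
#' @param ... Unused.
#' @return Tidy tibble with `participant_id`, `class`, `combination` and
#'   the measure columns (fractions).
#' @export
tidy.sladl_loso <- function(x, ...) {
  comb <- attr(x, "combination")$id %||% NA_character_
  purrr::map_dfr(seq_len(nrow(x)), function(k) {
    chart <- confusion_chart(x$y_true[[k]], x$y_pred[[k]])
    purrr::map_dfr(SLADL_CLASSES, function(cl) {
      dplyr::bind_cols(
        tibble::tibble(participant_id = x$val_participant_id[k],
                       class = factor(cl, levels = SLADL_CLASSES),
                       combination = comb),
        class_metrics(class_counts(chart, cl))
      )
    })
  })
}

#' One-row summary of a LOSO result
#'
#' Mean per-class measures (in percent) over all (participant, class)
#' records with defined values, plus the overall per-sample accuracy.
#'
#' @inheritParams tidy.sladl_loso
#' @return One-row tibble.
#' @export
glance.sladl_loso <- function(x, ...) {
  rec <- tidy(x)
  pooled <- confusion_chart(unlist_labels(x$y_true), unlist_labels(x$y_pred))
  tibble::tibble(
    combination = attr(x, "combination")$id %||% NA_character_,
    n_folds = nrow(x),
    n_samples = sum(x$n_val),
    sample_accuracy = sum(diag(pooled)) / sum(pooled),
    accuracy = 100 * mean(rec$accuracy, na.rm = TRUE),
    sensitivity = 100 * mean(rec$sensitivity, na.rm = TRUE),
    precision = 100 * mean(rec$precision, na.rm = TRUE),
    specificity = 100 * mean(rec$specificity, na.rm = TRUE)
  )
}

unlist_labels <- function(lst) {
  factor(unlist(purrr::map(lst, as.character)), levels = SLADL_CLASSES)
}

#' Summary table over sensor combinations
#'
#' Mean (SD) of each per-class measure, in percent, over all (participant,
#' class) records of each LOSO result -- the ablation summary across sensor
#' combinations. The SD is the sample standard deviation; undefined records
#' (empty class in a fold) are excluded. Set `by_participant = TRUE` to
#' average classes within participant first and summarize over
#' participants.
#'
#' @param ... One or more `sladl_loso` results (or a single list of them).
#' @param by_participant Average within participant before summarizing.
#' @return A tibble with one row per combination and `mean`/`sd` columns
#'   per measure.
#' @export
summarize_loso <- function(..., by_participant = FALSE) {
  results <- list(...)
  if (length(results) == 1 && !inherits(results[[1]], "sladl_loso")) {
    results <- results[[1]]
  }
  purrr::map_dfr(results, function(res) {
    rec <- tidy(res)
    if (by_participant) {
      rec <- rec |>
        dplyr::group_by(.data$participant_id, .data$combination) |>
        dplyr::summarise(dplyr::across(
          c("accuracy", "sensitivity", "precision", "specificity"),
          function(v) mean(v, na.rm = TRUE)), .groups = "drop")
    }
    long <- tidyr::pivot_longer(
      rec, cols = c("accuracy", "sensitivity", "precision", "specificity"),
      names_to = "measure", values_to = "value")
    long |>
      dplyr::group_by(.data$measure) |>
      dplyr::summarise(
        mean = 100 * mean(.data$value, na.rm = TRUE),
        sd = 100 * sd(.data$value, na.rm = TRUE), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "measure",
                         values_from = c("mean", "sd")) |>
      dplyr::mutate(combination = attr(res, "combination")$id %||% NA_character_,
                    .before = 1)
  })
}

#' Per-sample prediction timeline of one fold
#'
#' @param fold_result One row of an `sladl_loso` (or the tibble subset).
#' @return Tibble with `time_s`, `true`, `pred` aligned at 10 Hz.
#' @export
export_timeline <- function(fold_result) {
  tibble::tibble(
    time_s = fold_result$time_s[[1]],
    true = fold_result$y_true[[1]],
    pred = fold_result$y_pred[[1]]
  )
}

#' Five-number precision distribution per class
#'
#' Median, quartiles (linear interpolation, the default quantile
#' convention), whiskers at the most extreme records within 1.5 x IQR of
#' the quartiles, and outliers beyond them -- the boxplot statistics of the
#' per-participant precision records.
#'
#' @param records Tidy metrics records (from [tidy.sladl_loso()]), possibly
#'   several combinations bound together.
#' @param measure Which measure column to summarize.
#' @return Tibble per (combination, class): `q1`, `median`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `n`, and `outliers` (list column).
#' @export
precision_distribution <- function(records, measure = "precision") {
  records |>
    dplyr::group_by(.data$combination, .data$class) |>
    dplyr::group_modify(function(d, key) {
      v <- d[[measure]]
      v <- v[!is.na(v)]
      if (length(v) == 0) {
        return(tibble::tibble(q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                              whisker_lo = NA_real_, whisker_hi = NA_real_,
                              n = 0L, outliers = list(numeric(0))))
      }
      q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
      iqr <- q[3] - q[1]
      lo_fence <- q[1] - 1.5 * iqr
      hi_fence <- q[3] + 1.5 * iqr
      inside <- v >= lo_fence & v <= hi_fence
      tibble::tibble(
        q1 = q[1], median = q[2], q3 = q[3],
        whisker_lo = min(v[inside]), whisker_hi = max(v[inside]),
        n = length(v), outliers = list(v[!inside])
      )
    }) |>
    dplyr::ungroup()
}
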