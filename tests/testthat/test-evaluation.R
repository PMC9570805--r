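# Confusion charts, per-class counts and measures, normalized charts,
# summaries, timelines and precision distributions -- cross-checked against
# brute-force oracles.

classes8 <- as.character(activity_classes()$code)

rand_labels <- function(n, seed) {
  withr::with_seed(seed, {
    list(true = factor(sample(classes8, n, TRUE), levels = classes8),
         pred = factor(sample(classes8, n, TRUE), levels = classes8))
  })
}

# brute-force oracle: count one pair at a time
oracle_counts <- function(y_true, y_pred, cl) {
  tp <- sum(y_true == cl & y_pred == cl)
  fp <- sum(y_true != cl & y_pred == cl)
  fn <- sum(y_true == cl & y_pred != cl)
  list(TP = tp, FP = fp, FN = fn, TN = length(y_true) - tp - fp - fn)
}

test_that("confusion charts count true/predicted pairs exactly", {
  y <- factor(classes8[c(1, 1, 2)], levels = classes8)
  p <- factor(classes8[c(1, 2, 2)], levels = classes8)
  ch <- confusion_chart(y, p)
  expect_equal(ch[1, 1], 1L)
  expect_equal(ch[1, 2], 1L)
  expect_equal(ch[2, 2], 1L)
  expect_equal(sum(ch), 3L)

  same <- rand_labels(200, 1)$true
  diagonal <- confusion_chart(same, same)
  expect_equal(sum(diag(diagonal)), 200L)
  expect_equal(sum(diagonal) - sum(diag(diagonal)), 0L)

  expect_error(confusion_chart(same, same[-1]), "equal length")
})

test_that("per-class counts agree with a brute-force oracle over many random label sets", {
  for (s in 1:100) {
    lb <- rand_labels(60, s)
    ch <- confusion_chart(lb$true, lb$pred)
    cl <- classes8[(s %% 8) + 1]
    expect_identical(class_counts(ch, cl),
                     oracle_counts(lb$true, lb$pred, cl))
  }
  # algebraic identity: total FP mass = total FN mass = off-diagonal mass
  lb <- rand_labels(500, 999)
  ch <- confusion_chart(lb$true, lb$pred)
  fps <- sum(vapply(classes8, function(cl) class_counts(ch, cl)$FP, numeric(1)))
  fns <- sum(vapply(classes8, function(cl) class_counts(ch, cl)$FN, numeric(1)))
  off <- sum(ch) - sum(diag(ch))
  expect_equal(fps, off)
  expect_equal(fns, off)
})

test_that("performance measures match hand arithmetic and flag undefined ratios", {
  perfect <- class_metrics(list(TP = 50, FP = 0, FN = 0, TN = 50))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  precision = 1, specificity = 1,
                                  specificity_alt = 1))

  m <- class_metrics(list(TP = 8, FN = 2, FP = 4, TN = 86))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$accuracy, 0.94)
  expect_equal(m$specificity, 86 / 90)
  expect_equal(m$specificity_alt, 86 / 88)

  degenerate <- class_metrics(list(TP = 0, FP = 0, FN = 5, TN = 95))
  expect_true(is.na(degenerate$precision))
  expect_false(is.na(degenerate$sensitivity))
  expect_error(class_metrics(list(TP = 0, FP = 0, FN = 0, TN = 0)), "zero")
})

test_that("row/column-normalized diagonals equal sensitivity/precision in percent", {
  lb <- rand_labels(400, 7)
  ch <- confusion_chart(lb$true, lb$pred)
  rn <- normalize_chart(ch, "row")
  cn <- normalize_chart(ch, "column")
  for (i in seq_along(classes8)) {
    cc <- class_counts(ch, i)
    met <- class_metrics(cc)
    expect_equal(rn[i, i], 100 * met$sensitivity)
    expect_equal(cn[i, i], 100 * met$precision)
  }
  expect_equal(unname(rowSums(rn)), rep(100, 8), tolerance = 1e-9)
  expect_equal(unname(colSums(cn)), rep(100, 8), tolerance = 1e-9)

  # empty rows surface as NA, not NaN percentages
  ch0 <- confusion_chart(factor(rep("Stat", 5), levels = classes8),
                         factor(rep("Stat", 5), levels = classes8))
  expect_true(all(is.na(normalize_chart(ch0, "row")[1, ])))
})

# hand-built LOSO result with two folds of known predictions
fake_loso <- function(t1, p1, t2, p2, combination = sensor_combination(1)) {
  mk <- function(x) factor(classes8[x], levels = classes8)
  out <- tibble::tibble(
    val_participant_id = c("P01", "P02"),
    best_repeat = 0L,
    val_accuracy = c(mean(t1 == p1), mean(t2 == p2)),
    stopped_at_iter = 1L,
    n_val = c(length(t1), length(t2)),
    y_true = list(mk(t1), mk(t2)),
    y_pred = list(mk(p1), mk(p2)),
    time_s = list((seq_along(t1) - 1) / 10, (seq_along(t2) - 1) / 10),
    repeat_accuracies = list(0.5, 0.5),
    model = list(NULL, NULL)
  )
  attr(out, "combination") <- combination
  class(out) <- c("sladl_loso", class(out))
  out
}

test_that("tidy records and summaries follow the documented conventions", {
  idx <- rep(1:8, each = 10)
  perfect <- fake_loso(idx, idx, idx, idx)
  s <- summarize_loso(list(perfect))
  expect_equal(s$mean_accuracy, 100)
  expect_equal(s$sd_accuracy, 0)
  expect_equal(s$mean_sensitivity, 100)

  rec <- tidy(perfect)
  expect_equal(nrow(rec), 16)    # 2 participants x 8 classes
  expect_true(all(rec$accuracy == 1))

  # sample-SD convention over (participant, class) records: summarizing a
  # mixed result equals the hand-computed mean/sd of its tidy records
  mixed <- fake_loso(idx, idx, idx, c(idx[-1], 1))
  ms <- summarize_loso(list(mixed))
  recs <- tidy(mixed)
  expect_equal(ms$mean_accuracy, 100 * mean(recs$accuracy, na.rm = TRUE))
  expect_equal(ms$sd_accuracy, 100 * sd(recs$accuracy, na.rm = TRUE))
  expect_gt(ms$sd_accuracy, 0)

  g <- glance(perfect)
  expect_equal(g$sample_accuracy, 1)
  expect_equal(g$n_folds, 2)
})

test_that("summaries cover one row per combination in an ablation set", {
  idx <- rep(1:8, each = 5)
  res <- lapply(1:4, function(k) {
    fake_loso(idx, idx, idx, idx, combination = sensor_combination(k))
  })
  s <- summarize_loso(res)
  expect_equal(nrow(s), 4)
  expect_setequal(s$combination, c("C1", "C2", "C3", "C4"))
})

test_that("timelines align with the confusion chart mass", {
  withr::with_seed(13, {
    t1 <- sample(1:8, 120, TRUE)
    p1 <- ifelse(runif(120) < 0.8, t1, sample(1:8, 120, TRUE))
  })
  fl <- fake_loso(t1, p1, t1, t1)
  tl <- export_timeline(fl[1, ])
  expect_equal(nrow(tl), 120)
  expect_equal(diff(tl$time_s), rep(0.1, 119), tolerance = 1e-12)
  ch <- confusion_chart(fl$y_true[[1]], fl$y_pred[[1]])
  expect_equal(sum(tl$true != tl$pred), sum(ch) - sum(diag(ch)))

  perfect_tl <- export_timeline(fl[2, ])
  expect_true(all(perfect_tl$true == perfect_tl$pred))
})

test_that("precision distributions follow the linear-interpolation quantile convention", {
  rec <- tibble::tibble(
    combination = "C1",
    class = factor("WRL", levels = classes8),
    precision = c(0.6, 0.7, 0.8, 0.9, 1.0)
  )
  d <- precision_distribution(rec)
  expect_equal(d$median, 0.8)
  expect_equal(d$q1, unname(quantile(rec$precision, 0.25, type = 7)))
  expect_equal(d$q3, unname(quantile(rec$precision, 0.75, type = 7)))
  expect_equal(d$outliers[[1]], numeric(0))

  rec2 <- tibble::tibble(
    combination = "C1",
    class = factor("Stat", levels = classes8),
    precision = c(rep(0.9, 9), 0.1)
  )
  d2 <- precision_distribution(rec2)
  expect_equal(d2$outliers[[1]], 0.1)    # beyond 1.5 x IQR
  expect_equal(d2$whisker_lo, 0.9)
})
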