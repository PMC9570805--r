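# Leave-one-subject-out training protocol: per-fold full-batch training with
# validation-accuracy early stopping (15-iteration grace period, 2-iteration
# patience), five repeats per fold with best-network selection, run per
# sensor combination.

#' Training protocol configuration
#'
#' One "iteration" is a full pass over the training batch (all training
#' sequences fed whole, padded and masked) followed by one validation
#' evaluation. Early stopping halts training when, after `grace_iters`
#' initial iterations, the running-best validation accuracy has not improved
#' for `patience` consecutive iterations.
#'
#' @param grace_iters Iterations during which the early-stopping monitor is
#'   inert.
#' @param patience Consecutive non-improving post-grace iterations that
#'   trigger a stop.
#' @param repeats Training repeats per fold (differing in weight
#'   initialization); the best network by validation accuracy is kept.
#' @param max_iters Hard iteration cap guaranteeing termination.
#' @param lr Adam learning rate. The default is sized for the full-batch
#'   regime (one gradient step per iteration under a tight iteration
#'   budget), where classic mini-batch rates move the weights too little.
#' @param clip_norm Global gradient-norm clip.
#' @param base_seed Base seed; repeat `r` of fold `k` uses
#'   `base_seed + 1000 * k + r`.
#' @return List of class `sladl_training_config`.
#' @export
training_config <- function(grace_iters = 15, patience = 2, repeats = 5,
                            max_iters = 200, lr = 0.02, clip_norm = 1.0,
                            base_seed = 1) {
  stopifnot(grace_iters >= 0, patience >= 1, repeats >= 1,
            max_iters > grace_iters + patience)
  structure(list(grace_iters = grace_iters, patience = patience,
                 repeats = repeats, max_iters = max_iters, lr = lr,
                 clip_norm = clip_norm, base_seed = base_seed),
            class = "sladl_training_config")
}

#' Leave-one-subject-out folds
#'
#' @param cohort An `sladl_cohort` (or anything with a `participant_id`
#'   column).
#' @return A tibble with one row per fold: `val_id` and `train_ids`
#'   (list column). Every participant is the validation subject exactly
#'   once.
#' @export
loso_folds <- function(cohort) {
  ids <- unique(cohort$participant_id)
  if (length(ids) < 2) {
    abort_sladl("leave-one-subject-out requires at least 2 participants")
  }
  tibble::tibble(
    val_id = ids,
    train_ids = purrr::map(ids, function(i) setdiff(ids, i))
  )
}

#' Early-stopping decision from a validation-accuracy trace
#'
#' Returns `TRUE` (stop) iff the current iteration lies beyond the grace
#' period and the last `patience` post-grace iterations brought no new
#' running-best validation accuracy. Never stops at or before iteration
#' `grace_iters`; a constant trace therefore stops at iteration
#' `grace_iters + patience`.
#'
#' @param val_acc_trace Numeric vector of validation accuracies, one per
#'   completed iteration.
#' @param cfg A [training_config()].
#' @return Logical scalar.
#' @export
early_stop_decision <- function(val_acc_trace, cfg = training_config()) {
  n <- length(val_acc_trace)
  if (n == 0) abort_sladl("empty validation trace")
  if (n <= cfg$grace_iters) return(FALSE)
  prev_best <- c(-Inf, head(cummax(val_acc_trace), -1))
  improved <- val_acc_trace > prev_best
  post <- seq(cfg$grace_iters + 1, n)   # iterations the monitor watches
  if (length(post) < cfg$patience) return(FALSE)
  recent <- tail(post, cfg$patience)
  all(!improved[recent])
}

# Pad a list of T_b x D matrices into the D x B x Tmax cube + mask + labels.
pack_batch <- function(Xs, ys) {
  B <- length(Xs)
  D <- ncol(Xs[[1]])
  Ts <- vapply(Xs, nrow, integer(1))
  Tmax <- max(Ts)
  X <- array(0, c(D, B, Tmax))
  y <- matrix(-1L, B, Tmax)
  mask <- matrix(0, B, Tmax)
  for (b in seq_len(B)) {
    X[, b, seq_len(Ts[b])] <- t(Xs[[b]])
    y[b, seq_len(Ts[b])] <- ys[[b]]
    mask[b, seq_len(Ts[b])] <- 1
  }
  list(X = X, y = y, mask = mask)
}

#' Train one LOSO fold
#'
#' Full-batch training of the sequence classifier on the training
#' participants' feature sequences, monitoring per-sample validation
#' accuracy on the held-out participant every iteration. Training halts per
#' [early_stop_decision()] or at `max_iters`; the parameters returned are
#' the snapshot from the best-validation-accuracy iteration.
#'
#' @param train_features List of `sladl_features` (or `T x D` matrices with
#'   a `label` attribute is not supported -- use feature tibbles).
#' @param val_features One `sladl_features` for the held-out participant.
#' @param cfg A [training_config()].
#' @param repeat_seed Integer seed for weight initialization.
#' @param model_cfg Optional [model_config()]; defaults to the architecture
#'   sized for the feature dimensionality.
#' @return List with `model` (best snapshot), `val_acc_trace`,
#'   `stopped_at_iter`, `best_iter`, `val_accuracy`.
#' @export
train_fold <- function(train_features, val_features, cfg = training_config(),
                       repeat_seed = 1, model_cfg = NULL) {
  if (length(train_features) == 0) abort_sladl("empty training set")
  tr <- purrr::map(train_features, features_matrix)
  va <- features_matrix(val_features)
  D <- ncol(tr[[1]]$X)
  if (ncol(va$X) != D) abort_sladl("train/validation channel mismatch")
  batch <- pack_batch(purrr::map(tr, "X"), purrr::map(tr, "y"))
  Xv <- as_input_cube(va$X)
  mv <- matrix(1, 1, nrow(va$X))
  yv <- matrix(va$y, 1)
  storage.mode(yv) <- "integer"

  if (is.null(model_cfg)) model_cfg <- model_config(D, seed = repeat_seed)
  model_cfg$seed <- repeat_seed
  params <- init_params(model_cfg)
  opt <- adam_init(params)

  trace <- numeric(0)
  best <- list(acc = -Inf, params = params, iter = 0L)
  stopped_at <- cfg$max_iters
  for (iter in seq_len(cfg$max_iters)) {
    g <- model_gradient(params, batch$X, batch$y, batch$mask)
    upd <- adam_step(params, g$grads, opt, lr = cfg$lr,
                     clip_norm = cfg$clip_norm)
    params <- upd$params
    opt <- upd$state
    Pv <- rnn_forward_cpp(params, Xv, mv, FALSE)
    pred <- max.col(t(Pv[, 1, , drop = TRUE]), ties.method = "first") - 1L
    acc <- mean(pred == va$y)
    trace <- c(trace, acc)
    if (acc > best$acc) {
      best <- list(acc = acc, params = params, iter = iter)
    }
    if (early_stop_decision(trace, cfg)) {
      stopped_at <- iter
      break
    }
  }
  model <- structure(list(config = model_cfg, params = best$params),
                     class = "sladl_model")
  list(model = model, val_acc_trace = trace, stopped_at_iter = stopped_at,
       best_iter = best$iter, val_accuracy = best$acc)
}

#' Train a fold with repeats and keep the best network
#'
#' Runs [train_fold()] `cfg$repeats` times with repeat seeds
#' `base_seed + 1000 * fold_index + r`, `r = 0 .. repeats - 1` (repeats
#' differ in their random weight initialization), and keeps the repeat with
#' the highest validation accuracy; ties break toward the lowest repeat
#' index.
#'
#' @inheritParams train_fold
#' @param val_id Identifier of the held-out participant.
#' @param fold_index 0-based fold number (used in the repeat seed).
#' @param trainer Training backend, a function with [train_fold()]'s
#'   signature; injectable for protocol tests.
#' @return A one-row tibble (`FoldResult`): `val_participant_id`,
#'   `best_repeat`, `val_accuracy`, `stopped_at_iter`, `n_val`, plus list
#'   columns `y_true`, `y_pred`, `time_s`, `repeat_accuracies`, `model`.
#' @export
train_repeats <- function(train_features, val_features, cfg = training_config(),
                          val_id = "P?", fold_index = 0,
                          model_cfg = NULL, trainer = train_fold) {
  runs <- purrr::map(seq_len(cfg$repeats) - 1L, function(r) {
    trainer(train_features, val_features, cfg,
            repeat_seed = cfg$base_seed + 1000L * fold_index + r,
            model_cfg = model_cfg)
  })
  accs <- vapply(runs, function(x) x$val_accuracy, numeric(1))
  k <- which.max(accs)      # ties -> lowest repeat index
  bestrun <- runs[[k]]
  y_true <- val_features$label
  y_pred <- predict(bestrun$model, val_features)
  tibble::tibble(
    val_participant_id = val_id,
    best_repeat = k - 1L,
    val_accuracy = accs[k],
    stopped_at_iter = bestrun$stopped_at_iter,
    n_val = length(y_true),
    y_true = list(y_true),
    y_pred = list(y_pred),
    time_s = list(val_features$time_s),
    repeat_accuracies = list(accs),
    model = list(bestrun$model)
  )
}

#' Run the full LOSO protocol for one sensor combination
#'
#' Assembles the 10 Hz feature sequences for every participant, then trains
#' each leave-one-subject-out fold with repeats and collects the best
#' network's per-sample predictions on the held-out participant.
#'
#' @param cohort An `sladl_cohort`.
#' @param combination A [sensor_combination()] or id.
#' @param cfg A [training_config()].
#' @param config Cohort/preprocessing configuration; defaults to the one the
#'   cohort was generated with.
#' @param trainer Training backend (see [train_repeats()]).
#' @param verbose Print per-fold progress lines.
#' @return A tibble of class `sladl_loso`: one `FoldResult` row per
#'   participant, with the combination and config attached as attributes.
#' @export
run_combination <- function(cohort, combination = sensor_combination(1),
                            cfg = training_config(),
                            config = NULL, trainer = train_fold,
                            verbose = FALSE) {
  if (!inherits(combination, "sladl_combination")) {
    combination <- sensor_combination(combination)
  }
  config <- config %||% attr(cohort, "config") %||% default_config()
  feats <- purrr::pmap(
    list(cohort$recording, cohort$annotations, cohort$profile),
    function(rec, ann, prof) {
      assemble_features(rec, ann, combination, config, profile = prof)
    }
  )
  names(feats) <- cohort$participant_id
  folds <- loso_folds(cohort)
  res <- purrr::map(seq_len(nrow(folds)), function(k) {
    vid <- folds$val_id[k]
    fr <- train_repeats(feats[folds$train_ids[[k]]], feats[[vid]], cfg,
                        val_id = vid, fold_index = k - 1L, trainer = trainer)
    if (verbose) {
      message(sprintf("[%s] fold %d/%d (%s): val acc %.3f, stopped at %d",
                      combination$id, k, nrow(folds), vid, fr$val_accuracy,
                      fr$stopped_at_iter))
    }
    fr
  })
  out <- dplyr::bind_rows(res)
  attr(out, "combination") <- combination
  attr(out, "training_config") <- cfg
  class(out) <- c("sladl_loso", class(out))
  out
}
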