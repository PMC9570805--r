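# Shared fixtures. Expensive objects are built once per test run and cached
# in this environment; everything is generated in code from fixed seeds.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, expr, envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Short-schedule config for fast unit tests.
tiny_config <- function(...) {
  default_config(schedule = list(min_s = 4, max_s = 6), ...)
}

# Three-participant cohort reused across cohort/preprocessing tests.
tiny_cohort <- function() {
  memo("tiny_cohort", generate_cohort(3, tiny_config(), seed = 11))
}

tiny_features <- function(combination = 1) {
  key <- paste0("tiny_features_", combination)
  memo(key, {
    co <- tiny_cohort()
    cfg <- attr(co, "config")
    lapply(seq_len(nrow(co)), function(i) {
      assemble_features(co$recording[[i]], co$annotations[[i]],
                        sensor_combination(combination), cfg,
                        co$profile[[i]])
    })
  })
}

default_profile <- function(seed = 5) {
  memo(paste0("profile_", seed), {
    withr::with_seed(seed, new_profile("P01", default_config()))
  })
}

# Feature tibble with prescribed per-class channel means: a linearly
# separable sequence task for capacity/smoke tests.
toy_features <- function(labels, means, noise = 0.1, seed = 1) {
  withr::with_seed(seed, {
    labels <- as.integer(labels)   # indexes into the canonical class list
    X <- t(vapply(labels, function(k) {
      means[[k]] + rnorm(length(means[[k]]), 0, noise)
    }, numeric(length(means[[1]]))))
    codes <- as.character(activity_classes()$code)
    out <- tibble::tibble(
      time_s = (seq_along(labels) - 1) / 10,
      label = factor(codes[labels], levels = codes)
    )
    for (j in seq_len(ncol(X))) out[[paste0("ch", j)]] <- X[, j]
    class(out) <- c("sladl_features", class(out))
    out
  })
}

# Tiny but real classifier for protocol tests that only need a model object.
stub_model <- function(D) {
  build_model(model_config(D, gru_units = 2, bilstm_units = 2, seed = 1))
}

# Injectable trainer that records its calls and returns prescribed
# validation accuracies without training.
make_fake_trainer <- function(accuracies, D) {
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  calls$train_ids <- list()
  calls$seeds <- integer(0)
  trainer <- function(train_features, val_features, cfg, repeat_seed,
                      model_cfg = NULL) {
    calls$n <- calls$n + 1L
    calls$train_ids[[calls$n]] <- names(train_features)
    calls$seeds <- c(calls$seeds, repeat_seed)
    acc <- accuracies[(calls$n - 1L) %% length(accuracies) + 1L]
    list(model = stub_model(D), val_acc_trace = acc, stopped_at_iter = 1L,
         best_iter = 1L, val_accuracy = acc)
  }
  list(trainer = trainer, calls = calls)
}
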