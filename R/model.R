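# The per-timestep sequence classifier: sequence input (no normalization)
# -> GRU(100) -> biLSTM(200 units per direction) -> dense(8) -> softmax,
# trained with mean per-timestep cross-entropy. The forward/backward passes
# live in compiled code (src/rnn.cpp); this file owns configuration,
# seeded initialization and the user-facing forward/loss/predict surface.

#' Sequence classifier configuration
#'
#' @param input_dim Number of input channels D (depends on the sensor
#'   combination: 32, 30 or 6).
#' @param gru_units GRU hidden units (unidirectional).
#' @param bilstm_units LSTM hidden units per direction; the concatenated
#'   bidirectional output has twice this width.
#' @param n_classes Output classes.
#' @param seed Integer seed for parameter initialization.
#' @return List of class `sladl_model_config`.
#' @export
model_config <- function(input_dim, gru_units = 100, bilstm_units = 200,
                         n_classes = 8, seed = 1) {
  dims <- c(input_dim, gru_units, bilstm_units, n_classes)
  if (any(dims <= 0) || any(dims != round(dims))) {
    abort_sladl("model dimensions must be positive integers")
  }
  structure(list(input_dim = input_dim, gru_units = gru_units,
                 bilstm_units = bilstm_units, n_classes = n_classes,
                 seed = seed),
            class = "sladl_model_config")
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_params <- function(cfg) {
  D <- cfg$input_dim; H1 <- cfg$gru_units; H2 <- cfg$bilstm_units
  C <- cfg$n_classes
  lstm_b <- function() {
    b <- rep(0, 4 * H2)
    b[(H2 + 1):(2 * H2)] <- 1     # forget-gate bias at 1
    b
  }
  with_seed(cfg$seed, list(
    gru_W = glorot(3 * H1, D, D, H1),
    gru_U = glorot(3 * H1, H1, H1, H1),
    gru_b = rep(0, 3 * H1),
    lstm_fw_W = glorot(4 * H2, H1, H1, H2),
    lstm_fw_U = glorot(4 * H2, H2, H2, H2),
    lstm_fw_b = lstm_b(),
    lstm_bw_W = glorot(4 * H2, H1, H1, H2),
    lstm_bw_U = glorot(4 * H2, H2, H2, H2),
    lstm_bw_b = lstm_b(),
    fc_W = glorot(C, 2 * H2, 2 * H2, C),
    fc_b = rep(0, C)
  ))
}

#' Build a sequence classifier
#'
#' Initializes the GRU -> biLSTM -> dense -> softmax stack with
#' Glorot-uniform weights drawn from the configured seed (two builds with
#' the same configuration are identical).
#'
#' @param cfg A [model_config()].
#' @return Object of class `sladl_model` (configuration plus parameters).
#' @export
build_model <- function(cfg) {
  structure(list(config = cfg, params = init_params(cfg)),
            class = "sladl_model")
}

#' @export
print.sladl_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat("<sladl_model: ", cfg$input_dim, " -> GRU(", cfg$gru_units,
      ") -> biLSTM(2x", cfg$bilstm_units, ") -> dense(", cfg$n_classes,
      ") -> softmax; ", format(n_par, big.mark = ","), " parameters>\n",
      sep = "")
  invisible(x)
}

# T x D matrix -> D x 1 x T cube expected by the compiled core.
as_input_cube <- function(X) {
  X <- as.matrix(X)
  array(t(X), dim = c(ncol(X), 1L, nrow(X)))
}

#' Per-timestep class probabilities
#'
#' Runs the forward pass on a single sequence. The biLSTM consumes the whole
#' sequence in both directions, so the prediction at time `t` depends on
#' future as well as past context.
#'
#' @param model An `sladl_model`.
#' @param X `T x D` numeric matrix (or `sladl_features` tibble, from which
#'   the channel columns are taken).
#' @param precise Use double precision (default single, the training
#'   precision).
#' @return `T x n_classes` matrix of row-stochastic probabilities.
#' @export
model_forward <- function(model, X, precise = FALSE) {
  if (inherits(X, "sladl_features")) X <- features_matrix(X)$X
  X <- as.matrix(X)
  if (ncol(X) != model$config$input_dim) {
    abort_sladl(paste0("input has ", ncol(X), " channels; model expects ",
                       model$config$input_dim))
  }
  P <- rnn_forward_cpp(model$params, as_input_cube(X),
                       matrix(1, 1, nrow(X)), precise)
  t(P[, 1, , drop = TRUE])
}

#' Mean per-timestep cross-entropy loss
#'
#' @param P `T x C` row-stochastic probability matrix.
#' @param y Integer labels in `0 .. C-1` (or a factor with C levels).
#' @return Scalar mean categorical cross-entropy (natural log).
#' @export
sequence_loss <- function(P, y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (length(y) != nrow(P)) abort_sladl("labels and probabilities differ in length")
  if (any(y < 0 | y >= ncol(P))) {
    abort_sladl(paste0("labels must lie in 0..", ncol(P) - 1))
  }
  -mean(log(pmax(P[cbind(seq_along(y), y + 1L)], 1e-12)))
}

#' Predicted label sequence
#'
#' Per-timestep argmax of the class probabilities; exact ties break toward
#' the lowest class index.
#'
#' @inheritParams model_forward
#' @param ... Unused.
#' @return Factor vector of length T with the 8 activity levels.
#' @export
predict.sladl_model <- function(object, X, ...) {
  P <- model_forward(object, X)
  idx <- max.col(P, ties.method = "first")
  factor(SLADL_CLASSES[idx], levels = SLADL_CLASSES)
}

# One full-batch loss/gradient evaluation on padded, masked sequences.
# X: D x B x T cube; y: B x T integer (0-based, -1 at padding); mask: B x T.
model_gradient <- function(params, X, y, mask, precise = FALSE) {
  storage.mode(y) <- "integer"
  rnn_grad_cpp(params, X, y, mask, precise)
}

# Adam with global gradient-norm clipping.
adam_init <- function(params) {
  list(m = purrr::map(params, function(p) p * 0),
       v = purrr::map(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 0.02, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip_norm = 1.0) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(clip_norm) && gnorm > clip_norm) {
    grads <- purrr::map(grads, function(g) g * (clip_norm / gnorm))
  }
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
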