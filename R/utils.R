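# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so cohort generation is reproducible without clobbering the
# session RNG. A NULL seed leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

abort_sladl <- function(msg, class = "sladl_error") {
  rlang::abort(msg, class = class)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Gaussian bump centred at `center` (seconds), width = sd in seconds.
bump <- function(t, center, width) exp(-0.5 * ((t - center) / width)^2)

# Raised-cosine smoothing of a piecewise-constant waveform (width in samples).
smooth_edges <- function(x, n_smooth) {
  if (n_smooth < 2) return(x)
  k <- 0.5 * (1 - cos(2 * pi * seq_len(n_smooth) / (n_smooth + 1)))
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], n_smooth), x, rep(x[n], n_smooth))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(n_smooth + 1):(n_smooth + n)])
}
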