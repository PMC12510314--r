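# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Seeds R's RNG with `seed`, runs `expr`, and restores whatever RNG state
#' existed before the call, so generator calls are reproducible without
#' clobbering the caller's random stream.
#'
#' @param seed integer seed, `0 <= seed < 2^31`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  check_seed(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed < 0 || seed >= 2^31 || seed != floor(seed)) {
    stop("`seed` must be a single integer in [0, 2^31)", call. = FALSE)
  }
  invisible(as.integer(seed))
}

# Fixed-offset substream seed for replicate r of a generator call; keeps
# replicate-level reproducibility without shared-state coupling.
substream_seed <- function(seed, r, stride = 10000L) {
  s <- (as.numeric(seed) + stride * as.numeric(r)) %% (2^31 - 1)
  as.integer(s)
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a %s finite scalar", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

# Empirical quantile by linear interpolation of the empirical CDF (h = n*p),
# i.e. stats::quantile type 4: at p = 0.95 and n = 1000 this is exactly the
# 950th order statistic, and interpolates between order statistics otherwise.
empirical_quantile <- function(x, p) {
  stats::quantile(x, probs = p, type = 4, names = FALSE, na.rm = FALSE)
}
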