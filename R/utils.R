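# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# All stochastic routines in the package funnel through this, so a single
# integer seed makes every result reproducible.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed: keeps derived seeds well below .Machine$integer.max
# even when users pass large master seeds.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483587L)
}

stopifnot_numeric <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("%s must be finite numeric values", what), call. = FALSE)
  }
  invisible(x)
}

# Asymptotic consistency factor for an alpha-truncated multivariate normal
# covariance (used by the raw MCD and by the 0.975 reweighting step).
mcd_consistency_factor <- function(alpha, d) {
  if (alpha >= 1) return(1)
  alpha / stats::pchisq(stats::qchisq(alpha, df = d), df = d + 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
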