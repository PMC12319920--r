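#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded helpers do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-series seed below 2^31, derived from a master seed and
# the series coordinates (rat, run, delta index, condition)
derive_seed <- function(master, rat, run, delta_idx, cond) {
  cond_code <- if (identical(cond, "stimulus")) 1L else 0L
  x <- (as.numeric(master) %% 2147483647) * 31 + rat
  x <- (x * 131 + run) %% 2147483647
  x <- (x * 131 + delta_idx) %% 2147483647
  x <- (x * 131 + cond_code) %% 2147483647
  as.integer(x %% 2147483562 + 1)
}
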