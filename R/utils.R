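# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. seed = NULL leaves
# the ambient stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), seed >= 0)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# validation failures carry a dedicated condition class so callers can
# distinguish bad input from programming errors
abort_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("ionferm_validation_error", "error"),
                      call = call))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("'%s' must be a single finite number", name))
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    abort_validation(sprintf("'%s' = %g is outside its valid range", name, x))
  invisible(x)
}
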