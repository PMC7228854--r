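# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (bootstraps,
#' SIMEX, the simulator) never disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 95% interval critical value; fixed at 1.96 (reporting convention, not qnorm)
Z95 <- 1.96

stop_mrb <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mrbattery_error")))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
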