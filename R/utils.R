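# Internal helpers shared across modules.

# Round half away from zero (so 1.5 -> 2), unlike base round()'s
# round-half-even. Split sizes use this rule.
.roundHalfUp <- function(x) floor(x + 0.5)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 1 && x == as.integer(x)

.isProb <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1
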