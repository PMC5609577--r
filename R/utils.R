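#' @keywords internal
"_PACKAGE"

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All exported simulation entry points take an explicit seed and funnel
## through this, so a single master seed makes every run reproducible.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a deterministic child seed from a master seed and a stage label,
## kept within 32-bit integer range. Gives each pipeline stage an
## independent, reproducible stream.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

## Sample skewness g1 = m3 / m2^(3/2); 0 for (near-)constant vectors.
sample_skewness <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) return(0)
  mean((x - m)^3) / m2^1.5
}
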