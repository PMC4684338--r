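# internal helpers

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL / NA leaves the global
# stream untouched (and advances it).
withSeed <- function(seed, expr) {
  if (is.null(seed) || length(seed) == 0 || is.na(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

deg2rad <- function(deg) deg * pi / 180

# trapezoidal integral of y over x
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
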