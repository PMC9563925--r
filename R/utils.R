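# Run code under a local RNG state: seeds deterministically, restores the
# caller's .Random.seed afterwards so simulation helpers do not clobber the
# session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and an index; stays inside the
# 32-bit signed range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483646L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Solve for the gamma shape whose median/mean ratio equals r (r in (0, 1)).
# Used to set per-class between-sample dispersion from published
# median and mean enumerations.
gamma_shape_from_median_mean <- function(r) {
  stopifnot(is.finite(r), r > 0)
  if (r >= 1) return(1e3) # essentially symmetric
  f <- function(s) stats::qgamma(0.5, shape = s) / s - r
  stats::uniroot(f, c(1e-3, 1e3), tol = 1e-9)$root
}
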