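#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All sampling entry points route through this so that identical (args, seed)
# produce bit-identical results regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Truncated-normal draws by inverse-CDF; exact for the mild truncations used
# by the generator (bounds are >= 3 sd from the mean or at +/- 4 sd).
rtruncnorm <- function(n, mean = 0, sd = 1, lo = -Inf, hi = Inf) {
  stopifnot(sd >= 0, lo < hi)
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lo), hi)  # guard qnorm round-off at extreme u
}

`%||%` <- function(a, b) if (is.null(a)) b else a
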