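## shared internal helpers

## two-sided normal p from a z statistic, floored away from exact 0
.z_pval <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

## run fun() under a fixed RNG seed, restoring the caller's RNG state;
## seed = NULL leaves the RNG stream alone
.with_seed <- function(seed, fun) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed))) return(fun())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  fun()
}

## derive a child seed (kept under 2^31) so one user seed drives several
## independent seeded sub-computations deterministically
.child_seed <- function(seed, offset) {
  if (is.null(seed) || is.na(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}

.stop_empty_instruments <- function(detail) {
  stop("empty instrument set: ", detail, call. = FALSE)
}

.stop_insufficient <- function(need, have, what) {
  stop(sprintf("insufficient instruments for %s: need >= %d, have %d",
               what, need, have), call. = FALSE)
}

## reverse complement for single-letter alleles (vectorized)
.revcomp <- function(a) chartr("ACGT", "TGCA", a)
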