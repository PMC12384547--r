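`%||%` <- function(a, b) if (is.null(a)) b else a

# seed the RNG for the calling function's scope, restoring the caller's RNG
# state when that scope exits so simulation helpers do not perturb the
# session stream
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  restore <- function() {
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
  do.call(base::on.exit,
          list(as.call(list(restore)), add = TRUE),
          envir = envir)
  set.seed(as.integer(seed))
  invisible(seed)
}

# round-half-up to `digits` decimals; base round() rounds half to even, but
# the clinical tables round 0.05 upward
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
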