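# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# HU values representable on the 12-bit CT scale.
HU_MIN <- -1024L
HU_MAX <- 3071L

assert_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) {
    stop(sprintf("`%s` must be a 2-D matrix", arg), call. = FALSE)
  }
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) {
    stop(sprintf("`%s` must contain only 0 and 1", arg), call. = FALSE)
  }
  invisible(TRUE)
}

as_mask <- function(x) {
  m <- matrix(as.integer(x != 0), nrow = nrow(x), ncol = ncol(x))
  m
}

mask_empty <- function(mask) sum(mask) == 0L

# TRUE when a is a subset of b (as pixel sets).
mask_subset <- function(a, b) all(a <= b)
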