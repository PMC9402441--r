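# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# go through this so that stages are reproducible in isolation.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Fixed per-stage offsets added to the master seed so each simulate_* /
# sampling stage consumes an independent, regenerable stream. Kept small so
# master seeds near 2^31 do not overflow (wrapped into integer range anyway).
stage_seed <- function(seed, stage) {
  offsets <- c(
    truth = 101L, counts = 202L, traces = 303L, barcodes = 404L,
    module_score = 505L, subsample = 606L, downsample = 707L,
    bootstrap = 808L
  )
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) + offsets[[stage]]) %% .Machine$integer.max)
}

# Unbiased row variances of a (possibly sparse) matrix.
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) stop("need at least 2 columns to compute variances")
  mu <- Matrix::rowMeans(m)
  (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
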