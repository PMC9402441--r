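# Small programmatic fixtures shared across test files.

# A hand-sized count container with known category structure.
toy_counts <- function() {
  m <- rbind(
    geneA     = c(3, 10, 0, 5),
    geneB     = c(0, 2, 0, 1),
    `mt-gene` = c(1, 3, 0, 2),
    `ERCC-1`  = c(4, 4, 0, 4),
    Rps9      = c(2, 0, 0, 1)
  )
  colnames(m) <- paste0("c", 1:4)
  live_counts(m, cell_meta = data.frame(
    cell_id = colnames(m), batch = "b1",
    uniquely_mapped_rate = c(0.9, 0.8, 0.5, 0.95)
  ))
}

# Wrap a dense matrix of log-normalized values as a norm_matrix.
as_norm <- function(values, scale_factor = 10000) {
  structure(
    list(values = methods::as(Matrix::Matrix(values, sparse = TRUE),
                              "CsparseMatrix"),
         scale_factor = scale_factor),
    class = "norm_matrix"
  )
}

# Noise-free simulation config: traces are exact exponentials and the
# calibration beads are exact, so trace fits must recover truth to float
# precision.
noiseless_config <- function(..., seed = 1) {
  sim_config(trace_noise_sd = 0, bead_noise_sd = 0, background_level = 0,
             lag_hours = 0, bead_factor = 1, seed = seed, ...)
}

# Independent straight-line OLS oracle from explicit sums of squares;
# deliberately a different code path from the package's fits.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2) - sx^2 / n
  syy <- sum(y^2) - sy^2 / n
  sxy <- sum(x * y) - sx * sy / n
  beta1 <- sxy / sxx
  beta0 <- sy / n - beta1 * sx / n
  r2 <- sxy^2 / (sxx * syy)
  f <- r2 * (n - 2) / (1 - r2)
  list(beta0 = beta0, beta1 = beta1, r2 = r2, f = f,
       p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# Independent Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Fresh temporary directory removed by the session's tempdir cleanup.
withr_like_tempdir <- function() {
  d <- tempfile("txrec")
  dir.create(d)
  d
}
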