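# Synthetic-data generator: determinism, planted structure, noise limits.

test_that("config validation rejects malformed inputs", {
  expect_error(sim_config(phase_probs = c(G1 = 0.5, S = 0.5, G2M = 0.1)),
               "sum to 1")
  expect_error(sim_config(trace_times = c(0, 1, 1)), "strictly increasing")
  expect_error(sim_config(nb_dispersion = 0))
})

test_that("simulation is bitwise reproducible under a fixed seed", {
  cfg <- sim_config(n_cells = 10L, n_genes = 200L, n_qc_fail_cells = 2L,
                    seed = 42)
  e1 <- simulate_recorder_experiment(cfg)
  e2 <- simulate_recorder_experiment(cfg)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$counts$counts, e2$counts$counts)
  expect_identical(traces_to_df(e1$traces), traces_to_df(e2$traces))
  bc1 <- simulate_barcodes(cfg, 5)
  bc2 <- simulate_barcodes(cfg, 5)
  expect_identical(bc1, bc2)
})

test_that("null configuration decouples slope from latents and phase", {
  cfg <- sim_config(n_cells = 1000L, n_qc_fail_cells = 0L,
                    effect_slope_neg = 0, effect_slope_neg_weak = 0,
                    effect_intercept_pos = 0, effect_s_phase = 0, seed = 3)
  tr <- simulate_truth(cfg)
  expect_lt(abs(cor(tr$cells$z1, tr$cells$true_slope)), 0.2)
  expect_lt(abs(cor(tr$cells$z2, tr$cells$true_slope)), 0.2)
  expect_lt(abs(cor(as.numeric(tr$cells$phase == "S"), tr$cells$true_slope)),
            0.2)
})

test_that("planted slope effect reaches its closed-form correlation", {
  # b = b0 + c*z1 + eps with c = -0.6, sd(eps) = 0.1:
  # corr(z1, b) = c / sqrt(c^2 + 0.01) = -0.986, well below -0.9
  cfg <- sim_config(n_cells = 1000L, n_qc_fail_cells = 0L,
                    effect_slope_neg = -0.6, effect_slope_neg_weak = 0,
                    effect_s_phase = 0, slope_noise_sd = 0.1, seed = 4)
  tr <- simulate_truth(cfg)
  expect_lt(cor(tr$cells$z1, tr$cells$true_slope), -0.9)
})

test_that("counts conserve per-cell library draws and gene roles partition", {
  cfg <- sim_config(n_cells = 20L, n_genes = 300L, n_qc_fail_cells = 3L,
                    seed = 5)
  tr <- simulate_truth(cfg)
  x <- simulate_counts(tr, cfg)
  expect_true(all(x$counts@x >= 0))
  expect_true(all(x$counts@x == round(x$counts@x)))
  expect_equal(nrow(x$counts), 300L)
  expect_equal(ncol(x$counts), 23L)
  # one role per gene
  expect_equal(anyDuplicated(tr$genes$gene_id), 0L)
  expect_true(all(table(tr$genes$gene_id) == 1L))
  # regenerating counts alone reproduces the same totals (stream isolation)
  x2 <- simulate_counts(tr, cfg)
  expect_identical(Matrix::colSums(x$counts), Matrix::colSums(x2$counts))
})

test_that("near-zero dispersion approaches the Poisson variance/mean limit", {
  cfg <- sim_config(n_cells = 500L, n_genes = 500L, n_qc_fail_cells = 0L,
                    nb_dispersion = 1e-9, library_size_log_sd = 0,
                    effect_slope_neg = 0, effect_slope_neg_weak = 0,
                    effect_intercept_pos = 0, marker_effect = 0, seed = 6)
  x <- simulate_counts(simulate_truth(cfg), cfg)
  bg <- x$gene_flags$gene_id[x$gene_flags$role == "background"]
  m <- x$counts[bg, ]
  mu <- Matrix::rowMeans(m)
  v <- (Matrix::rowSums(m^2) - ncol(m) * mu^2) / (ncol(m) - 1)
  ratio <- v[mu > 0.5] / mu[mu > 0.5]
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.25)
})

test_that("constructed contaminant cells violate the intended QC thresholds", {
  cfg <- sim_config(n_cells = 10L, n_genes = 300L, n_qc_fail_cells = 6L,
                    seed = 7)
  x <- simulate_counts(simulate_truth(cfg), cfg)
  qc <- compute_cell_qc(filter_genes(x))
  mode <- x$cell_meta$qc_fail_mode
  expect_true(all(qc$pct_mito[mode %in% "high_mito"] > 30))
  expect_true(all(qc$n_gene[mode %in% "low_ngene"] <= 1000))
  expect_true(all(qc$uniquely_mapped_rate[mode %in% "low_mapped"] < 0.30))
})

test_that("noiseless traces are exactly log-linear and non-negative", {
  cfg <- noiseless_config(n_cells = 5L, n_genes = 200L, n_qc_fail_cells = 0L)
  tr <- simulate_truth(cfg)
  traces <- simulate_traces(tr, cfg)
  for (i in seq_along(traces)) {
    trace <- traces[[i]]
    expect_true(all(trace$intensity >= cfg$background_level))
    keep <- trace$intensity > 0
    expect_equal(log(trace$intensity[keep]),
                 tr$cells$true_intercept[i] +
                   tr$cells$true_slope[i] * trace$time_h[keep],
                 tolerance = 1e-12)
  }
})

test_that("windowed fits on noiseless traces recover truth to 1e-9", {
  cfg <- sim_config(n_cells = 8L, n_genes = 200L, n_qc_fail_cells = 0L,
                    trace_noise_sd = 0, bead_noise_sd = 0, seed = 9)
  tr <- simulate_truth(cfg)
  profiles <- fit_response_profiles(simulate_traces(tr, cfg))
  expect_equal(profiles$intercept, tr$cells$true_intercept, tolerance = 1e-9)
  expect_equal(profiles$slope, tr$cells$true_slope, tolerance = 1e-9)
})

test_that("barcode observations reflect truth at the configured error rate", {
  cfg0 <- sim_config(barcode_error_rate = 0, seed = 10)
  bc0 <- simulate_barcodes(cfg0, 6)
  expect_true(all(bc0$pre$barcode ==
                    bc0$truth$barcode[match(bc0$pre$cell_id, bc0$truth$cell_id)]))

  cfg <- sim_config(barcode_error_rate = 0.01, seed = 11)
  bc <- simulate_barcodes(cfg, 10, n_obs = 12)
  cons_pre <- consensus_barcodes(bc$pre)
  cons_post <- consensus_barcodes(bc$post)
  expect_identical(unname(cons_pre[bc$truth$cell_id]), bc$truth$barcode)
  expect_identical(unname(cons_post[bc$truth$cell_id]), bc$truth$barcode)
  # paired consensus barcodes coincide
  expect_true(all(vapply(bc$truth$cell_id, function(id) {
    hamming_distance(cons_pre[[id]], cons_post[[id]])
  }, 0L) == 0L))
})
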