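# Per-gene predictive models, bootstrap significance, BH adjustment, ranking.

test_that("a perfect linear relationship fits exactly", {
  fit <- fit_gene_model(1:5, 2 * (1:5), gene_id = "g")
  expect_equal(fit$beta1, 2, tolerance = 1e-12)
  expect_equal(fit$beta0, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(fit$p_f, 0)
  expect_false(fit$skipped)
})

test_that("the four-point fit matches hand-computed normal equations", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  fit <- fit_gene_model(x, y)
  # by hand: Sxx = 5, Sxy = 3, Syy = 5 -> beta1 = 0.6, r2 = 9/25
  expect_equal(fit$beta1, 0.6, tolerance = 1e-12)
  expect_equal(fit$r2, 0.36, tolerance = 1e-12)
  expect_equal(fit$f_stat, 0.36 * 2 / 0.64, tolerance = 1e-12)
  o <- ols_oracle(x, y)
  expect_equal(fit$p_f, o$p, tolerance = 1e-12)
})

test_that("F-test p equals the two-sided t-test p for the slope (F = t^2)", {
  set.seed(51)
  for (i in 1:5) {
    x <- rnorm(12); y <- 0.4 * x + rnorm(12)
    fit <- fit_gene_model(x, y)
    sm <- summary(lm(y ~ x))
    expect_equal(fit$p_f, sm$coefficients["x", "Pr(>|t|)"], tolerance = 1e-12)
    expect_equal(fit$f_stat, sm$coefficients["x", "t value"]^2,
                 tolerance = 1e-10)
  }
})

test_that("degenerate predictors and responses follow the contracts", {
  skipped <- fit_gene_model(rep(2, 6), rnorm(6), gene_id = "flat")
  expect_true(skipped$skipped)
  expect_match(skipped$skip_reason, "constant predictor")
  const_y <- fit_gene_model(1:6, rep(1, 6))
  expect_equal(const_y$r2, 0)
  expect_equal(const_y$p_f, 1)
  expect_error(fit_gene_model(1:3, 1:3), "at least 4")
})

test_that("implementation matches an independent OLS oracle on random instances", {
  set.seed(52)
  max_rel <- 0
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(1) * x + rnorm(n)
    fit <- fit_gene_model(x, y)
    o <- ols_oracle(x, y)
    rel <- function(a, b) abs(a - b) / max(abs(b), 1e-12)
    max_rel <- max(max_rel, rel(fit$beta1, o$beta1), rel(fit$r2, o$r2),
                   rel(fit$f_stat, o$f), rel(fit$p_f, o$p))
  }
  expect_lt(max_rel, 1e-10)
})

test_that("a forced-sign association gives the minimal bootstrap p", {
  x <- 1:10
  p <- bootstrap_empirical_p(x, 2 * x, B = 500, seed = 1)
  expect_equal(p, 2 / 501, tolerance = 1e-12)
})

test_that("bootstrap resampling is position-indexed (documented contract)", {
  set.seed(53)
  x <- rnorm(20); y <- rnorm(20)
  p1 <- bootstrap_empirical_p(x, y, B = 200, seed = 9)
  expect_identical(p1, bootstrap_empirical_p(x, y, B = 200, seed = 9))
  # same pairs, same seed, permuted cell order: resampling indexes by
  # position, so the replicate sets differ and the p-value is NOT invariant
  perm <- sample(20)
  p2 <- bootstrap_empirical_p(x[perm], y[perm], B = 200, seed = 9)
  expect_false(identical(p1, p2))
  expect_true(p2 > 0 && p2 <= 1)
})

test_that("a nearly constant predictor exhausts bootstrap retries", {
  set.seed(55)
  x <- c(1, rep(0, 29))
  y <- rnorm(30)
  expect_error(bootstrap_empirical_p(x, y, B = 100, seed = 2, max_retry = 0L),
               "nearly constant")
})

test_that("BH adjustment matches the step-up oracle and validates input", {
  p <- c(0.01, 0.04, 0.03, 0.002)
  expect_equal(bh_adjust(p), c(0.02, 0.04, 0.04, 0.008), tolerance = 1e-12)
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  set.seed(54)
  pr <- runif(100)
  expect_equal(bh_adjust(pr), bh_oracle(pr), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(0.37, 5)), rep(0.37, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("ranking orders by r2 with deterministic ties and skip handling", {
  fits <- rbind(
    fit_gene_model(1:6, c(1, 2, 3, 4, 5, 6) + c(0, .1, -.1, 0, .1, -.1), "gMid"),
    fit_gene_model(1:6, 2 * (1:6), "gTop"),
    fit_gene_model(rep(1, 6), rnorm(6), "gSkip"),
    fit_gene_model(1:6, rnorm(6), "gLow")
  )
  tab <- rank_genes(fits)
  expect_identical(tab$gene_id[1], "gTop")
  expect_identical(tab$rank[tab$gene_id == "gTop"], 1L)
  expect_true(is.na(tab$rank[tab$gene_id == "gSkip"]))
  ranked <- tab[!tab$skipped, ]
  expect_true(all(diff(ranked$r2) <= 1e-12))
  expect_identical(ranked$rank, seq_len(nrow(ranked)))
  expect_error(rank_genes(fits[fits$skipped, , drop = FALSE]), "skipped")
})

test_that("candidate selection unions HVG lists and applies the strict floor", {
  disp <- c(a = 0.5, b = 0.099, c = 0.1, d = 2, e = 0.0999999)
  cand <- select_candidates(c("a", "b", "c"), c("c", "d", "e"), disp)
  expect_identical(cand$gene_id, c("a", "c", "d"))  # b, e below 0.1
  expect_identical(cand$provenance, c("hvg_live", "both", "hvg_reference"))
  # disjoint lists -> union size; identical lists -> same size
  disp2 <- setNames(rep(1, 6), letters[1:6])
  expect_equal(nrow(select_candidates(letters[1:3], letters[4:6], disp2)), 6L)
  expect_equal(nrow(select_candidates(letters[1:3], letters[1:3], disp2)), 3L)
  expect_identical(
    select_candidates(letters[1:4], letters[3:6], disp2,
                      mode = "intersection")$gene_id,
    c("c", "d")
  )
  # empty result (all below floor, or empty intersection) is an error
  expect_error(select_candidates(letters[1:3], letters[4:6], disp2,
                                 mode = "intersection"))
  expect_error(select_candidates("b", "e", disp), "dispersion filter")
})

test_that("ranking tables survive a CSV round trip", {
  cfg <- sim_config(n_cells = 20L, n_genes = 300L, n_qc_fail_cells = 0L,
                    seed = 55)
  e <- simulate_recorder_experiment(cfg)
  kept <- filter_genes(e$counts)
  norm <- lognormalize(kept)
  prof <- fit_response_profiles(e$traces)
  hvg <- select_hvg(vst_standardized_variance(kept), 50)
  cand <- select_candidates(hvg, hvg, gene_dispersion(norm),
                            min_dispersion = 0)
  tab <- rank_recorder_genes(norm, prof, cand, response = "slope", B = 100,
                             seed = 3)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f)
  for (col in c("beta1", "r2", "p_f", "p_boot", "fdr_f", "fdr_boot")) {
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-10)
  }
  expect_identical(back$gene_id, tab$gene_id)
})
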