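# Synthetic recorder-experiment generator. Every stochastic stage draws from
# its own stream derived from the master seed, so stages can be regenerated
# independently and the whole experiment is bitwise reproducible.

gene_roles_table <- function(cfg) {
  n <- cfg$n_genes
  roles <- c(
    predictor_slope_neg = 1L, predictor_slope_neg_weak = 1L,
    predictor_intercept_pos = 1L,
    s_marker = 20L, g2m_marker = 20L,
    mito = 13L, ercc = 20L, ribosomal = 20L, blacklist = 10L
  )
  n_special <- sum(roles)
  if (n < n_special + 50L) stop("n_genes too small for the role layout")
  ids <- c(
    "PredSlopeStrong", "PredSlopeWeak", "PredIntercept",
    sprintf("Smarker%02d", seq_len(roles[["s_marker"]])),
    sprintf("G2mMarker%02d", seq_len(roles[["g2m_marker"]])),
    sprintf("mt-Sim%02d", seq_len(roles[["mito"]])),
    sprintf("ERCC-%05d", seq_len(roles[["ercc"]])),
    sprintf("Rp%sSim%02d", rep(c("s", "l"), length.out = roles[["ribosomal"]]),
            seq_len(roles[["ribosomal"]])),
    sprintf("NegCtrl%02d", seq_len(roles[["blacklist"]])),
    sprintf("Gene%05d", seq_len(n - n_special))
  )
  role <- c(rep(names(roles), times = roles), rep("background", n - n_special))
  data.frame(gene_id = ids, role = role, stringsAsFactors = FALSE)
}

#' Simulate the latent ground truth of a recorder cohort
#'
#' Draws, per cell, the latent predictor scores, cell-cycle phase and the
#' true response parameters (intercept `a`, the basal reporter expression,
#' and slope `b`, the extent of the response), and assigns every gene a role
#' (planted predictors, phase markers, mitochondrial/spike-in/ribosomal/
#' blacklist categories, background) with its planted effect size.
#'
#' The slope is `b = b0 + effect_slope_neg*z1 + effect_slope_neg_weak*z2 +
#' effect_s_phase*[phase == S] + eps_b` and the intercept is
#' `a = a0 + effect_intercept_pos*z3 + eps_a`, with `z1, z2, z3` independent
#' standard normals.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_truth`: list with `cells` (per-cell truth,
#'   including the QC-failure mode planted for contaminant cells), `genes`
#'   (per-gene role and effect size) and the `config`.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  genes <- gene_roles_table(config)
  genes$effect <- 0
  genes$effect[genes$role == "predictor_slope_neg"] <- config$effect_slope_neg
  genes$effect[genes$role == "predictor_slope_neg_weak"] <- config$effect_slope_neg_weak
  genes$effect[genes$role == "predictor_intercept_pos"] <- config$effect_intercept_pos
  genes$effect[genes$role %in% c("s_marker", "g2m_marker")] <- config$marker_effect

  n_total <- config$n_cells + config$n_qc_fail_cells
  cells <- with_seed(stage_seed(config$seed, "truth"), {
    z1 <- stats::rnorm(n_total)
    z2 <- stats::rnorm(n_total)
    z3 <- stats::rnorm(n_total)
    phase <- sample(c("G1", "S", "G2M"), n_total, replace = TRUE,
                    prob = config$phase_probs[c("G1", "S", "G2M")])
    eps_a <- stats::rnorm(n_total, 0, config$intercept_noise_sd)
    eps_b <- stats::rnorm(n_total, 0, config$slope_noise_sd)
    b <- config$base_slope + config$effect_slope_neg * z1 +
      config$effect_slope_neg_weak * z2 +
      config$effect_s_phase * (phase == "S") + eps_b
    a <- config$base_intercept + config$effect_intercept_pos * z3 + eps_a
    fail_modes <- c("high_mito", "low_ngene", "low_mapped")
    qc_fail_mode <- rep(NA_character_, n_total)
    if (config$n_qc_fail_cells > 0L) {
      idx <- config$n_cells + seq_len(config$n_qc_fail_cells)
      qc_fail_mode[idx] <- fail_modes[(seq_along(idx) - 1L) %% 3L + 1L]
    }
    data.frame(
      cell_id = sprintf("cell%03d", seq_len(n_total)),
      z1 = z1, z2 = z2, z3 = z3, phase = phase,
      true_intercept = a, true_slope = b,
      qc_fail_mode = qc_fail_mode,
      stringsAsFactors = FALSE
    )
  })
  structure(list(cells = cells, genes = genes, config = config),
            class = "sim_truth")
}

#' Simulate a ground-state count matrix with planted structure
#'
#' Per-cell totals are drawn log-normally and reads are distributed over
#' genes by a single multinomial draw per cell, with gamma-mixed gene weights
#' giving negative-binomial-like overdispersion (`nb_dispersion` is the gamma
#' variance; near 0 the draw approaches the Poisson/multinomial limit).
#' Planted predictor genes' log-weights shift linearly with the matching
#' latent score; S/G2M marker genes are elevated in cells of the matching
#' phase; mitochondrial genes carry a high baseline so the mitochondrial
#' percentage is realistic. Contaminant cells are forced to violate one QC
#' threshold each: mitochondrial weight inflated to about half the library,
#' a library too small to detect 1,000 genes, or a low uniquely-mapped rate
#' recorded in the cell metadata.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The same [sim_config()] used for the truth.
#' @return A [live_counts()] object whose `cell_meta` carries `batch`,
#'   `uniquely_mapped_rate` and `phase_truth`.
#' @export
simulate_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  validate_sim_config(config)
  genes <- truth$genes
  cells <- truth$cells
  n_g <- nrow(genes)
  n_c <- nrow(cells)

  with_seed(stage_seed(config$seed, "counts"), {
    base_log_mu <- stats::rnorm(n_g, 0, config$gene_log_mean_sd)
    # anchor special categories at realistic relative abundances
    base_log_mu[genes$role %in% c(
      "predictor_slope_neg", "predictor_slope_neg_weak",
      "predictor_intercept_pos", "s_marker", "g2m_marker"
    )] <- stats::rnorm(sum(genes$role %in% c(
      "predictor_slope_neg", "predictor_slope_neg_weak",
      "predictor_intercept_pos", "s_marker", "g2m_marker"
    )), 1.5, 0.3)
    base_log_mu[genes$role == "mito"] <- stats::rnorm(sum(genes$role == "mito"), 4, 0.3)
    base_log_mu[genes$role == "ercc"] <- stats::rnorm(sum(genes$role == "ercc"), 1, 0.5)

    lib <- round(stats::rlnorm(n_c, config$library_size_log_mean,
                               config$library_size_log_sd))
    lib <- pmax(lib, 100)
    mapped <- stats::runif(n_c, 0.75, 0.98)

    fail <- cells$qc_fail_mode
    lib[!is.na(fail) & fail == "low_ngene"] <- 400
    mapped[!is.na(fail) & fail == "low_mapped"] <- stats::runif(
      sum(!is.na(fail) & fail == "low_mapped"), 0.05, 0.25)

    i_pred1 <- which(genes$role == "predictor_slope_neg")
    i_pred2 <- which(genes$role == "predictor_slope_neg_weak")
    i_pred3 <- which(genes$role == "predictor_intercept_pos")
    i_smark <- which(genes$role == "s_marker")
    i_gmark <- which(genes$role == "g2m_marker")
    i_mito <- which(genes$role == "mito")

    shape <- 1 / config$nb_dispersion
    use_gamma <- config$nb_dispersion > 1e-8

    cols <- vector("list", n_c)
    for (c_i in seq_len(n_c)) {
      log_w <- base_log_mu
      log_w[i_pred1] <- log_w[i_pred1] + config$expression_coupling * cells$z1[c_i]
      log_w[i_pred2] <- log_w[i_pred2] + config$expression_coupling * cells$z2[c_i]
      log_w[i_pred3] <- log_w[i_pred3] + config$expression_coupling * cells$z3[c_i]
      if (cells$phase[c_i] == "S") {
        log_w[i_smark] <- log_w[i_smark] + config$marker_effect
      }
      if (cells$phase[c_i] == "G2M") {
        log_w[i_gmark] <- log_w[i_gmark] + config$marker_effect
      }
      w <- exp(log_w)
      if (use_gamma) w <- w * stats::rgamma(n_g, shape = shape, rate = shape)
      if (!is.na(fail[c_i]) && fail[c_i] == "high_mito") {
        # inflate mitochondrial weight to ~50% of the library
        w[i_mito] <- w[i_mito] * sum(w[-i_mito]) / sum(w[i_mito])
      }
      cols[[c_i]] <- stats::rmultinom(1, lib[c_i], w)[, 1]
    }
    m <- do.call(cbind, cols)
    dimnames(m) <- list(genes$gene_id, cells$cell_id)

    gene_flags <- data.frame(
      gene_id = genes$gene_id,
      is_mito = genes$role == "mito",
      is_ercc = genes$role == "ercc",
      is_ribosomal = genes$role == "ribosomal",
      is_blacklist = genes$role == "blacklist",
      role = genes$role,
      stringsAsFactors = FALSE
    )
    cell_meta <- data.frame(
      cell_id = cells$cell_id,
      batch = "sim1",
      uniquely_mapped_rate = mapped,
      phase_truth = cells$phase,
      qc_fail_mode = cells$qc_fail_mode,
      stringsAsFactors = FALSE
    )
    live_counts(m, gene_flags = gene_flags, cell_meta = cell_meta)
  })
}

#' Simulate calibrated reporter time courses
#'
#' Intensity follows `background + bead_factor * ramp(t) * exp(a + b*t + eps)`
#' with i.i.d. Gaussian log-noise `eps` and a saturating lag ramp
#' `ramp(t) = min(t / lag_hours, 1)` (identically 1 when `lag_hours = 0`), so
#' the log trace is linear only at and beyond the lag — inside the analysis
#' window by construction.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The matching [sim_config()].
#' @return A named list of [fluor_trace()] objects (one per cell) with an
#'   attribute `bead_intensities`, the simulated calibration-bead readings
#'   whose mean is each trace's `bead_mean`.
#' @export
simulate_traces <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  validate_sim_config(config)
  cells <- truth$cells
  tt <- config$trace_times
  with_seed(stage_seed(config$seed, "traces"), {
    beads <- config$bead_factor + stats::rnorm(config$n_beads, 0, config$bead_noise_sd)
    bead_mean <- mean(beads)
    ramp <- if (config$lag_hours == 0) rep(1, length(tt)) else pmin(tt / config$lag_hours, 1)
    traces <- lapply(seq_len(nrow(cells)), function(i) {
      eps <- stats::rnorm(length(tt), 0, config$trace_noise_sd)
      intensity <- config$background_level + config$bead_factor * ramp *
        exp(cells$true_intercept[i] + cells$true_slope[i] * tt + eps)
      fluor_trace(
        cell_id = cells$cell_id[i], time_h = tt, intensity = intensity,
        background = rep(config$background_level, length(tt)),
        bead_mean = bead_mean
      )
    })
    names(traces) <- cells$cell_id
    attr(traces, "bead_intensities") <- beads
    traces
  })
}

#' Simulate paired pre/post barcode observations
#'
#' Each tracked cell carries one true barcode shared between its pre- and
#' post-transition observation sets; every observed read is the true barcode
#' with independent per-base substitutions at `barcode_error_rate`.
#'
#' @param config A [sim_config()].
#' @param n_pairs Number of tracked cells.
#' @param n_obs Observations per cell per side (default 12).
#' @return List with `truth` (cell_id, barcode), and long data.frames `pre`
#'   and `post` of observations (cell_id, barcode).
#' @export
simulate_barcodes <- function(config, n_pairs, n_obs = 12L) {
  validate_sim_config(config)
  stopifnot(n_pairs >= 1L, n_obs >= 1L)
  bases <- c("A", "C", "G", "T")
  with_seed(stage_seed(config$seed, "barcodes"), {
    truth_mat <- matrix(sample(bases, n_pairs * config$barcode_length,
                               replace = TRUE),
                        nrow = n_pairs)
    truth_bc <- apply(truth_mat, 1, paste0, collapse = "")
    ids <- sprintf("pair%03d", seq_len(n_pairs))
    observe <- function() {
      do.call(rbind, lapply(seq_len(n_pairs), function(i) {
        obs <- vapply(seq_len(n_obs), function(o) {
          b <- truth_mat[i, ]
          err <- stats::runif(config$barcode_length) < config$barcode_error_rate
          if (any(err)) {
            b[err] <- vapply(b[err], function(x) sample(setdiff(bases, x), 1), "")
          }
          paste0(b, collapse = "")
        }, "")
        data.frame(cell_id = ids[i], barcode = obs, stringsAsFactors = FALSE)
      }))
    }
    list(
      truth = data.frame(cell_id = ids, barcode = truth_bc,
                         stringsAsFactors = FALSE),
      pre = observe(),
      post = observe()
    )
  })
}

#' Simulate a complete recorder experiment
#'
#' Convenience wrapper drawing truth, counts and traces under one config.
#'
#' @param config A [sim_config()].
#' @return List with `truth`, `counts`, `traces` and `config`.
#' @export
simulate_recorder_experiment <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  list(
    truth = truth,
    counts = simulate_counts(truth, config),
    traces = simulate_traces(truth, config),
    config = config
  )
}
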