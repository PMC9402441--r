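#' Configuration for the synthetic recorder experiment
#'
#' Defines the generative conditions for a synthetic transcriptomic-recording
#' cohort: a small set of cells whose ground-state counts are profiled before
#' stimulation, whose reporter intensity then rises exponentially in time
#' (linear in log within the analysis window), and in which a handful of
#' planted genes and the cell-cycle S phase causally shape the per-cell
#' response slope and intercept.
#'
#' Response-parameter model per cell i (see [simulate_truth()]):
#' \deqn{b_i = b_0 + \beta_{neg} z_{1i} + \beta_{weak} z_{2i} +
#'       \beta_S 1[phase_i = S] + \epsilon_b}
#' \deqn{a_i = a_0 + \beta_{int} z_{3i} + \epsilon_a}
#' with latent standard-normal cell scores \eqn{z}. The planted predictor
#' genes' count means shift log-linearly with the matching latent score, so
#' ground-state expression carries the predictive signal.
#'
#' @param n_cells Number of cells passing quality control (default 17, the
#'   size of a realistic recorder cohort for this assay).
#' @param n_genes Number of genes in the matrix (default 2000).
#' @param n_qc_fail_cells Number of additional contaminant cells constructed
#'   to fail at least one QC threshold (default 23, so the default cohort is
#'   17 usable cells out of 40 tracked).
#' @param library_size_log_mean,library_size_log_sd Log-normal parameters of
#'   per-cell total counts.
#' @param nb_dispersion Negative-binomial overdispersion of counts
#'   (gamma-mixture variance; values near 0 approach the Poisson limit).
#' @param gene_log_mean_sd Spread (natural-log scale) of per-gene baseline
#'   abundances.
#' @param effect_slope_neg Planted coefficient linking latent score z1 to the
#'   response slope; negative: high expression of the strong predictor gene
#'   marks weak responders.
#' @param effect_slope_neg_weak Weaker negative z2 -> slope coefficient.
#' @param effect_intercept_pos Positive z3 -> intercept coefficient.
#' @param effect_s_phase Slope decrement applied to S-phase cells. The
#'   default (-0.75) puts roughly a fifth of the slope variance on the cell
#'   cycle, the magnitude of the reported S-score association.
#' @param expression_coupling Log-mean shift per latent-score unit applied to
#'   the planted predictor genes' counts.
#' @param marker_effect Log-mean elevation of S/G2M marker genes in cells of
#'   the matching phase.
#' @param base_intercept,base_slope Baseline response intercept (ln intensity
#'   units) and slope (per hour).
#' @param intercept_noise_sd,slope_noise_sd Gaussian noise on the per-cell
#'   true intercept/slope.
#' @param phase_probs Named 3-simplex over `c(G1, S, G2M)`.
#' @param trace_times Imaging time grid in hours after stimulation.
#' @param trace_noise_sd Log-normal multiplicative noise sd on intensities.
#' @param lag_hours Duration of the pre-linear lag ramp (hours). The log
#'   trace is linear only for `t >= lag_hours`, which is what makes the
#'   analysis-window restriction matter.
#' @param bead_factor Calibration-bead intensity scale.
#' @param bead_noise_sd Gaussian sd of individual bead intensities.
#' @param n_beads Number of calibration beads imaged.
#' @param background_level Constant imaging background intensity.
#' @param barcode_length Tracking-barcode length (nt).
#' @param barcode_error_rate Per-base substitution probability in barcode
#'   observations.
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [sim_config_depth()] for presets that emulate the detected-gene
#'   depth of shallow biopsy-based and deep whole-cell assays.
#' @export
sim_config <- function(n_cells = 17L,
                       n_genes = 2000L,
                       n_qc_fail_cells = 23L,
                       library_size_log_mean = log(60000),
                       library_size_log_sd = 0.25,
                       nb_dispersion = 0.15,
                       gene_log_mean_sd = 1.5,
                       effect_slope_neg = -0.6,
                       effect_slope_neg_weak = -0.3,
                       effect_intercept_pos = 0.5,
                       effect_s_phase = -0.75,
                       expression_coupling = 1.0,
                       marker_effect = 1.5,
                       base_intercept = 1.0,
                       base_slope = 0.5,
                       intercept_noise_sd = 0.1,
                       slope_noise_sd = 0.1,
                       phase_probs = c(G1 = 0.5, S = 0.3, G2M = 0.2),
                       trace_times = seq(0, 10, by = 0.5),
                       trace_noise_sd = 0.05,
                       lag_hours = 2,
                       bead_factor = 100,
                       bead_noise_sd = 2,
                       n_beads = 30L,
                       background_level = 50,
                       barcode_length = 20L,
                       barcode_error_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    n_qc_fail_cells = as.integer(n_qc_fail_cells),
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    nb_dispersion = nb_dispersion,
    gene_log_mean_sd = gene_log_mean_sd,
    effect_slope_neg = effect_slope_neg,
    effect_slope_neg_weak = effect_slope_neg_weak,
    effect_intercept_pos = effect_intercept_pos,
    effect_s_phase = effect_s_phase,
    expression_coupling = expression_coupling,
    marker_effect = marker_effect,
    base_intercept = base_intercept, base_slope = base_slope,
    intercept_noise_sd = intercept_noise_sd,
    slope_noise_sd = slope_noise_sd,
    phase_probs = phase_probs,
    trace_times = trace_times,
    trace_noise_sd = trace_noise_sd,
    lag_hours = lag_hours,
    bead_factor = bead_factor, bead_noise_sd = bead_noise_sd,
    n_beads = as.integer(n_beads),
    background_level = background_level,
    barcode_length = as.integer(barcode_length),
    barcode_error_rate = barcode_error_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_cells >= 1L, cfg$n_genes >= 150L, cfg$n_qc_fail_cells >= 0L,
    cfg$nb_dispersion > 0, cfg$gene_log_mean_sd > 0,
    cfg$library_size_log_sd >= 0,
    cfg$intercept_noise_sd >= 0, cfg$slope_noise_sd >= 0,
    cfg$trace_noise_sd >= 0, cfg$lag_hours >= 0,
    cfg$bead_factor > 0, cfg$bead_noise_sd >= 0, cfg$n_beads >= 1L,
    cfg$background_level >= 0,
    cfg$barcode_length >= 1L,
    cfg$barcode_error_rate >= 0, cfg$barcode_error_rate < 1
  )
  if (length(cfg$phase_probs) != 3L ||
      !setequal(names(cfg$phase_probs), c("G1", "S", "G2M"))) {
    stop("phase_probs must be named over G1, S, G2M")
  }
  if (abs(sum(cfg$phase_probs) - 1) > 1e-12) {
    stop("phase_probs must sum to 1")
  }
  if (any(cfg$phase_probs < 0)) stop("phase_probs must be non-negative")
  tt <- cfg$trace_times
  if (length(tt) < 2L || any(diff(tt) <= 0)) {
    stop("trace_times must be strictly increasing with at least 2 points")
  }
  invisible(cfg)
}

#' Depth presets emulating shallow and deep single-cell assays
#'
#' Returns a [sim_config()] whose library sizes were calibrated so that the
#' simulated matrices reach the typical per-cell sensitivity of the two
#' assays being compared: a shallow cytoplasmic-biopsy profile detecting
#' roughly 4,100 genes per cell and a deep whole-cell profile detecting
#' roughly 8,300 genes per cell, both over a 12,000-gene annotation.
#'
#' @param profile `"shallow"` (biopsy-like) or `"deep"` (whole-cell-like).
#' @param n_cells Number of cells (default 500, the paired-fixture size).
#' @param seed Master seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_depth <- function(profile = c("shallow", "deep"),
                             n_cells = 500L, seed = 1L, ...) {
  profile <- match.arg(profile)
  lib_log_mean <- switch(profile,
    shallow = log(5e4),
    deep = log(7e5)
  )
  sim_config(
    n_cells = n_cells, n_genes = 12000L, n_qc_fail_cells = 0L,
    library_size_log_mean = lib_log_mean, library_size_log_sd = 0.25,
    gene_log_mean_sd = 2.5,
    seed = seed, ...
  )
}
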