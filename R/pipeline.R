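# End-to-end orchestration: simulate (or load) -> gene/cell QC -> normalize
# -> HVG/dispersion -> trace fitting -> recorder ranking -> cell-cycle
# scoring, with seeded determinism and a written-artifact manifest.

#' Flatten traces to a long data.frame (and back)
#'
#' CSV-friendly long format: one row per (cell, timepoint) with the raw
#' intensity, the per-timepoint background and the bead mean.
#'
#' @param traces Named list of [fluor_trace()] objects.
#' @return data.frame with `cell_id`, `time_h`, `intensity`, `background`,
#'   `bead_mean`.
#' @export
traces_to_df <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, time_h = tr$time_h,
               intensity = tr$intensity, background = tr$background,
               bead_mean = tr$bead_mean, stringsAsFactors = FALSE)
  }))
}

#' @rdname traces_to_df
#' @param df A data.frame in the long format written by [traces_to_df()].
#' @export
traces_from_df <- function(df) {
  stopifnot(all(c("cell_id", "time_h", "intensity", "background", "bead_mean")
                %in% names(df)))
  ids <- unique(df$cell_id)
  traces <- lapply(ids, function(id) {
    d <- df[df$cell_id == id, , drop = FALSE]
    d <- d[order(d$time_h), , drop = FALSE]
    fluor_trace(id, d$time_h, d$intensity, d$background, d$bead_mean[1])
  })
  names(traces) <- ids
  traces
}

#' Pipeline configuration
#'
#' Collects every stage threshold at its standard default: QC thresholds
#' (`min_genes` 1000, `max_pct_mito` 30, `min_mapped` 0.30), normalization
#' `scale_factor` 10000, `hvg_k` 500, candidate `min_dispersion` 0.1, the
#' response-fit `window` (3, 7.5) hours, bootstrap replicates `B` 1000,
#' down-sampling `tolerance` 5, and module-score parameters (`n_bins` 24,
#' `n_ctrl` 100). Unknown keys are rejected.
#'
#' @param sim A [sim_config()] describing the synthetic experiment to
#'   generate (the pipeline's input when no external data is supplied).
#' @param out_dir Output directory; `NULL` (default) keeps everything in
#'   memory and writes nothing.
#' @param response Response parameter to rank against: `"slope"`,
#'   `"intercept"` or `"both"` (default).
#' @param seed Master pipeline seed (also overrides `sim$seed`).
#' @param ... Overrides for the named defaults above.
#' @return A list of class `recorder_config`.
#' @export
recorder_config <- function(sim = sim_config(), out_dir = NULL,
                            response = c("both", "slope", "intercept"),
                            seed = 1L, ...) {
  response <- match.arg(response)
  cfg <- list(
    sim = sim, out_dir = out_dir, response = response, seed = as.integer(seed),
    min_genes = 1000, max_pct_mito = 30, min_mapped = 0.30,
    scale_factor = 10000, hvg_k = 500, min_dispersion = 0.1,
    window = c(3.0, 7.5), B = 1000, tolerance = 5,
    n_bins = 24, n_ctrl = 100, blacklist = character(0)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg$sim$seed <- cfg$seed
  class(cfg) <- "recorder_config"
  cfg
}

#' Run the full recorder pipeline
#'
#' Stages, in order: simulate the experiment (unless `experiment` is
#' supplied), remove spike-in/ribosomal/blacklisted genes, compute cell QC
#' and apply the three strict filters, log-normalize, compute vst
#' standardized variance and select HVGs, compute dispersions, calibrate and
#' fit the reporter traces in the analysis window, assemble the candidate
#' set, rank genes against the requested response parameter(s), and score
#' the cell cycle with the simulation's own marker sets. When `out_dir` is
#' set, every table is written (counts as MatrixMarket + sidecars, the rest
#' as CSV) and a manifest of file hashes is returned.
#'
#' @param config A [recorder_config()].
#' @param experiment Optional pre-built experiment (list with `truth`,
#'   `counts`, `traces`), e.g. from [simulate_recorder_experiment()];
#'   defaults to simulating from `config$sim`.
#' @param hvg_reference Optional HVG list from a deeper reference dataset;
#'   defaults to the recorder data's own HVGs (candidate set = HVG list).
#' @return List with `qc`, `keep`, `profiles`, `variability`, `hvg`,
#'   `dispersion`, `candidates`, `ranking` (named by response), `cellcycle`,
#'   `log` (per-stage counts) and `manifest` (file, md5; empty when nothing
#'   is written).
#' @export
run_recorder_pipeline <- function(config = recorder_config(),
                                  experiment = NULL,
                                  hvg_reference = NULL) {
  stopifnot(inherits(config, "recorder_config"))
  if (is.null(experiment)) {
    experiment <- simulate_recorder_experiment(config$sim)
  }
  counts <- experiment$counts
  log <- list(seed = config$seed,
              genes_in = nrow(counts$counts), cells_in = ncol(counts$counts))

  counts <- filter_genes(counts, blacklist = config$blacklist)
  log$genes_kept <- nrow(counts$counts)

  qc <- compute_cell_qc(counts)
  keep <- filter_cells(qc, min_genes = config$min_genes,
                       max_pct_mito = config$max_pct_mito,
                       min_mapped = config$min_mapped)
  qc$pass <- as.logical(keep)
  if (!any(keep)) stop("no cells pass QC")
  log$cells_kept <- sum(keep)
  kept <- subset_counts(counts, cells = which(keep))

  norm <- lognormalize(kept, scale_factor = config$scale_factor)
  variability <- vst_standardized_variance(kept)
  hvg <- select_hvg(variability, k = min(config$hvg_k, nrow(variability)))
  dispersion <- gene_dispersion(norm)

  traces <- experiment$traces[names(keep)[keep]]
  profiles <- fit_response_profiles(traces, window = config$window)

  candidates <- select_candidates(
    hvg_live = hvg,
    hvg_reference = hvg_reference %||% hvg,
    dispersion_live = dispersion,
    min_dispersion = config$min_dispersion
  )
  log$n_candidates <- nrow(candidates)

  responses <- if (config$response == "both") c("slope", "intercept")
               else config$response
  ranking <- lapply(responses, function(r) {
    rank_recorder_genes(norm, profiles, candidates, response = r,
                        B = config$B, seed = config$seed)
  })
  names(ranking) <- responses

  truth_genes <- experiment$truth$genes
  cellcycle <- score_cell_cycle(
    norm,
    s_genes = truth_genes$gene_id[truth_genes$role == "s_marker"],
    g2m_genes = truth_genes$gene_id[truth_genes$role == "g2m_marker"],
    n_bins = config$n_bins, n_ctrl = config$n_ctrl,
    seed = stage_seed(config$seed, "module_score")
  )

  manifest <- data.frame(file = character(0), md5 = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- write_live_counts(kept, file.path(config$out_dir, "counts"))
    wr <- function(df, name) {
      p <- file.path(config$out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    paths <- c(
      paths,
      wr(qc, "qc_report.csv"),
      wr(profiles, "response_profiles.csv"),
      wr(traces_to_df(traces), "traces.csv"),
      wr(variability, "gene_variability.csv"),
      wr(data.frame(gene_id = names(dispersion), dispersion = dispersion,
                    row.names = NULL), "dispersion.csv"),
      wr(candidates, "candidates.csv"),
      unlist(lapply(responses, function(r) {
        wr(ranking[[r]], paste0("ranking_", r, ".csv"))
      })),
      wr(cellcycle, "cellcycle_scores.csv")
    )
    manifest <- data.frame(
      file = basename(paths),
      md5 = unname(tools::md5sum(paths)),
      stringsAsFactors = FALSE
    )
  }

  list(qc = qc, keep = keep, profiles = profiles, variability = variability,
       hvg = hvg, dispersion = dispersion, candidates = candidates,
       ranking = ranking, cellcycle = cellcycle, log = log,
       manifest = manifest)
}
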