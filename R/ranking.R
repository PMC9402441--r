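# Core of the package: rank ground-state genes by how well each one, alone,
# predicts a per-cell response parameter (slope or intercept of the windowed
# log-linear reporter fit) via simple linear models, with F-test and
# bootstrap significance, both BH-corrected.

#' Assemble the candidate gene set for the recorder ranking
#'
#' Combines the top highly variable genes of the (shallow) recorder dataset
#' and of a deeper reference dataset — by default their union — and removes
#' genes whose dispersion in the recorder data falls below `min_dispersion`
#' (strictly; a gene at exactly the threshold is retained). The result is
#' sorted by gene id for determinism.
#'
#' @param hvg_live,hvg_reference Character vectors of HVG ids from the
#'   recorder and reference datasets.
#' @param dispersion_live Named per-gene dispersion vector
#'   (see [gene_dispersion()]) covering every candidate gene.
#' @param min_dispersion Dispersion floor (default 0.1).
#' @param mode `"union"` (default) or `"intersection"` of the two HVG lists.
#' @return data.frame with `gene_id` (sorted) and `provenance`
#'   (`"hvg_live"`, `"hvg_reference"` or `"both"`).
#' @export
select_candidates <- function(hvg_live, hvg_reference, dispersion_live,
                              min_dispersion = 0.1,
                              mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!length(hvg_live) || !length(hvg_reference)) {
    stop("both HVG lists must be non-empty")
  }
  ids <- if (mode == "union") union(hvg_live, hvg_reference)
         else intersect(hvg_live, hvg_reference)
  ids <- sort(ids)
  missing <- setdiff(ids, names(dispersion_live))
  if (length(missing)) {
    stop("dispersion_live lacks ", length(missing), " candidate genes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  keep <- dispersion_live[ids] >= min_dispersion
  ids <- ids[keep]
  if (!length(ids)) stop("no candidate genes survive the dispersion filter")
  provenance <- ifelse(ids %in% hvg_live & ids %in% hvg_reference, "both",
                       ifelse(ids %in% hvg_live, "hvg_live", "hvg_reference"))
  data.frame(gene_id = ids, provenance = provenance, stringsAsFactors = FALSE)
}

#' Fit one gene's predictive linear model
#'
#' Ordinary least squares `y = beta0 + beta1 * x` of the response parameter
#' on one gene's ground-state expression, with `r2 = 1 - RSS/TSS`, the
#' overall-model F statistic `f = r2 * (n - 2) / (1 - r2)` and its upper-tail
#' p-value on `F(1, n - 2)`. A constant predictor yields a skipped record
#' (not an error — with few cells many genes are all-zero); a constant
#' response yields `r2 = 0`, `p_f = 1`.
#'
#' @param x Per-cell expression of the gene.
#' @param y Per-cell response parameter, same length (`n >= 4`), both finite.
#' @param gene_id Identifier recorded in the output.
#' @return One-row data.frame: `gene_id`, `beta0`, `beta1`, `r2`, `f_stat`,
#'   `p_f`, `n_cells`, `skipped`, `skip_reason`.
#' @export
fit_gene_model <- function(x, y, gene_id = "gene") {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4L) stop("need at least 4 cells")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("x and y must be finite")
  skipped_row <- function(reason) {
    data.frame(gene_id = gene_id, beta0 = NA_real_, beta1 = NA_real_,
               r2 = NA_real_, f_stat = NA_real_, p_f = NA_real_,
               n_cells = n, skipped = TRUE, skip_reason = reason,
               stringsAsFactors = FALSE)
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(skipped_row("constant predictor"))
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta1 <- sxy / sxx
  beta0 <- mean(y) - beta1 * mean(x)
  if (syy == 0) {
    r2 <- 0; f <- 0; p <- 1
  } else {
    r2 <- max(0, min(1, sxy^2 / (sxx * syy)))
    f <- if (r2 >= 1) Inf else r2 * (n - 2) / (1 - r2)
    # floor at the smallest positive double so p stays in (0, 1] even for
    # numerically perfect fits (keeps the BH family valid)
    p <- max(stats::pf(f, 1, n - 2, lower.tail = FALSE), .Machine$double.xmin)
  }
  data.frame(gene_id = gene_id, beta0 = beta0, beta1 = beta1, r2 = r2,
             f_stat = f, p_f = p, n_cells = n, skipped = FALSE,
             skip_reason = NA_character_, stringsAsFactors = FALSE)
}

#' Bootstrap empirical p-value for a gene's association
#'
#' Cells (x, y pairs) are resampled with replacement `B` times and the slope
#' refit; the two-sided empirical p-value summarizes the sign stability of
#' the resampled slopes, `p = 2 * min(#\{b* <= 0\} + 1, #\{b* >= 0\} + 1) /
#' (B + 1)`, capped at 1 (a zero resampled slope counts on both sides).
#' Degenerate resamples with a constant predictor are redrawn up to
#' `max_retry` times, then counted as sign-indeterminate on both sides; if
#' more than 10 percent of replicates exhaust their retries the predictor is
#' effectively constant and an error is raised.
#'
#' Resampling indexes cells by position, so the p-value is reproducible for
#' a fixed seed and input order but is not invariant to permuting the cells.
#'
#' @param x,y Per-cell expression and response (length `n >= 4`).
#' @param B Number of bootstrap replicates (default 1000, minimum 100).
#' @param seed Seed for the resampling stream.
#' @param max_retry Redraw attempts per degenerate replicate (default 10).
#' @return The empirical p-value in `(0, 1]`.
#' @export
bootstrap_empirical_p <- function(x, y, B = 1000, seed = 1, max_retry = 10L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L, B >= 100L)
  slope_of <- function(idx) {
    xs <- x[idx]
    sxx <- sum((xs - mean(xs))^2)
    if (sxx == 0) return(NA_real_)
    ys <- y[idx]
    sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
  }
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    b_star <- vapply(seq_len(B), function(b) slope_of(idx[, b]), 0)
    degenerate <- which(is.na(b_star))
    for (b in degenerate) {
      for (r in seq_len(max_retry)) {
        b_star[b] <- slope_of(sample.int(n, n, replace = TRUE))
        if (!is.na(b_star[b])) break
      }
    }
    n_exhausted <- sum(is.na(b_star))
    if (n_exhausted > 0.1 * B) {
      stop("predictor nearly constant: ", n_exhausted, " of ", B,
           " bootstrap replicates degenerate after ", max_retry, " retries")
    }
    n_le <- sum(b_star <= 0, na.rm = TRUE) + n_exhausted
    n_ge <- sum(b_star >= 0, na.rm = TRUE) + n_exhausted
    min(1, 2 * min(n_le + 1, n_ge + 1) / (B + 1))
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' mapped back to input order. Input p-values must lie in `(0, 1]`.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Rank gene model fits by explained variance
#'
#' Sorts non-skipped fits by `r2` descending (ties broken by gene id
#' ascending), assigns ranks, and computes BH-adjusted q-values over the
#' non-skipped family — for the F-test p-values and, when present, for the
#' bootstrap p-values separately. Skipped genes are appended unranked.
#'
#' @param fits data.frame of [fit_gene_model()] rows, optionally with a
#'   `p_boot` column.
#' @return The ranking table: `fits` plus `fdr_f` (and `fdr_boot`) and
#'   `rank` (`NA` for skipped genes), ordered by rank.
#' @export
rank_genes <- function(fits) {
  stopifnot(all(c("gene_id", "r2", "p_f", "skipped") %in% names(fits)))
  ok <- !fits$skipped
  if (!any(ok)) stop("all gene fits are skipped")
  ranked <- fits[ok, , drop = FALSE]
  skipped <- fits[!ok, , drop = FALSE]
  ord <- order(-ranked$r2, ranked$gene_id)
  ranked <- ranked[ord, , drop = FALSE]
  ranked$fdr_f <- bh_adjust(ranked$p_f)
  if ("p_boot" %in% names(ranked)) ranked$fdr_boot <- bh_adjust(ranked$p_boot)
  ranked$rank <- seq_len(nrow(ranked))
  if (nrow(skipped)) {
    skipped$fdr_f <- NA_real_
    if ("p_boot" %in% names(ranked)) skipped$fdr_boot <- NA_real_
    skipped$rank <- NA_integer_
    ranked <- rbind(ranked, skipped)
  }
  rownames(ranked) <- NULL
  ranked
}

#' Genome-wide recorder ranking
#'
#' Fits, for every candidate gene, the linear model predicting the chosen
#' response parameter (slope or intercept of the reporter response) from that
#' gene's ground-state log-normalized expression; computes the F-test and,
#' when `B > 0`, bootstrap empirical p-values (each gene's bootstrap stream
#' derives from `seed` plus the gene's position in the sorted candidate
#' list); ranks genes by `r2`.
#'
#' @param norm A [lognormalize()] result on the QC-passing ground-state
#'   cells.
#' @param profiles Response profiles from [fit_response_profiles()] (or any
#'   data.frame with `cell_id` and the response column). Only cells present
#'   in both inputs are used.
#' @param candidates Candidate set from [select_candidates()], or a character
#'   vector of gene ids.
#' @param response `"slope"` (default) or `"intercept"`.
#' @param B Bootstrap replicates per gene; 0 skips the bootstrap (default
#'   1000).
#' @param seed Master seed for the bootstrap streams.
#' @return Ranking table from [rank_genes()] with attributes `response`, `B`,
#'   `seed` and `n_cells`.
#' @export
rank_recorder_genes <- function(norm, profiles, candidates,
                                response = c("slope", "intercept"),
                                B = 1000, seed = 1) {
  stopifnot(inherits(norm, "norm_matrix"))
  response <- match.arg(response)
  gene_ids <- if (is.data.frame(candidates)) candidates$gene_id else candidates
  gene_ids <- sort(unique(gene_ids))
  missing <- setdiff(gene_ids, rownames(norm$values))
  if (length(missing)) {
    stop(length(missing), " candidate genes missing from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  cells <- intersect(colnames(norm$values), profiles$cell_id)
  if (length(cells) < 4L) stop("fewer than 4 cells shared between inputs")
  y <- profiles[[response]][match(cells, profiles$cell_id)]
  expr <- as.matrix(norm$values[gene_ids, cells, drop = FALSE])

  fits <- do.call(rbind, lapply(seq_along(gene_ids), function(i) {
    fit <- fit_gene_model(expr[i, ], y, gene_id = gene_ids[i])
    if (B > 0 && !fit$skipped) {
      fit$p_boot <- bootstrap_empirical_p(
        expr[i, ], y, B = B,
        seed = stage_seed(seed, "bootstrap") + i
      )
    } else if (B > 0) {
      fit$p_boot <- NA_real_
    }
    fit
  }))
  if (B > 0) {
    ok <- !fits$skipped
    # skipped genes carry no bootstrap p; rank_genes adjusts over the family
    fits$p_boot[!ok] <- NA_real_
  }
  tab <- rank_genes(fits)
  attr(tab, "response") <- response
  attr(tab, "B") <- B
  attr(tab, "seed") <- seed
  attr(tab, "n_cells") <- length(cells)
  tab
}
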