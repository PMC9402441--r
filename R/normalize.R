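#' Log-normalize a count matrix
#'
#' Each entry becomes `ln(1 + scale_factor * count / cell_total)`: counts are
#' normalized to the cell's total expression, multiplied by a scale factor
#' (default 10,000), and natural-log transformed with a pseudo-count. A zero
#' count maps to exactly zero, so sparsity is preserved.
#'
#' @param x A [live_counts()] object; every cell must have total count > 0
#'   (zero-total cells should have been removed by QC).
#' @param scale_factor Positive scale factor (default 10000).
#' @return An object of class `norm_matrix`: list with `values` (sparse
#'   gene x cell matrix, natural-log scale) and `scale_factor`.
#' @export
lognormalize <- function(x, scale_factor = 10000) {
  stopifnot(inherits(x, "live_counts"), scale_factor > 0)
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    stop("cells with zero total counts: ",
         paste(utils::head(colnames(x$counts)[totals == 0], 5), collapse = ", "),
         " (run QC filtering first)")
  }
  scaled <- x$counts %*% Matrix::Diagonal(ncol(x$counts), scale_factor / totals)
  values <- methods::as(log1p(scaled), "CsparseMatrix")
  dimnames(values) <- dimnames(x$counts)
  structure(list(values = values, scale_factor = scale_factor),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix: %d genes x %d cells (ln(1 + %g * count/total))\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Variance-stabilized standardized variance per gene
#'
#' Implements the vst-style variability score used for highly variable gene
#' selection: the mean-variance relationship of raw counts is fit by local
#' polynomial regression of `log10(variance)` on `log10(mean)` over genes
#' with positive variance; each gene's counts are then standardized by its
#' observed mean and the regularized (trend-predicted) standard deviation,
#' standardized values are clipped at `sqrt(n_cells)` in absolute value, and
#' the gene's score is the variance of the clipped values.
#'
#' With fewer than `min_loess_genes` positive-variance genes the trend is fit
#' by a straight line instead (a local fit is not identifiable); with a
#' single positive-variance gene its own variance is used as the trend value.
#'
#' @param x A [live_counts()] object with at least 2 cells.
#' @param loess_span,loess_degree Local-regression parameters (defaults 0.3
#'   and 2, the convention of the vst method).
#' @param min_loess_genes Minimum positive-variance genes for a local fit
#'   (default 10).
#' @return data.frame with `gene_id`, `mean`, `variance` (raw-count scale)
#'   and `standardized_variance` (0 for constant genes).
#' @export
vst_standardized_variance <- function(x, loess_span = 0.3, loess_degree = 2,
                                      min_loess_genes = 10L) {
  stopifnot(inherits(x, "live_counts"))
  n <- ncol(x$counts)
  if (n < 2L) stop("need at least 2 cells")
  mu <- Matrix::rowMeans(x$counts)
  v <- row_vars(x$counts)
  fit_idx <- which(v > 0)
  exp_var <- rep(NA_real_, length(mu))
  if (length(fit_idx) == 0L) {
    sv <- rep(0, length(mu))
    return(data.frame(gene_id = rownames(x$counts), mean = mu, variance = v,
                      standardized_variance = sv, stringsAsFactors = FALSE,
                      row.names = NULL))
  } else if (length(fit_idx) == 1L) {
    exp_var[fit_idx] <- v[fit_idx]
  } else if (length(fit_idx) < min_loess_genes) {
    fit <- stats::lm(log10(v[fit_idx]) ~ log10(mu[fit_idx]))
    exp_var[fit_idx] <- 10^stats::fitted(fit)
  } else {
    fit <- stats::loess(log10(v[fit_idx]) ~ log10(mu[fit_idx]),
                        span = loess_span, degree = loess_degree)
    exp_var[fit_idx] <- 10^stats::fitted(fit)
  }
  clip <- sqrt(n)
  sv <- numeric(length(mu))
  dense <- as.matrix(x$counts[fit_idx, , drop = FALSE])
  z <- (dense - mu[fit_idx]) / sqrt(exp_var[fit_idx])
  z <- pmin(pmax(z, -clip), clip)
  zbar <- rowMeans(z)
  sv[fit_idx] <- (rowSums(z^2) - n * zbar^2) / (n - 1)
  data.frame(gene_id = rownames(x$counts), mean = mu, variance = v,
             standardized_variance = sv, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select the top highly variable genes
#'
#' Genes are ordered by standardized variance, descending, with ties broken
#' by gene id ascending, and the first `k` returned.
#'
#' @param variability Output of [vst_standardized_variance()].
#' @param k Number of genes to select (default 500); must not exceed the
#'   number of genes.
#' @return Character vector of `k` gene ids.
#' @export
select_hvg <- function(variability, k = 500) {
  stopifnot(all(c("gene_id", "standardized_variance") %in% names(variability)))
  if (k > nrow(variability)) {
    stop("k = ", k, " exceeds the number of genes (", nrow(variability), ")")
  }
  ord <- order(-variability$standardized_variance, variability$gene_id)
  variability$gene_id[ord][seq_len(k)]
}

#' Per-gene dispersion of normalized expression
#'
#' Dispersion is the variance-to-mean ratio of log-normalized expression
#' across cells (unbiased variance); genes with zero mean get dispersion 0.
#' Used as the expression-variability floor (default threshold 0.1) when
#' assembling the candidate gene set for the recorder ranking.
#'
#' @param norm A [lognormalize()] result.
#' @return Named numeric vector of dispersions (names are gene ids).
#' @export
gene_dispersion <- function(norm) {
  stopifnot(inherits(norm, "norm_matrix"))
  mu <- Matrix::rowMeans(norm$values)
  v <- row_vars(norm$values)
  d <- ifelse(mu > 0, v / mu, 0)
  names(d) <- rownames(norm$values)
  d
}
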