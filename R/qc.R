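#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of detected genes (count > 0), the
#' total count, the percentage of counts from mitochondrial genes and the
#' uniquely-mapped-read rate carried in the cell metadata. Spike-in and
#' ribosomal genes are excluded from these denominators by applying
#' [filter_genes()] first; this function works on whatever matrix it is
#' given.
#'
#' @param x A [live_counts()] object.
#' @return data.frame with columns `cell_id`, `n_gene`, `n_count`,
#'   `pct_mito` (0 for all-zero cells, which fail filtering anyway),
#'   `uniquely_mapped_rate` and `pass` (`NA` until [filter_cells()] is run).
#' @export
compute_cell_qc <- function(x) {
  stopifnot(inherits(x, "live_counts"))
  if (nrow(x$counts) == 0L || ncol(x$counts) == 0L) {
    stop("empty count matrix")
  }
  n_count <- Matrix::colSums(x$counts)
  n_gene <- Matrix::colSums(x$counts > 0)
  mito <- Matrix::colSums(x$counts[x$gene_flags$is_mito, , drop = FALSE])
  pct_mito <- ifelse(n_count > 0, 100 * mito / n_count, 0)
  data.frame(
    cell_id = colnames(x$counts),
    n_gene = as.integer(n_gene),
    n_count = as.numeric(n_count),
    pct_mito = pct_mito,
    uniquely_mapped_rate = x$cell_meta$uniquely_mapped_rate,
    pass = NA,
    stringsAsFactors = FALSE
  )
}

#' Cell-level quality filter
#'
#' Keeps a cell only if it detects more than `min_genes` genes, has fewer
#' than `max_pct_mito` percent mitochondrial counts, and more than
#' `min_mapped` uniquely mapped reads. All three inequalities are strict, so
#' a cell sitting exactly on a threshold is excluded. Cells with zero total
#' counts always fail (they cannot exceed `min_genes`).
#'
#' @param qc Output of [compute_cell_qc()].
#' @param min_genes Detected-gene threshold (default 1000).
#' @param max_pct_mito Mitochondrial percentage threshold (default 30).
#' @param min_mapped Uniquely-mapped-rate threshold (default 0.30).
#' @return Named logical keep mask (names are cell ids).
#' @export
filter_cells <- function(qc, min_genes = 1000, max_pct_mito = 30,
                         min_mapped = 0.30) {
  stopifnot(all(c("cell_id", "n_gene", "pct_mito", "uniquely_mapped_rate")
                %in% names(qc)))
  keep <- qc$n_gene > min_genes &
    qc$pct_mito < max_pct_mito &
    qc$uniquely_mapped_rate > min_mapped
  names(keep) <- qc$cell_id
  keep
}

#' Gene-level filter: spike-ins, ribosomal genes and a blacklist
#'
#' Removes ERCC spike-ins (used only for technical evaluation), ribosomal
#' protein-coding genes (which confound downstream expression analysis) and
#' any blacklisted genes — e.g. the most frequent genes in negative-control
#' wells, which reflect misalignment or oligo artefacts. Genes flagged
#' `is_blacklist` in the container are removed as well. Order of the
#' remaining genes is preserved, and the operation is idempotent.
#'
#' @param x A [live_counts()] object.
#' @param blacklist Character vector of gene ids to remove; ids absent from
#'   the matrix are ignored with a warning.
#' @return A filtered [live_counts()] object.
#' @export
filter_genes <- function(x, blacklist = character(0)) {
  stopifnot(inherits(x, "live_counts"))
  unknown <- setdiff(blacklist, x$gene_flags$gene_id)
  if (length(unknown)) {
    warning("ignoring ", length(unknown), " blacklist ids not in the matrix: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  drop <- x$gene_flags$is_ercc | x$gene_flags$is_ribosomal |
    x$gene_flags$is_blacklist | x$gene_flags$gene_id %in% blacklist
  if (all(drop)) stop("gene filtering removed every gene")
  subset_counts(x, genes = which(!drop))
}
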