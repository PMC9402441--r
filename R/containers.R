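#' Construct a gene-by-cell count container
#'
#' Lightweight container for a raw count matrix plus the per-gene category
#' flags and per-cell metadata the downstream filters need. Genes are rows
#' and cells are columns, the layout produced by plate-based feature
#' counting.
#'
#' @param counts Integer gene x cell matrix (base matrix or any
#'   \pkg{Matrix} class); coerced to sparse `dgCMatrix`. Must have unique,
#'   non-empty rownames (gene ids) and colnames (cell ids).
#' @param gene_flags Optional data.frame with columns `gene_id`, `is_mito`,
#'   `is_ercc`, `is_ribosomal`, `is_blacklist` (and optionally `role`).
#'   When omitted, flags are inferred from gene-id prefixes: `mt-`
#'   (case-insensitive) for mitochondrial, `ERCC-` for spike-ins,
#'   `Rps`/`Rpl` for ribosomal protein genes; `is_blacklist` defaults to
#'   `FALSE`.
#' @param cell_meta Optional data.frame with columns `cell_id`, `batch`,
#'   `uniquely_mapped_rate` (fraction in `[0, 1]`). Defaults to batch
#'   `"batch1"` and mapped rate 1.
#'
#' @return An object of class `live_counts`: a list with elements `counts`
#'   (`dgCMatrix`), `gene_flags` and `cell_meta`.
#' @export
live_counts <- function(counts, gene_flags = NULL, cell_meta = NULL) {
  dn <- dimnames(counts)
  if (!methods::is(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- dn
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if ((is.null(gene_ids) && nrow(counts) > 0) ||
      (is.null(cell_ids) && ncol(counts) > 0)) {
    stop("counts must have gene ids as rownames and cell ids as colnames")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers")
  }

  gene_ids <- gene_ids %||% character(0)
  cell_ids <- cell_ids %||% character(0)
  if (is.null(gene_flags)) {
    gene_flags <- data.frame(
      gene_id = gene_ids,
      is_mito = grepl("^mt-", gene_ids, ignore.case = TRUE),
      is_ercc = grepl("^ERCC-", gene_ids),
      is_ribosomal = grepl("^Rp[sl]", gene_ids),
      is_blacklist = FALSE,
      stringsAsFactors = FALSE
    )
  }
  req <- c("gene_id", "is_mito", "is_ercc", "is_ribosomal", "is_blacklist")
  if (!all(req %in% names(gene_flags))) {
    stop("gene_flags must contain columns: ", paste(req, collapse = ", "))
  }
  if (!setequal(gene_flags$gene_id, gene_ids)) {
    stop("gene_flags$gene_id must match the matrix gene ids")
  }
  gene_flags <- gene_flags[match(gene_ids, gene_flags$gene_id), , drop = FALSE]
  rownames(gene_flags) <- NULL

  if (is.null(cell_meta)) {
    cell_meta <- data.frame(
      cell_id = cell_ids,
      batch = rep("batch1", length(cell_ids)),
      uniquely_mapped_rate = rep(1, length(cell_ids)),
      stringsAsFactors = FALSE
    )
  }
  reqc <- c("cell_id", "batch", "uniquely_mapped_rate")
  if (!all(reqc %in% names(cell_meta))) {
    stop("cell_meta must contain columns: ", paste(reqc, collapse = ", "))
  }
  if (!setequal(cell_meta$cell_id, cell_ids)) {
    stop("cell_meta$cell_id must match the matrix cell ids")
  }
  if (any(cell_meta$uniquely_mapped_rate < 0 | cell_meta$uniquely_mapped_rate > 1)) {
    stop("uniquely_mapped_rate must lie in [0, 1]")
  }
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL

  structure(
    list(counts = counts, gene_flags = gene_flags, cell_meta = cell_meta),
    class = "live_counts"
  )
}

#' @export
print.live_counts <- function(x, ...) {
  cat(sprintf(
    "live_counts: %d genes x %d cells (%d mito, %d ERCC, %d ribosomal, %d blacklist)\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$gene_flags$is_mito), sum(x$gene_flags$is_ercc),
    sum(x$gene_flags$is_ribosomal), sum(x$gene_flags$is_blacklist)
  ))
  invisible(x)
}

#' @export
dim.live_counts <- function(x) dim(x$counts)

#' Subset a count container by gene and/or cell
#'
#' @param x A `live_counts` object.
#' @param genes,cells Character ids or logical/integer indices; `NULL` keeps
#'   all. Order is preserved as given.
#' @return A `live_counts` object.
#' @export
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "live_counts"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else cells
  if (is.character(gi)) gi <- match(gi, rownames(x$counts))
  if (is.character(ci)) ci <- match(ci, colnames(x$counts))
  if (anyNA(gi) || anyNA(ci)) stop("unknown gene or cell ids in subset")
  m <- x$counts[gi, ci, drop = FALSE]
  live_counts(
    m,
    gene_flags = x$gene_flags[match(rownames(m), x$gene_flags$gene_id), , drop = FALSE],
    cell_meta = x$cell_meta[match(colnames(m), x$cell_meta$cell_id), , drop = FALSE]
  )
}

#' Write a count container to disk
#'
#' Writes either MatrixMarket (`matrix.mtx` + `genes.tsv` + `barcodes.tsv`)
#' or a single dense TSV (`counts.tsv`), plus `gene_flags.tsv` and
#' `cell_meta.csv` sidecars.
#'
#' @param x A `live_counts` object.
#' @param dir Output directory (created if missing).
#' @param format `"mtx"` (sparse, default) or `"tsv"` (dense).
#' @return Invisibly, the paths written.
#' @export
write_live_counts <- function(x, dir, format = c("mtx", "tsv")) {
  stopifnot(inherits(x, "live_counts"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (format == "mtx") {
    mtx <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(x$counts, mtx)
    genes <- file.path(dir, "genes.tsv")
    barcodes <- file.path(dir, "barcodes.tsv")
    utils::write.table(data.frame(gene_id = rownames(x$counts)), genes,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(cell_id = colnames(x$counts)), barcodes,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(mtx, genes, barcodes)
  } else {
    tsv <- file.path(dir, "counts.tsv")
    dense <- as.matrix(x$counts)
    utils::write.table(data.frame(gene_id = rownames(dense), dense,
        check.names = FALSE), tsv,
      sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- tsv
  }
  fl <- file.path(dir, "gene_flags.tsv")
  utils::write.table(x$gene_flags, fl, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- file.path(dir, "cell_meta.csv")
  utils::write.csv(x$cell_meta, cm, row.names = FALSE)
  invisible(c(paths, fl, cm))
}

#' Read a count container written by [write_live_counts()]
#'
#' @param dir Directory containing either `matrix.mtx`/`genes.tsv`/
#'   `barcodes.tsv` or `counts.tsv`, plus the `gene_flags.tsv` and
#'   `cell_meta.csv` sidecars.
#' @return A `live_counts` object.
#' @export
read_live_counts <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (file.exists(mtx)) {
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    rownames(m) <- utils::read.table(file.path(dir, "genes.tsv"))[[1]]
    colnames(m) <- utils::read.table(file.path(dir, "barcodes.tsv"))[[1]]
  } else {
    d <- utils::read.table(file.path(dir, "counts.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
  }
  gene_flags <- utils::read.table(file.path(dir, "gene_flags.tsv"),
                                  header = TRUE, sep = "\t")
  cell_meta <- utils::read.csv(file.path(dir, "cell_meta.csv"))
  live_counts(m, gene_flags = gene_flags, cell_meta = cell_meta)
}
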