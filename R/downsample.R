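# Feature-matched down-sampling: make a deeper dataset comparable to a
# shallower one by resampling each deep cell's reads so its detected-gene
# count matches a paired shallow cell (absolute difference below a
# tolerance), then resampling to the shallow cell's exact library size.

#' Randomly subsample cells from a count container
#'
#' Uniform, seeded subset without replacement; the original column order of
#' the selected cells is preserved.
#'
#' @param x A [live_counts()] object.
#' @param n_target Number of cells to keep (`<= ncol`).
#' @param seed Seed for the draw.
#' @return A [live_counts()] with `n_target` cells.
#' @export
subsample_cells <- function(x, n_target, seed = 1) {
  stopifnot(inherits(x, "live_counts"))
  n <- ncol(x$counts)
  if (n_target > n) stop("n_target (", n_target, ") exceeds cell count (", n, ")")
  keep <- with_seed(stage_seed(seed, "subsample"),
                    sort(sample.int(n, n_target)))
  subset_counts(x, cells = keep)
}

#' Pair cells across datasets by detected-feature rank
#'
#' Both QC tables are ordered by detected-gene count (ties broken by cell
#' id) and the k-th ranked reference cell is paired with the k-th ranked
#' target cell, so pairing is invariant to input row order.
#'
#' @param reference_qc,target_qc [compute_cell_qc()] tables of equal row
#'   count.
#' @return data.frame with `reference_cell_id`, `target_cell_id`,
#'   `reference_n_gene`, `target_n_gene`; one row per pair, in rank order.
#' @export
pair_by_features <- function(reference_qc, target_qc) {
  if (nrow(reference_qc) != nrow(target_qc)) {
    stop("reference and target must have the same number of cells")
  }
  ro <- order(reference_qc$n_gene, reference_qc$cell_id)
  to <- order(target_qc$n_gene, target_qc$cell_id)
  data.frame(
    reference_cell_id = reference_qc$cell_id[ro],
    target_cell_id = target_qc$cell_id[to],
    reference_n_gene = reference_qc$n_gene[ro],
    target_n_gene = target_qc$n_gene[to],
    stringsAsFactors = FALSE
  )
}

#' Down-sample one cell's reads to a target detected-feature count
#'
#' Searches for a read number `m` by bisection on `[1, 10 x total]`; at each
#' candidate `m` one seeded multinomial sample of `m` reads is drawn with
#' replacement (probabilities proportional to the counts) and its
#' detected-feature count evaluated. The first draw whose detected-feature
#' count differs from `target_n_gene` by less than `tolerance` is returned.
#' Because the detected count of a single draw is stochastic, the bracket is
#' re-centred around the best `m` seen whenever it collapses, so remaining
#' iterations are spent redrawing near the optimum.
#'
#' @param cell_counts Non-negative integer per-gene counts with total > 0.
#' @param target_n_gene Target detected-feature count; must not exceed the
#'   cell's own detected-feature count.
#' @param tolerance Strict acceptance bound on the absolute difference
#'   (default 5, i.e. accepted differences are 0-4).
#' @param seed Seed for the sampling stream.
#' @param max_iter Maximum draws before giving up (default 400).
#' @return Integer per-gene vector summing to the accepted `m`, with
#'   attributes `m` (reads drawn) and `achieved_n_gene`.
#' @export
downsample_to_features <- function(cell_counts, target_n_gene, tolerance = 5,
                                   seed = 1, max_iter = 400L) {
  ids <- names(cell_counts)
  cell_counts <- as.numeric(cell_counts)
  names(cell_counts) <- ids
  total <- sum(cell_counts)
  if (total <= 0) stop("cell has zero total counts")
  detected <- sum(cell_counts > 0)
  if (target_n_gene > detected) {
    stop("target_n_gene (", target_n_gene, ") exceeds the cell's detected features (",
         detected, ")")
  }
  with_seed(stage_seed(seed, "downsample"), {
    lo <- 1; hi <- 10 * total
    best_m <- total; best_diff <- Inf; best_draw <- NULL
    for (iter in seq_len(max_iter)) {
      m <- max(1, floor((lo + hi) / 2))
      draw <- stats::rmultinom(1, m, cell_counts)[, 1]
      d <- sum(draw > 0)
      diff <- abs(d - target_n_gene)
      if (diff < best_diff) {
        best_diff <- diff; best_m <- m; best_draw <- draw
      }
      if (diff < tolerance) {
        names(draw) <- names(cell_counts)
        attr(draw, "m") <- m
        attr(draw, "achieved_n_gene") <- d
        return(draw)
      }
      if (d > target_n_gene) hi <- m - 1 else lo <- m + 1
      if (lo > hi) {
        lo <- max(1, floor(best_m * 0.98))
        hi <- max(lo, ceiling(best_m * 1.02))
      }
    }
    stop("could not reach target_n_gene = ", target_n_gene, " within ",
         max_iter, " draws; best achieved difference ", best_diff,
         " at m = ", best_m)
  })
}

#' Resample a cell to an exact library size
#'
#' One multinomial draw of `target_total` reads with probabilities
#' proportional to the (down-sampled) counts; the support never grows and the
#' output total equals `target_total` exactly.
#'
#' @param ds_counts Non-negative per-gene counts with positive total.
#' @param target_total Library size to reach.
#' @param seed Seed for the draw.
#' @return Integer per-gene vector summing to `target_total`.
#' @export
upsample_to_library <- function(ds_counts, target_total, seed = 1) {
  ids <- names(ds_counts)
  ds_counts <- as.numeric(ds_counts)
  names(ds_counts) <- ids
  if (sum(ds_counts) <= 0) stop("all-zero input counts")
  stopifnot(target_total >= 1)
  draw <- with_seed(stage_seed(seed, "downsample") + 1L,
                    stats::rmultinom(1, target_total, ds_counts)[, 1])
  names(draw) <- names(ds_counts)
  draw
}

#' Feature- and depth-match a deep dataset to a shallow one
#'
#' End-to-end procedure: (1) randomly subsample the reference (deep) cells to
#' the target (shallow) cell count, (2) order both by detected features and
#' pair rank-to-rank, (3) down-sample each reference cell's reads until its
#' detected-feature count is within `tolerance` of its paired target cell,
#' and (4) resample to the target cell's exact library size.
#'
#' @param reference Deep [live_counts()] dataset.
#' @param target Shallow [live_counts()] dataset (its cell count must not
#'   exceed the reference's).
#' @param seed Master seed; per-cell streams derive from it.
#' @param tolerance Strict detected-feature tolerance (default 5).
#' @param max_iter Per-cell draw budget (default 400).
#' @return List with `matched` (a [live_counts()] of matched reference
#'   cells) and `report`, a data.frame per pair: `reference_id`, `target_id`,
#'   `target_n_gene`, `achieved_n_gene`, `m`, `final_total`,
#'   `target_n_count`.
#' @export
downsample_match <- function(reference, target, seed = 1, tolerance = 5,
                             max_iter = 400L) {
  stopifnot(inherits(reference, "live_counts"), inherits(target, "live_counts"))
  n_t <- ncol(target$counts)
  if (ncol(reference$counts) < n_t) {
    stop("reference has fewer cells than target")
  }
  if (ncol(reference$counts) > n_t) {
    reference <- subsample_cells(reference, n_t, seed = seed)
  }
  pairs <- pair_by_features(compute_cell_qc(reference), compute_cell_qc(target))
  target_totals <- Matrix::colSums(target$counts)
  cols <- vector("list", nrow(pairs))
  report <- pairs
  report$m <- NA_real_
  report$achieved_n_gene <- NA_integer_
  report$final_total <- NA_real_
  report$target_n_count <- as.numeric(target_totals[pairs$target_cell_id])
  for (k in seq_len(nrow(pairs))) {
    ref_counts <- as.numeric(reference$counts[, pairs$reference_cell_id[k]])
    names(ref_counts) <- rownames(reference$counts)
    ds <- downsample_to_features(ref_counts, pairs$target_n_gene[k],
                                 tolerance = tolerance, seed = seed + k,
                                 max_iter = max_iter)
    up <- upsample_to_library(ds, report$target_n_count[k], seed = seed + k)
    report$m[k] <- attr(ds, "m")
    report$achieved_n_gene[k] <- attr(ds, "achieved_n_gene")
    report$final_total[k] <- sum(up)
    cols[[k]] <- up
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(rownames(reference$counts), pairs$reference_cell_id)
  matched <- live_counts(
    m,
    gene_flags = reference$gene_flags,
    cell_meta = reference$cell_meta[
      match(colnames(m), reference$cell_meta$cell_id), , drop = FALSE]
  )
  names(report)[names(report) == "reference_cell_id"] <- "reference_id"
  names(report)[names(report) == "target_cell_id"] <- "target_id"
  list(matched = matched, report = report)
}
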