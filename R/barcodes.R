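# Lineage-barcode tracking: consensus call per cell, Hamming distances and
# sequential pre/post matching.

#' Consensus barcode from repeated observations
#'
#' The most frequent observed string; ties are broken by lexicographic order
#' (smallest string wins), so the call is deterministic.
#'
#' @param observations Non-empty character vector of observed barcode reads.
#' @return The consensus barcode string.
#' @export
consensus_barcode <- function(observations) {
  if (!length(observations)) stop("no barcode observations")
  tab <- table(observations)
  names(tab)[which.max(tab)][1]
}

#' Consensus barcodes for a table of observations
#'
#' @param observations data.frame with columns `cell_id` and `barcode` (one
#'   row per read; an optional `count` column repeats rows).
#' @return Named character vector: cell id -> consensus barcode.
#' @export
consensus_barcodes <- function(observations) {
  stopifnot(all(c("cell_id", "barcode") %in% names(observations)))
  if ("count" %in% names(observations)) {
    observations <- observations[rep(seq_len(nrow(observations)),
                                     observations$count), ]
  }
  ids <- sort(unique(observations$cell_id))
  out <- vapply(ids, function(id) {
    consensus_barcode(observations$barcode[observations$cell_id == id])
  }, "")
  names(out) <- ids
  out
}

#' Hamming distance with unit gap cost
#'
#' Positional mismatches over the shorter string cost 1 each; every
#' unmatched trailing position of the longer string adds 1 (mismatch = 1,
#' gap = 1). On equal-length strings this is the Hamming metric.
#'
#' @param s1,s2 Non-empty strings.
#' @return Non-negative integer distance.
#' @export
hamming_distance <- function(s1, s2) {
  stopifnot(nchar(s1) > 0, nchar(s2) > 0)
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  k <- min(length(a), length(b))
  sum(a[seq_len(k)] != b[seq_len(k)]) + abs(length(a) - length(b))
}

#' All-pairs barcode distance matrix
#'
#' @param set1,set2 Named character vectors (cell id -> consensus barcode).
#' @return Integer matrix of distances, rows `set1`, columns `set2`.
#' @export
barcode_distance_matrix <- function(set1, set2 = set1) {
  stopifnot(length(set1) > 0, length(set2) > 0)
  m <- outer(seq_along(set1), seq_along(set2),
             Vectorize(function(i, j) hamming_distance(set1[[i]], set2[[j]])))
  dimnames(m) <- list(names(set1), names(set2))
  m
}

#' Match sequentially sampled cells by barcode distance
#'
#' A pre/post pair is accepted only when its distance is at most `max_dist`
#' and is the unique minimum both in its row and in its column of the
#' distance matrix; ambiguous cells (tied minima) stay unmatched, with their
#' nearest distance reported.
#'
#' @param pre,post Named character vectors (cell id -> consensus barcode).
#' @param max_dist Maximum accepted distance (default 0: identical barcodes
#'   prove identity).
#' @return List with `matches` (data.frame `pre_id`, `post_id`, `distance`)
#'   and `unmatched_pre` / `unmatched_post` (data.frames `cell_id`,
#'   `nearest_distance`).
#' @export
match_sequential <- function(pre, post, max_dist = 0) {
  d <- barcode_distance_matrix(pre, post)
  matches <- data.frame(pre_id = character(0), post_id = character(0),
                        distance = integer(0), stringsAsFactors = FALSE)
  matched_pre <- logical(nrow(d))
  matched_post <- logical(ncol(d))
  for (i in seq_len(nrow(d))) {
    row <- d[i, ]
    j <- which.min(row)
    if (sum(row == row[j]) != 1L) next       # ambiguous in the row
    col <- d[, j]
    if (sum(col == col[i]) != 1L || which.min(col) != i) next # ambiguous in the column
    if (row[j] > max_dist) next
    matches <- rbind(matches, data.frame(
      pre_id = rownames(d)[i], post_id = colnames(d)[j],
      distance = as.integer(row[j]), stringsAsFactors = FALSE
    ))
    matched_pre[i] <- TRUE
    matched_post[j] <- TRUE
  }
  list(
    matches = matches,
    unmatched_pre = data.frame(
      cell_id = rownames(d)[!matched_pre],
      nearest_distance = if (any(!matched_pre))
        as.integer(apply(d[!matched_pre, , drop = FALSE], 1, min)) else integer(0),
      stringsAsFactors = FALSE
    ),
    unmatched_post = data.frame(
      cell_id = colnames(d)[!matched_post],
      nearest_distance = if (any(!matched_post))
        as.integer(apply(d[, !matched_post, drop = FALSE], 2, min)) else integer(0),
      stringsAsFactors = FALSE
    )
  )
}
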