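#' Construct a fluorescence time course
#'
#' @param cell_id Cell identifier.
#' @param time_h Strictly increasing times in hours (0 = stimulant addition).
#' @param intensity Raw intensities (arbitrary units), one per timepoint.
#' @param background Per-timepoint background intensities.
#' @param bead_mean Mean calibration-bead intensity (positive).
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(cell_id, time_h, intensity, background = rep(0, length(time_h)),
                        bead_mean = 1) {
  stopifnot(
    length(time_h) == length(intensity),
    length(time_h) == length(background),
    length(time_h) >= 2L,
    all(diff(time_h) > 0)
  )
  structure(
    list(cell_id = as.character(cell_id), time_h = as.numeric(time_h),
         intensity = as.numeric(intensity), background = as.numeric(background),
         bead_mean = as.numeric(bead_mean), calibrated = FALSE),
    class = "fluor_trace"
  )
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("fluor_trace %s: %d timepoints over %.1f-%.1f h (%s)\n",
              x$cell_id, length(x$time_h), min(x$time_h), max(x$time_h),
              if (x$calibrated) "calibrated" else "raw"))
  invisible(x)
}

#' Background-subtract and bead-normalize a trace
#'
#' Per timepoint, `intensity' = (intensity - background) / bead_mean`; after
#' calibration the background is zero and `bead_mean` is reset to 1, so the
#' operation is idempotent only in that trivial state.
#'
#' @param trace A [fluor_trace()].
#' @return The calibrated `fluor_trace`.
#' @export
calibrate_trace <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (trace$bead_mean <= 0) stop("bead_mean must be positive")
  trace$intensity <- (trace$intensity - trace$background) / trace$bead_mean
  trace$background <- rep(0, length(trace$background))
  trace$bead_mean <- 1
  trace$calibrated <- TRUE
  trace
}

#' Fit the log-linear response model inside the analysis window
#'
#' Ordinary least squares of `ln(intensity)` on time over the in-window
#' (closed interval, default 3 to 7.5 h) timepoints with positive calibrated
#' intensity. Non-positive points are dropped point-wise rather than floored,
#' to avoid bias in log space; their count is returned. The intercept is the
#' basal (log) reporter expression and the slope the extent of the response.
#'
#' For a constant in-window trace the slope is 0 and, because the fit is then
#' exact, `r2_fit` is reported as 1.
#'
#' @param trace A calibrated [fluor_trace()].
#' @param window Closed analysis window in hours, default `c(3, 7.5)`.
#' @return One-row data.frame: `cell_id`, `intercept`, `slope`, `r2_fit`,
#'   `n_points_used`, `n_dropped_nonpositive`, `window_start`, `window_end`.
#' @export
fit_log_linear <- function(trace, window = c(3.0, 7.5)) {
  stopifnot(inherits(trace, "fluor_trace"), length(window) == 2L,
            window[1] < window[2])
  inw <- trace$time_h >= window[1] & trace$time_h <= window[2]
  t_in <- trace$time_h[inw]
  i_in <- trace$intensity[inw]
  pos <- i_in > 0
  n_dropped <- sum(!pos)
  t_use <- t_in[pos]
  y <- log(i_in[pos])
  if (length(t_use) < 3L) {
    stop("cell ", trace$cell_id, ": fewer than 3 positive in-window points (",
         length(t_use), " usable, ", n_dropped, " dropped as non-positive)")
  }
  n <- length(t_use)
  tbar <- mean(t_use); ybar <- mean(y)
  sxx <- sum((t_use - tbar)^2)
  sxy <- sum((t_use - tbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * tbar
  rss <- sum((y - intercept - slope * t_use)^2)
  tss <- sum((y - ybar)^2)
  r2 <- if (tss <= 0) {
    if (rss <= 1e-24) 1 else 0
  } else {
    max(0, min(1, 1 - rss / tss))
  }
  data.frame(
    cell_id = trace$cell_id, intercept = intercept, slope = slope,
    r2_fit = r2, n_points_used = n, n_dropped_nonpositive = n_dropped,
    window_start = window[1], window_end = window[2],
    stringsAsFactors = FALSE
  )
}

#' Fit response profiles for a collection of traces
#'
#' Calibrates each trace (unless already calibrated) and fits the windowed
#' log-linear model.
#'
#' @param traces List of [fluor_trace()] objects.
#' @param window Analysis window, default `c(3, 7.5)`.
#' @return data.frame with one row per cell (see [fit_log_linear()]).
#' @export
fit_response_profiles <- function(traces, window = c(3.0, 7.5)) {
  do.call(rbind, lapply(traces, function(tr) {
    if (!tr$calibrated) tr <- calibrate_trace(tr)
    fit_log_linear(tr, window = window)
  }))
}

#' Area under the calibrated intensity curve
#'
#' Trapezoidal integral of intensity over the in-window timepoints (closed
#' interval, default 3 to 7.5 h).
#'
#' @param trace A calibrated [fluor_trace()].
#' @param window Analysis window, default `c(3, 7.5)`.
#' @return Numeric area (intensity units x hours).
#' @export
auc_trace <- function(trace, window = c(3.0, 7.5)) {
  stopifnot(inherits(trace, "fluor_trace"))
  inw <- trace$time_h >= window[1] & trace$time_h <= window[2]
  t_in <- trace$time_h[inw]
  i_in <- trace$intensity[inw]
  if (length(t_in) < 2L) stop("need at least 2 in-window points for the AUC")
  sum(diff(t_in) * (utils::head(i_in, -1) + utils::tail(i_in, -1)) / 2)
}

# Volume units used throughout: 1 pl = 1,000 um^3 = 1,000 fl.

volume_record <- function(kind, value_pl, inputs, flagged = FALSE) {
  structure(list(kind = kind, value_pl = value_pl, inputs = inputs,
                 flagged = flagged),
            class = "volume_measurement")
}

#' @export
print.volume_measurement <- function(x, ...) {
  cat(sprintf("volume_measurement [%s]: %.4f pl%s\n", x$kind, x$value_pl,
              if (x$flagged) " (flagged: non-positive difference)" else ""))
  invisible(x)
}

#' Spherical cell volume from three averaged diameters
#'
#' Three diameters are measured per rounded cell and averaged; the volume is
#' `(pi/6) * mean(d)^3`, reported in picolitres (1 pl = 1,000 um^3).
#'
#' @param d1,d2,d3 Diameters in micrometres (positive).
#' @return A `volume_measurement` of kind `"cell_sphere"` with `value_pl`.
#' @export
cell_volume_from_diameters <- function(d1, d2, d3) {
  d <- c(d1, d2, d3)
  if (any(!is.finite(d)) || any(d <= 0)) stop("diameters must be positive")
  dbar <- mean(d)
  vol_um3 <- pi / 6 * dbar^3
  volume_record("cell_sphere", vol_um3 / 1000, list(diameters_um = d))
}

#' Probe channel volume from the occupied area
#'
#' The area occupied by aqueous solution in the probe cantilever is
#' multiplied by the 0.8 um channel height, and the 90 fl volume of the
#' hollow pyramidal tip is added.
#'
#' @param area Occupied area in square micrometres (non-negative).
#' @return A `volume_measurement` of kind `"probe_channel"` with `value_pl`.
#' @export
probe_channel_volume <- function(area) {
  if (!is.finite(area) || area < 0) stop("area must be non-negative")
  vol_fl <- area * 0.8 + 90
  volume_record("probe_channel", vol_fl / 1000, list(area_um2 = area))
}

#' Extracted biopsy volume from before/after probe areas
#'
#' The preloaded-buffer volume (probe imaged before extraction) is subtracted
#' from the mixed buffer-plus-extract volume (probe imaged after), so the
#' constant 90 fl tip term cancels. A non-positive difference reflects
#' measurement noise: it is returned flagged, with a warning, rather than
#' silently dropped.
#'
#' @param area_before,area_after Occupied areas in square micrometres.
#' @return A `volume_measurement` of kind `"extracted"`; `flagged` is `TRUE`
#'   when the difference is not positive.
#' @export
extracted_volume <- function(area_before, area_after) {
  v <- probe_channel_volume(area_after)$value_pl -
    probe_channel_volume(area_before)$value_pl
  flagged <- v <= 0
  if (v < 0) {
    warning("negative extracted volume (", format(v), " pl): flagged record")
  }
  volume_record("extracted", v,
                list(area_before_um2 = area_before, area_after_um2 = area_after),
                flagged = flagged)
}
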