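#' Protofilament trace
#'
#' An ordered 3D polyline (nm) of one protofilament, directed from the
#' minus end toward the plus end. Arclength per point is derived from the
#' coordinates.
#'
#' @param end_id Character id of the microtubule end the trace belongs to.
#' @param pf_id Integer protofilament id (angular position on the lattice).
#' @param points Numeric matrix with 3 columns (x, y, z in nm), >= 4 rows.
#' @return An object of class `pf_trace` with fields `end_id`, `pf_id`,
#'   `points`, and `arclength` (nm, starting at 0, strictly increasing).
#' @export
pf_trace <- function(end_id, pf_id, points) {
  new_pf_trace(end_id, pf_id, points, min_points = 4L)
}

# internal constructor; resampling may legitimately produce 2-point traces
new_pf_trace <- function(end_id, pf_id, points, min_points = 2L) {
  if (!is.matrix(points) || ncol(points) != 3L)
    stop_field("points", "must be an n x 3 numeric matrix")
  if (!is.numeric(points) || any(!is.finite(points)))
    stop_field("points", "coordinates must be finite")
  if (nrow(points) < min_points)
    stop_field("points", sprintf("a trace needs at least %d points", min_points))
  steps <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(steps <= 0))
    stop_field("points", "consecutive points must be distinct")
  structure(list(end_id = as.character(end_id), pf_id = as.integer(pf_id),
                 points = unname(points),
                 arclength = c(0, cumsum(steps))),
            class = "pf_trace")
}

#' Microtubule end
#'
#' A set of protofilament traces from one microtubule plus-end, with an
#' optional condition label and microtubule length (needed for seed
#' filtering).
#'
#' @param end_id Character id.
#' @param traces List of [pf_trace()] objects, one per protofilament.
#' @param condition Optional condition label.
#' @param length_um Optional microtubule length in micrometres.
#' @param n_pf Protofilament count of the lattice the end comes from;
#'   defaults to the number of traces.
#' @return An object of class `mt_end`.
#' @export
mt_end <- function(end_id, traces, condition = NA_character_,
                   length_um = NA_real_, n_pf = length(traces)) {
  if (!length(traces) || !all(vapply(traces, inherits, TRUE, "pf_trace")))
    stop_field("traces", "must be a non-empty list of pf_trace objects")
  ids <- vapply(traces, `[[`, 0L, "pf_id")
  if (anyDuplicated(ids)) stop_field("traces", "duplicate pf_id")
  structure(list(end_id = as.character(end_id),
                 traces = traces[order(ids)],
                 condition = condition, length_um = length_um,
                 n_pf = as.integer(n_pf)),
            class = "mt_end")
}

#' @export
print.mt_end <- function(x, ...) {
  cat(sprintf("<mt_end> %s: %d traces (lattice of %d protofilaments)%s\n",
              x$end_id, length(x$traces), x$n_pf,
              if (is.na(x$condition)) "" else paste0(", condition ", x$condition)))
  invisible(x)
}

#' Smooth a trace with cross-validated splines
#'
#' Independent point noise on a densely sampled polyline inflates its
#' arclength (every step gains length from the noise), which would bias
#' every arclength-based measurement. Smoothing splines (one per
#' coordinate) fitted against the raw arclength parameter recover the
#' underlying smooth curve; the returned trace is re-evaluated on a fine
#' grid so its arclength is that of the smooth curve. The flexibility is
#' set deterministically from the trace length (about one degree of
#' freedom per 8 nm, at least 6): protofilament shapes are gentle arcs,
#' so this comfortably follows the geometry while suppressing point
#' noise, and avoids the occasional noise-chasing of cross-validated
#' smoothness selection. Traces with fewer than 10 points are returned
#' unchanged.
#'
#' @param trace A [pf_trace()].
#' @param grid_step_nm Evaluation step of the smoothed curve (nm).
#' @param nm_per_df Trace length per spline degree of freedom (nm).
#' @return A smoothed `pf_trace`.
#' @export
smooth_trace <- function(trace, grid_step_nm = 0.5, nm_per_df = 8) {
  stopifnot(inherits(trace, "pf_trace"))
  check_scalar(grid_step_nm, "grid_step_nm", positive = TRUE)
  check_scalar(nm_per_df, "nm_per_df", positive = TRUE)
  t <- trace$arclength
  n <- length(t)
  if (n < 10L) return(trace)
  df <- max(6, min(n - 4, ceiling(t[n] / nm_per_df)))
  grid <- seq(0, t[n], by = grid_step_nm)
  if (grid[length(grid)] < t[n]) grid <- c(grid, t[n])
  pts <- vapply(seq_len(3L), function(j) {
    sp <- stats::smooth.spline(t, trace$points[, j], df = df)
    stats::predict(sp, grid)$y
  }, numeric(length(grid)))
  new_pf_trace(trace$end_id, trace$pf_id, pts)
}

#' Resample a trace at uniform arclength spacing
#'
#' Linear interpolation along the polyline; both endpoints are preserved,
#' so the final spacing may be shorter than `step_nm`. Total arclength is
#' conserved to within one step.
#'
#' @param trace A [pf_trace()].
#' @param step_nm Target arclength step (nm), > 0.
#' @return A resampled `pf_trace`.
#' @export
resample_trace <- function(trace, step_nm) {
  stopifnot(inherits(trace, "pf_trace"))
  check_scalar(step_nm, "step_nm", positive = TRUE)
  s <- trace$arclength
  total <- s[length(s)]
  grid <- seq(0, total, by = step_nm)
  if (grid[length(grid)] < total) grid <- c(grid, total)
  pts <- vapply(seq_len(3L),
                function(j) approx(s, trace$points[, j], xout = grid)$y,
                numeric(length(grid)))
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3L)
  new_pf_trace(trace$end_id, trace$pf_id, pts)
}
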