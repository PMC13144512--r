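#' Segment a protofilament trace into lattice and bent parts
#'
#' The radial excess of each sample is its distance to the fitted axis
#' minus the fitted lattice radius. A bend is called at the smallest
#' arclength where the excess exceeds `bend_radial_excess_nm` for at least
#' `bend_persistence_samples` consecutive samples. Because a flare departs
#' tangentially, the excess at the detection threshold lags the true onset
#' by roughly \eqn{\sqrt{2\varepsilon/\kappa}}; the onset is therefore
#' refined by extrapolating \eqn{\sqrt{excess}} — linear in arclength for a
#' tangential circular arc — back to zero.
#'
#' @param trace A [pf_trace()]; it is resampled internally at
#'   `config$resample_step_nm`.
#' @param axis An `axis_model` from [fit_axis()].
#' @param config A [geometry_config()].
#' @return An object of class `bend_segmentation`: `pf_id`, `bent`,
#'   `onset_arclength_nm` (NA if unbent), `bent_length_nm` (0 if unbent),
#'   `onset_z_nm` (axial coordinate of the onset; terminus for unbent),
#'   `terminus_z_nm`, `arclength`, `radial_excess`, and the resampled
#'   trace.
#' @export
segment_bend <- function(trace, axis, config = geometry_config()) {
  stopifnot(inherits(trace, "pf_trace"), inherits(axis, "axis_model"))
  if (config$smooth_traces %||% TRUE)
    trace <- smooth_trace(trace, config$resample_step_nm / 2)
  tr <- resample_trace(trace, config$resample_step_nm)
  co <- axis_coords(axis, tr$points)
  excess <- co$r_nm - axis$radius_nm
  s <- tr$arclength
  eps <- config$bend_radial_excess_nm
  k <- config$bend_persistence_samples

  above <- excess > eps
  i0 <- detect_run_start(above, k)

  if (is.na(i0)) {
    out <- list(pf_id = tr$pf_id, bent = FALSE,
                onset_arclength_nm = NA_real_, bent_length_nm = 0,
                onset_z_nm = co$z_nm[length(s)],
                terminus_z_nm = co$z_nm[length(s)],
                arclength = s, radial_excess = excess, trace = tr)
    class(out) <- "bend_segmentation"
    return(out)
  }

  onset_s <- refine_onset(s, excess, i0, k, eps)
  onset_z <- stats::approx(s, co$z_nm, xout = onset_s)$y
  out <- list(pf_id = tr$pf_id, bent = TRUE,
              onset_arclength_nm = onset_s,
              bent_length_nm = s[length(s)] - onset_s,
              onset_z_nm = onset_z,
              terminus_z_nm = co$z_nm[length(s)],
              arclength = s, radial_excess = excess, trace = tr)
  class(out) <- "bend_segmentation"
  out
}

# first index starting a run of >= k TRUE values, NA if none
detect_run_start <- function(above, k) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= k)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

# extrapolate sqrt(excess) to zero over the rise preceding the detection
refine_onset <- function(s, excess, i0, k, eps) {
  lo <- i0
  while (lo > 1 && excess[lo - 1] > eps / 3) lo <- lo - 1
  hi <- min(i0 + k, length(s))
  idx <- lo:hi
  idx <- idx[excess[idx] > 0]
  if (length(idx) < 2L) return(s[i0])
  fit <- stats::lm.fit(cbind(1, s[idx]), sqrt(excess[idx]))
  a <- fit$coefficients[2]; b <- fit$coefficients[1]
  if (!is.finite(a) || a <= 0) return(s[i0])
  min(max(-b / a, 0), s[i0])
}

#' Summarise the shape of one microtubule end
#'
#' Counts unbent protofilaments, collects bent-segment lengths, and
#' computes the raggedness: the population standard deviation of the axial
#' bend-onset coordinates, with unbent protofilaments contributing their
#' plus-terminus coordinate.
#'
#' @param end The [mt_end()] the segmentations belong to.
#' @param segmentations List of [segment_bend()] results, one per
#'   protofilament of the end.
#' @param config A [geometry_config()].
#' @param lattice_spacing_nm Optional measured lattice spacing to carry.
#' @return An object of class `end_shape_summary`: `end_id`, `condition`,
#'   `n_pf`, `fraction_unbent`, `bent_lengths_nm`, `raggedness_nm`,
#'   `lattice_spacing_nm`, `length_um`.
#' @export
end_summary <- function(end, segmentations, config = geometry_config(),
                        lattice_spacing_nm = NA_real_) {
  stopifnot(inherits(end, "mt_end"))
  if (!length(segmentations))
    stop("empty end: no segmentations supplied", call. = FALSE)
  if (!all(vapply(segmentations, inherits, TRUE, "bend_segmentation")))
    stop("`segmentations` must be bend_segmentation objects", call. = FALSE)
  n <- length(segmentations)
  bent <- vapply(segmentations, `[[`, TRUE, "bent")
  zref <- vapply(segmentations, `[[`, 0, "onset_z_nm")
  lens <- vapply(segmentations, `[[`, 0, "bent_length_nm")[bent]
  structure(list(end_id = end$end_id, condition = end$condition,
                 n_pf = n,
                 fraction_unbent = sum(!bent) / n,
                 bent_lengths_nm = as.numeric(lens),
                 raggedness_nm = sqrt(mean((zref - mean(zref))^2)),
                 lattice_spacing_nm = lattice_spacing_nm,
                 length_um = end$length_um),
            class = "end_shape_summary")
}
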