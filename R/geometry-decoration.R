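#' Measure decoration thickness from a radial intensity profile
#'
#' Thickness of the protein shell decorating the microtubule wall,
#' measured radially: the outermost radius at which the intensity exceeds
#' background + 3 background SDs (for at least `persistence` consecutive
#' samples, to reject isolated noise), minus the outer radius of the wall.
#' The wall outer radius is where the intensity falls to half-maximum
#' outside the wall peak, which assumes the wall is at least about twice
#' as bright as the decoration shell (axial projections of tomograms
#' satisfy this comfortably). The background statistics come from the
#' outermost tail of the profile.
#'
#' @param profile A `radial_profile` (see [generate_radial_profile()]).
#' @param config A [geometry_config()]; `dimer_thickness_nm` sets the
#'   class boundary between a single decorating layer and multi-layer
#'   assemblies (boundary inclusive).
#' @param bg_tail_nm Width of the outer tail used for background
#'   statistics.
#' @param persistence Consecutive above-threshold samples required.
#' @return A list: `thickness_nm`, `layer_class` ("within_single_dimer" or
#'   "multi_layer"), `wall_outer_radius_nm`, `threshold`.
#' @export
decoration_thickness <- function(profile, config = geometry_config(),
                                 bg_tail_nm = 10, persistence = 3L) {
  r <- profile$radius_nm
  y <- profile$intensity
  if (max(r) < profile$mt_radius_nm + 40)
    stop("profile must extend >= 40 nm beyond the wall", call. = FALSE)
  tail_idx <- r >= max(r) - bg_tail_nm
  bg_mean <- mean(y[tail_idx])
  bg_sd <- stats::sd(y[tail_idx])
  thr <- bg_mean + 3 * bg_sd

  i_wall <- which.max(y)
  if (y[i_wall] <= thr + 3 * bg_sd)
    stop("wall not detectable above background", call. = FALSE)
  # outer wall edge: half-maximum crossing outside the wall peak
  half <- (y[i_wall] + bg_mean) / 2
  i_edge <- i_wall
  while (i_edge < length(y) && y[i_edge + 1L] > half) i_edge <- i_edge + 1L
  wall_outer <- r[i_edge]

  above <- y > thr
  # outermost run of >= persistence consecutive above-threshold samples
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  runs <- which(rl$values & rl$lengths >= persistence)
  if (!length(runs))
    stop("wall not detectable above background", call. = FALSE)
  outer_idx <- ends[runs[length(runs)]]
  thickness <- max(0, r[outer_idx] - wall_outer)
  list(thickness_nm = thickness,
       layer_class = if (thickness <= config$dimer_thickness_nm)
         "within_single_dimer" else "multi_layer",
       wall_outer_radius_nm = wall_outer, threshold = thr)
}

#' Convert an oligomer train length to a copy number
#'
#' A train decorating every tubulin monomer of one protofilament has one
#' copy every `monomer_spacing_nm` (4.1 nm), so a train of length L
#' carries `floor(L / spacing) + 1` copies (fencepost counting).
#'
#' @param train_length_nm Train length(s) in nm, >= 0.
#' @param config A [geometry_config()].
#' @return Integer copy number(s).
#' @examples
#' train_copy_number(41.0)  # 11
#' @export
train_copy_number <- function(train_length_nm, config = geometry_config()) {
  if (any(!is.finite(train_length_nm)) || any(train_length_nm < 0))
    stop_field("train_length_nm", "must be finite and >= 0")
  as.integer(floor(train_length_nm / config$monomer_spacing_nm + 1e-9) + 1L)
}

#' Classify an oligomer as at the end or distal to it
#'
#' An oligomer whose plus-end-most point lies within
#' `contact_distance_nm` (50 nm, inclusive) of the nearest protofilament
#' flare onset can contact the bent protofilaments directly and is
#' classified `at_end`; otherwise `distal`.
#'
#' @param oligomer_plus_z_nm Axial coordinate of the oligomer's plus-most
#'   point (same axis model as the flare onset).
#' @param flare_onset_z_nm Axial coordinate of the minus-most flare onset.
#' @param config A [geometry_config()].
#' @return `"at_end"` or `"distal"`.
#' @export
classify_oligomer_position <- function(oligomer_plus_z_nm, flare_onset_z_nm,
                                       config = geometry_config()) {
  check_scalar(oligomer_plus_z_nm, "oligomer_plus_z_nm")
  check_scalar(flare_onset_z_nm, "flare_onset_z_nm")
  gap <- max(0, flare_onset_z_nm - oligomer_plus_z_nm)
  if (gap <= config$contact_distance_nm) "at_end" else "distal"
}
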