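#' Geometric-analysis configuration
#'
#' Thresholds and step sizes for per-end geometry: trace resampling, bend
#' detection, oligomer proximity classification, and the monomer repeat used
#' to convert oligomer train lengths to copy numbers.
#'
#' @param resample_step_nm Uniform arclength resampling step (nm).
#' @param bend_radial_excess_nm Radial excess over the fitted lattice
#'   cylinder (nm) above which a sample counts as bent.
#' @param bend_persistence_samples Number of consecutive above-threshold
#'   samples required to call a bend (guards against point noise).
#' @param contact_distance_nm Maximal axial gap (nm) between an oligomer and
#'   the nearest protofilament flare for the oligomer to be classified as
#'   sitting "at the end" (direct contact possible). Default 50.
#' @param monomer_spacing_nm Axial tubulin repeat (nm) used for copy-number
#'   conversion. Default 4.1.
#' @param dimer_thickness_nm Expected radial extent of a single decorating
#'   dimer (nm); the class boundary for decoration-thickness measurements.
#'   Default 18.
#' @param smooth_traces Smooth traces with [smooth_trace()] before
#'   geometric analysis (default TRUE); point noise otherwise inflates
#'   arclength-based measurements.
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(resample_step_nm = 1.0,
                            bend_radial_excess_nm = 1.5,
                            bend_persistence_samples = 3L,
                            contact_distance_nm = 50,
                            monomer_spacing_nm = 4.1,
                            dimer_thickness_nm = 18,
                            smooth_traces = TRUE) {
  check_scalar(resample_step_nm, "resample_step_nm", positive = TRUE)
  check_scalar(bend_radial_excess_nm, "bend_radial_excess_nm", positive = TRUE)
  check_scalar(bend_persistence_samples, "bend_persistence_samples",
               positive = TRUE, integerish = TRUE)
  check_scalar(contact_distance_nm, "contact_distance_nm", positive = TRUE)
  check_scalar(monomer_spacing_nm, "monomer_spacing_nm", positive = TRUE)
  check_scalar(dimer_thickness_nm, "dimer_thickness_nm", positive = TRUE)
  structure(list(resample_step_nm = resample_step_nm,
                 bend_radial_excess_nm = bend_radial_excess_nm,
                 bend_persistence_samples = as.integer(bend_persistence_samples),
                 contact_distance_nm = contact_distance_nm,
                 monomer_spacing_nm = monomer_spacing_nm,
                 dimer_thickness_nm = dimer_thickness_nm,
                 smooth_traces = isTRUE(smooth_traces)),
            class = "geometry_config")
}

#' Lateral-clustering configuration
#'
#' Parameters of the weighted overlap score between neighbouring bent
#' protofilaments and of the clustering threshold sweep. The default
#' threshold 0.1 corresponds to at least 50% of the weighted linear
#' distances between protofilaments deviating by less than 20% from the
#' lattice neighbour spacing, over their full mutual bent overlap.
#'
#' @param deviation_tolerance Relative deviation of a matched inter-trace
#'   distance from `d_ref` below which the sample counts as laterally
#'   associated. Default 0.20.
#' @param overlap_threshold Overlap score above (or equal to) which two
#'   neighbouring protofilaments are linked. Default 0.10.
#' @param sweep_thresholds Ascending thresholds for robustness sweeps.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(deviation_tolerance = 0.20,
                           overlap_threshold = 0.10,
                           sweep_thresholds = c(0.03, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  check_scalar(deviation_tolerance, "deviation_tolerance", unit = TRUE)
  if (deviation_tolerance <= 0 || deviation_tolerance >= 1)
    stop_field("deviation_tolerance", "must lie strictly in (0, 1)")
  check_scalar(overlap_threshold, "overlap_threshold")
  if (overlap_threshold <= 0 || overlap_threshold > 1)
    stop_field("overlap_threshold", "must lie in (0, 1]")
  if (!is.numeric(sweep_thresholds) || any(!is.finite(sweep_thresholds)) ||
      is.unsorted(sweep_thresholds, strictly = TRUE))
    stop_field("sweep_thresholds", "must be strictly ascending numerics")
  structure(list(deviation_tolerance = deviation_tolerance,
                 overlap_threshold = overlap_threshold,
                 sweep_thresholds = sweep_thresholds),
            class = "cluster_config")
}

#' Seed-exclusion configuration
#'
#' Plus ends of short microtubules with an expanded lattice are likely the
#' ends of stable GMPCPP seeds rather than GDP ends, and are excluded from
#' end-shape analysis.
#'
#' @param min_length_um Length (micrometres) below which a microtubule is
#'   considered possibly seed-only. Default 3.
#' @param expanded_spacing_cutoff_nm Lattice spacing (nm) above which the
#'   lattice is considered expanded. Default 4.16.
#' @return A list of class `seed_filter_config`.
#' @export
seed_filter_config <- function(min_length_um = 3.0,
                               expanded_spacing_cutoff_nm = 4.16) {
  check_scalar(min_length_um, "min_length_um", positive = TRUE)
  check_scalar(expanded_spacing_cutoff_nm, "expanded_spacing_cutoff_nm",
               positive = TRUE)
  structure(list(min_length_um = min_length_um,
                 expanded_spacing_cutoff_nm = expanded_spacing_cutoff_nm),
            class = "seed_filter_config")
}

#' Dwell-time analysis configuration
#'
#' @param long_threshold_s Residence-time boundary (s) between short and
#'   long events. Default 0.32.
#' @param robustness_thresholds_s Alternative boundaries at which the
#'   short/long split is recomputed. Defaults 0.2 and 0.4.
#' @param detection_sd Intensity detection threshold in units of background
#'   standard deviations. Default 5.
#' @param min_event_frames Minimal event length in frames. Default 1.
#' @return A list of class `dwell_config`.
#' @export
dwell_config <- function(long_threshold_s = 0.32,
                         robustness_thresholds_s = c(0.2, 0.4),
                         detection_sd = 5,
                         min_event_frames = 1L) {
  check_scalar(long_threshold_s, "long_threshold_s", positive = TRUE)
  if (!is.numeric(robustness_thresholds_s) || any(robustness_thresholds_s <= 0))
    stop_field("robustness_thresholds_s", "must be positive numerics")
  check_scalar(detection_sd, "detection_sd", positive = TRUE)
  check_scalar(min_event_frames, "min_event_frames", positive = TRUE,
               integerish = TRUE)
  structure(list(long_threshold_s = long_threshold_s,
                 robustness_thresholds_s = robustness_thresholds_s,
                 detection_sd = detection_sd,
                 min_event_frames = as.integer(min_event_frames)),
            class = "dwell_config")
}
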