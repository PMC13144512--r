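#' Parameters for synthetic microtubule-end generation
#'
#' Describes an end as a straight cylindrical lattice region followed by
#' per-protofilament flares: outwardly curved segments of variable length
#' and curvature. Protofilaments listed in `cluster_spec` peel off as
#' laterally associated sheets: members of one cluster leave the lattice at
#' a common axial position and follow a common arc, so neighbouring members
#' stay at the lattice neighbour spacing `d_ref` along the whole flare.
#' Solitary flares bend radially outward in their own axial plane, with
#' independently drawn bend-onset positions (taper) and curvatures, so
#' their mutual distances grow with arclength.
#'
#' Flare lengths are drawn lognormal by default; the distribution family of
#' real flares is not constrained by the data this emulates, and the choice
#' is a fixture convention, not a claim.
#'
#' @param lattice A [lattice_model()].
#' @param lattice_length_nm Mean length of the straight lattice region below
#'   the flare onsets (nm).
#' @param flare_length_mean_nm,flare_length_sd_nm Mean and SD (nm) of the
#'   flare arclength distribution.
#' @param flare_length_family `"lognormal"` (default), `"gamma"`, or
#'   `"constant"` (ignores the SD).
#' @param curvature_per_nm Mean flare curvature (1/nm); default 0.04,
#'   i.e. a 25 nm radius of curvature.
#' @param curvature_sd_per_nm SD of per-flare curvature (1/nm).
#' @param unbent_fraction Probability that a protofilament outside any
#'   cluster has no flare at all.
#' @param cluster_spec Integer vector of cluster sizes (each >= 2); their
#'   sum must not exceed `n_pf`. Members are placed on angularly contiguous
#'   protofilaments.
#' @param taper_sd_nm SD (nm) of the axial bend-onset (or terminus)
#'   positions across protofilaments — the ground-truth raggedness scale.
#' @param point_noise_sd_nm Isotropic Gaussian noise added to every sampled
#'   point (nm per coordinate).
#' @param sample_step_nm Arclength sampling step of the emitted polylines.
#' @param length_um Microtubule length (micrometres) recorded on the end,
#'   for seed filtering downstream.
#' @param seed RNG seed (mandatory).
#' @return A list of class `end_gen_params`.
#' @export
end_gen_params <- function(lattice = lattice_model(),
                           lattice_length_nm = 100,
                           flare_length_mean_nm = 40,
                           flare_length_sd_nm = 15,
                           flare_length_family = c("lognormal", "gamma", "constant"),
                           curvature_per_nm = 0.04,
                           curvature_sd_per_nm = 0.01,
                           unbent_fraction = 0.3,
                           cluster_spec = integer(0),
                           taper_sd_nm = 15,
                           point_noise_sd_nm = 0.5,
                           sample_step_nm = 1.0,
                           length_um = 6.0,
                           seed = NULL) {
  stopifnot(inherits(lattice, "lattice_model"))
  flare_length_family <- match.arg(flare_length_family)
  check_scalar(lattice_length_nm, "lattice_length_nm", positive = TRUE)
  check_scalar(flare_length_mean_nm, "flare_length_mean_nm", positive = TRUE)
  check_scalar(flare_length_sd_nm, "flare_length_sd_nm", nonneg = TRUE)
  check_scalar(curvature_per_nm, "curvature_per_nm", positive = TRUE)
  check_scalar(curvature_sd_per_nm, "curvature_sd_per_nm", nonneg = TRUE)
  check_scalar(unbent_fraction, "unbent_fraction", unit = TRUE)
  check_scalar(taper_sd_nm, "taper_sd_nm", nonneg = TRUE)
  check_scalar(point_noise_sd_nm, "point_noise_sd_nm", nonneg = TRUE)
  check_scalar(sample_step_nm, "sample_step_nm", positive = TRUE)
  check_scalar(length_um, "length_um", positive = TRUE)
  if (length(cluster_spec)) {
    if (any(cluster_spec < 2) || any(cluster_spec != round(cluster_spec)))
      stop_field("cluster_spec", "cluster sizes must be integers >= 2")
    if (sum(cluster_spec) > lattice$n_pf)
      stop_field("cluster_spec", "cluster sizes must sum to at most n_pf")
  }
  seed <- check_seed(seed)
  structure(list(lattice = lattice, lattice_length_nm = lattice_length_nm,
                 flare_length_mean_nm = flare_length_mean_nm,
                 flare_length_sd_nm = flare_length_sd_nm,
                 flare_length_family = flare_length_family,
                 curvature_per_nm = curvature_per_nm,
                 curvature_sd_per_nm = curvature_sd_per_nm,
                 unbent_fraction = unbent_fraction,
                 cluster_spec = as.integer(cluster_spec),
                 taper_sd_nm = taper_sd_nm,
                 point_noise_sd_nm = point_noise_sd_nm,
                 sample_step_nm = sample_step_nm,
                 length_um = length_um, seed = seed),
            class = "end_gen_params")
}

draw_flare_lengths <- function(n, mean, sd, family) {
  if (family == "constant" || sd == 0) return(rep(mean, n))
  switch(family,
    lognormal = {
      sdlog <- sqrt(log1p((sd / mean)^2))
      meanlog <- log(mean) - sdlog^2 / 2
      rlnorm(n, meanlog, sdlog)
    },
    gamma = {
      shape <- (mean / sd)^2
      rgamma(n, shape = shape, rate = shape / mean)
    })
}

# place cluster runs on angularly contiguous, non-overlapping protofilaments
place_clusters <- function(sizes, n_pf) {
  taken <- rep(FALSE, n_pf)
  out <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    k <- sizes[ci]
    starts <- sample.int(n_pf)
    placed <- FALSE
    for (st in starts) {
      run <- ((st - 1L + 0:(k - 1L)) %% n_pf) + 1L
      if (!any(taken[run])) {
        taken[run] <- TRUE
        out[[ci]] <- run
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_field("cluster_spec", "could not place non-overlapping clusters")
  }
  out
}

#' Generate a synthetic microtubule end with ground truth
#'
#' Samples protofilament traces from the model described by
#' [end_gen_params()]: a straight region on the lattice cylinder, then (for
#' flared protofilaments) a circular arc departing tangentially with the
#' drawn curvature. Clustered protofilaments share an onset and a common
#' arc displacement, so adjacent members remain exactly `d_ref` apart at
#' matched arclengths (before noise).
#'
#' @param params An [end_gen_params()].
#' @param end_id Id given to the generated end.
#' @param condition Condition label recorded on the end.
#' @return A list with elements `end` (an [mt_end()]) and `truth`, the
#'   ground truth: per-protofilament table (`pf_id`, `bent`,
#'   `onset_arclength_nm`, `flare_length_nm`, `curvature_per_nm`,
#'   `cluster_id`), the partition of bent protofilaments into clusters,
#'   `raggedness_nm` (population SD of onset/terminus axial positions), and
#'   `lattice_spacing_nm`.
#' @examples
#' gen <- generate_end(end_gen_params(cluster_spec = 3, seed = 1))
#' gen$truth$partition
#' @export
generate_end <- function(params, end_id = "end1", condition = NA_character_) {
  stopifnot(inherits(params, "end_gen_params"))
  with_seed(params$seed, {
    lat <- params$lattice
    n_pf <- lat$n_pf
    R <- lat$radius_nm
    step <- params$sample_step_nm

    clusters <- if (length(params$cluster_spec))
      place_clusters(params$cluster_spec, n_pf) else list()
    in_cluster <- integer(n_pf)            # 0 = not in a cluster
    for (ci in seq_along(clusters)) in_cluster[clusters[[ci]]] <- ci

    bent <- logical(n_pf)
    bent[in_cluster > 0L] <- TRUE
    free <- which(in_cluster == 0L)
    bent[free] <- runif(length(free)) >= params$unbent_fraction

    # axial onset (bent) / terminus (unbent) positions: ragged taper
    onset_z <- params$lattice_length_nm + rnorm(n_pf, 0, params$taper_sd_nm)
    for (ci in seq_along(clusters))       # one shared onset per sheet
      onset_z[clusters[[ci]]] <- params$lattice_length_nm +
        rnorm(1, 0, params$taper_sd_nm)
    onset_z <- pmax(onset_z, 4 * step)

    flare_len <- rep(NA_real_, n_pf)
    curv <- rep(NA_real_, n_pf)
    n_bent <- sum(bent)
    if (n_bent) {
      flare_len[bent] <- pmax(draw_flare_lengths(
        n_bent, params$flare_length_mean_nm, params$flare_length_sd_nm,
        params$flare_length_family), 2 * step)
      curv[bent] <- pmax(rnorm(n_bent, params$curvature_per_nm,
                               params$curvature_sd_per_nm), 0.005)
    }
    for (ci in seq_along(clusters)) {     # sheets share one arc template
      m <- clusters[[ci]]
      flare_len[m] <- flare_len[m[1]]
      curv[m] <- curv[m[1]]
    }

    phi <- 2 * pi * (seq_len(n_pf) - 1L) / n_pf
    traces <- vector("list", n_pf)
    for (i in seq_len(n_pf)) {
      z0 <- onset_z[i]
      total <- if (bent[i]) z0 + flare_len[i] else z0
      s <- seq(0, total, by = step)
      if (s[length(s)] < total) s <- c(s, total)
      base <- c(R * cos(phi[i]), R * sin(phi[i]))
      # radial bending direction: own plane for solitary flares, the
      # cluster's mean angular direction for sheet members
      if (bent[i] && in_cluster[i] > 0L) {
        m <- clusters[[in_cluster[i]]]
        # circular mean of member angles (handles wrap-around runs)
        ang <- atan2(mean(sin(phi[m])), mean(cos(phi[m])))
        rhat <- c(cos(ang), sin(ang), 0)
      } else {
        rhat <- c(cos(phi[i]), sin(phi[i]), 0)
      }
      pts <- matrix(0, length(s), 3L)
      straight <- s <= z0
      pts[straight, 1] <- base[1]
      pts[straight, 2] <- base[2]
      pts[straight, 3] <- s[straight]
      if (any(!straight)) {
        u <- s[!straight] - z0
        k <- curv[i]
        dz <- sin(k * u) / k
        dr <- (1 - cos(k * u)) / k
        pts[!straight, 1] <- base[1] + dr * rhat[1]
        pts[!straight, 2] <- base[2] + dr * rhat[2]
        pts[!straight, 3] <- z0 + dz
      }
      if (params$point_noise_sd_nm > 0)
        pts <- pts + matrix(rnorm(length(pts), 0, params$point_noise_sd_nm),
                            ncol = 3L)
      traces[[i]] <- pf_trace(end_id, i, pts)
    }

    cluster_id <- rep(NA_integer_, n_pf)
    next_id <- 1L
    for (ci in seq_along(clusters)) {
      cluster_id[clusters[[ci]]] <- next_id
      next_id <- next_id + 1L
    }
    for (i in which(bent & in_cluster == 0L)) {
      cluster_id[i] <- next_id
      next_id <- next_id + 1L
    }
    partition <- split(which(bent), cluster_id[bent])
    partition <- unname(lapply(partition, as.integer))

    ragged_ref <- onset_z                  # onset for bent, terminus otherwise
    truth <- list(
      per_pf = data.frame(
        pf_id = seq_len(n_pf), bent = bent,
        onset_arclength_nm = ifelse(bent, onset_z, NA_real_),
        terminus_z_nm = ifelse(bent, NA_real_, onset_z),
        flare_length_nm = flare_len, curvature_per_nm = curv,
        cluster_id = cluster_id),
      partition = partition,
      raggedness_nm = sqrt(mean((ragged_ref - mean(ragged_ref))^2)),
      lattice_spacing_nm = lat$monomer_spacing_nm)

    list(end = mt_end(end_id, traces, condition = condition,
                      length_um = params$length_um, n_pf = n_pf),
         truth = truth)
  })
}
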