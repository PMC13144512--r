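#' Generate a periodic lattice intensity profile
#'
#' Emulates an axial intensity profile along a microtubule wall near the
#' plus end, whose dominant spatial period is the tubulin monomer repeat.
#' The profile is a raised cosine with a weaker second harmonic plus
#' Gaussian noise, sampled finely enough (`spacing_nm / 16`) to resolve the
#' period.
#'
#' @param spacing_nm True axial repeat (nm), > 0.
#' @param n_repeats Number of repeats covered; at least 8, otherwise the
#'   period cannot be estimated reliably.
#' @param noise_sd Gaussian noise SD relative to the unit-amplitude
#'   fundamental.
#' @param seed RNG seed (mandatory).
#' @param sample_step_nm Sampling interval; must be <= `spacing_nm / 8`.
#' @return An object of class `intensity_profile`: `position_nm`,
#'   `intensity`, `step_nm`, `true_spacing_nm`.
#' @export
generate_intensity_profile <- function(spacing_nm, n_repeats, noise_sd = 0,
                                       seed = NULL,
                                       sample_step_nm = spacing_nm / 16) {
  check_scalar(spacing_nm, "spacing_nm", positive = TRUE)
  check_scalar(n_repeats, "n_repeats", positive = TRUE, integerish = TRUE)
  if (n_repeats < 8)
    stop_field("n_repeats", "at least 8 repeats are needed to resolve the period")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(sample_step_nm, "sample_step_nm", positive = TRUE)
  if (sample_step_nm > spacing_nm / 8)
    stop_field("sample_step_nm", "must be <= spacing_nm / 8")
  seed <- check_seed(seed)
  with_seed(seed, {
    x <- seq(0, spacing_nm * n_repeats, by = sample_step_nm)
    phase <- runif(1, 0, 2 * pi)
    y <- 1 + cos(2 * pi * x / spacing_nm + phase) +
      0.25 * cos(4 * pi * x / spacing_nm + 2 * phase)
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    structure(list(position_nm = x, intensity = y, step_nm = sample_step_nm,
                   true_spacing_nm = spacing_nm),
              class = "intensity_profile")
  })
}

#' Generate a radial intensity profile of a decorated microtubule
#'
#' Emulates an axial-projection profile versus distance from the
#' microtubule axis: a dim lumen, a bright wall at the microtubule radius,
#' a decoration shell of the stated thickness directly outside the wall,
#' and background beyond.
#'
#' @param mt_radius_nm Outer-wall centre radius (nm).
#' @param decoration_thickness_nm Radial extent of the decoration shell
#'   outside the wall (nm, >= 0).
#' @param level Decoration intensity (the wall is drawn at `3 * level`).
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed (mandatory).
#' @param wall_half_width_nm Half-width of the wall density (nm).
#' @param r_max_nm Outermost radius sampled; must exceed
#'   `mt_radius_nm + 40`.
#' @param step_nm Radial sampling step.
#' @return An object of class `radial_profile`: `radius_nm`, `intensity`,
#'   `mt_radius_nm`, `wall_half_width_nm`, `true_thickness_nm`.
#' @export
generate_radial_profile <- function(mt_radius_nm = 12.5,
                                    decoration_thickness_nm = 0,
                                    level = 1, noise_sd = 0.02, seed = NULL,
                                    wall_half_width_nm = 2,
                                    r_max_nm = mt_radius_nm + 60,
                                    step_nm = 0.25) {
  check_scalar(mt_radius_nm, "mt_radius_nm", positive = TRUE)
  check_scalar(decoration_thickness_nm, "decoration_thickness_nm", nonneg = TRUE)
  check_scalar(level, "level", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(wall_half_width_nm, "wall_half_width_nm", positive = TRUE)
  check_scalar(step_nm, "step_nm", positive = TRUE)
  if (r_max_nm < mt_radius_nm + 40)
    stop_field("r_max_nm", "profile must extend >= 40 nm beyond the wall")
  seed <- check_seed(seed)
  with_seed(seed, {
    r <- seq(0, r_max_nm, by = step_nm)
    y <- numeric(length(r))
    wall <- abs(r - mt_radius_nm) <= wall_half_width_nm
    y[wall] <- 3 * level
    shell <- r > mt_radius_nm + wall_half_width_nm &
      r <= mt_radius_nm + wall_half_width_nm + decoration_thickness_nm
    y[shell] <- level
    lumen <- r < mt_radius_nm - wall_half_width_nm
    y[lumen] <- 0.1 * level
    if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
    structure(list(radius_nm = r, intensity = y, mt_radius_nm = mt_radius_nm,
                   wall_half_width_nm = wall_half_width_nm,
                   true_thickness_nm = decoration_thickness_nm),
              class = "radial_profile")
  })
}
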