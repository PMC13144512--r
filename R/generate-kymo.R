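#' Kymograph object
#'
#' A position-versus-time intensity array: rows are frames (time increasing
#' downward), columns are positions along the microtubule with the seed at
#' low column indices.
#'
#' @param intensity Numeric matrix (rows = time, cols = position).
#' @param pixel_nm Pixel size along the position axis (nm).
#' @param frame_s Frame interval (s).
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(intensity, pixel_nm, frame_s) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop_field("intensity", "must be a numeric matrix")
  if (any(!is.finite(intensity)))
    stop_field("intensity", "must be finite")
  check_scalar(pixel_nm, "pixel_nm", positive = TRUE)
  check_scalar(frame_s, "frame_s", positive = TRUE)
  structure(list(intensity = unname(intensity), pixel_nm = pixel_nm,
                 frame_s = frame_s),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d px (%.0f nm/px, %.3f s/frame)\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_nm, x$frame_s))
  invisible(x)
}

#' Parameters for synthetic kymograph generation
#'
#' Emulates a decorated dynamic microtubule imaged by TIRF: a microtubule
#' spanning columns `mt_cols`, a brighter tip-proximal envelope separated
#' from the dimmer lattice by a time-stationary boundary at `boundary_col`,
#' an optional growing tip, an optional FRAP bleach, and optional transient
#' single-molecule binding events.
#'
#' @param n_rows Number of frames.
#' @param n_cols Number of position pixels.
#' @param pixel_nm Pixel size (nm).
#' @param frame_s Frame interval (s).
#' @param background_level,lattice_level,envelope_level Intensity levels;
#'   must satisfy `envelope_level >= lattice_level >= background_level >= 0`.
#' @param mt_cols Integer range (2-vector) of columns covered by the
#'   microtubule at frame 1, seed at the low end.
#' @param boundary_col Column of the envelope/lattice boundary (envelope on
#'   the high-column, tip-proximal side). `NA` for no envelope.
#' @param growth_speed_px_per_frame Tip growth speed; 0 keeps the tip
#'   stationary.
#' @param frap Optional list `(bleach_frame, bleach_cols, recovery_fraction,
#'   recovery_rate_per_s)`: at `bleach_frame` the decorated signal within
#'   `bleach_cols` drops to background and recovers exponentially toward
#'   `recovery_fraction` of the bleached-away signal.
#' @param events Optional list `(n, duration_mixture, intensity, dimer_fraction,
#'   intensity_cv)` describing transient binding events; `duration_mixture` is
#'   a data frame with columns `weight` and `mean_s`.
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed (mandatory).
#' @return A list of class `kymo_gen_params`.
#' @export
kymo_gen_params <- function(n_rows = 200L, n_cols = 200L, pixel_nm = 100,
                            frame_s = 0.5, background_level = 10,
                            lattice_level = 20, envelope_level = 30,
                            mt_cols = c(20L, 160L), boundary_col = 110L,
                            growth_speed_px_per_frame = 0,
                            frap = NULL, events = NULL,
                            noise_sd = 0, seed = NULL) {
  check_scalar(n_rows, "n_rows", positive = TRUE, integerish = TRUE)
  check_scalar(n_cols, "n_cols", positive = TRUE, integerish = TRUE)
  check_scalar(pixel_nm, "pixel_nm", positive = TRUE)
  check_scalar(frame_s, "frame_s", positive = TRUE)
  check_scalar(background_level, "background_level", nonneg = TRUE)
  check_scalar(lattice_level, "lattice_level", nonneg = TRUE)
  check_scalar(envelope_level, "envelope_level", nonneg = TRUE)
  if (lattice_level < background_level)
    stop_field("lattice_level", "must be >= background_level")
  if (envelope_level < lattice_level)
    stop_field("envelope_level", "must be >= lattice_level")
  if (length(mt_cols) != 2L || mt_cols[1] < 1 || mt_cols[2] > n_cols ||
      mt_cols[1] >= mt_cols[2])
    stop_field("mt_cols", "must be an increasing 2-vector within the image")
  if (!is.na(boundary_col) &&
      (boundary_col <= mt_cols[1] || boundary_col > mt_cols[2]))
    stop_field("boundary_col", "must lie inside mt_cols")
  check_scalar(growth_speed_px_per_frame, "growth_speed_px_per_frame",
               nonneg = TRUE)
  if (!is.null(frap)) {
    check_scalar(frap$bleach_frame, "frap$bleach_frame", positive = TRUE,
                 integerish = TRUE)
    if (frap$bleach_frame >= n_rows)
      stop_field("frap$bleach_frame", "must precede the last frame")
    if (length(frap$bleach_cols) != 2L || frap$bleach_cols[1] >= frap$bleach_cols[2])
      stop_field("frap$bleach_cols", "must be an increasing 2-vector")
    check_scalar(frap$recovery_fraction, "frap$recovery_fraction", unit = TRUE)
    check_scalar(frap$recovery_rate_per_s, "frap$recovery_rate_per_s",
                 positive = TRUE)
  }
  if (!is.null(events)) {
    check_scalar(events$n, "events$n", nonneg = TRUE, integerish = TRUE)
    if (!is.data.frame(events$duration_mixture) ||
        !all(c("weight", "mean_s") %in% names(events$duration_mixture)))
      stop_field("events$duration_mixture",
                 "needs columns `weight` and `mean_s`")
    check_scalar(events$intensity, "events$intensity", positive = TRUE)
  }
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  seed <- check_seed(seed)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_nm = pixel_nm, frame_s = frame_s,
                 background_level = background_level,
                 lattice_level = lattice_level,
                 envelope_level = envelope_level,
                 mt_cols = as.integer(mt_cols),
                 boundary_col = if (is.na(boundary_col)) NA_integer_
                                else as.integer(boundary_col),
                 growth_speed_px_per_frame = growth_speed_px_per_frame,
                 frap = frap, events = events, noise_sd = noise_sd,
                 seed = seed),
            class = "kymo_gen_params")
}

#' Generate a synthetic kymograph with ground truth
#'
#' @param params A [kymo_gen_params()].
#' @return A list with `kymo` (a [kymograph()]) and `truth` recording the
#'   boundary column, level means, tip position per frame, FRAP settings,
#'   and the placed events (start frame, duration frames, columns).
#' @export
generate_kymograph <- function(params) {
  stopifnot(inherits(params, "kymo_gen_params"))
  with_seed(params$seed, {
    nr <- params$n_rows; nc <- params$n_cols
    img <- matrix(params$background_level, nr, nc)
    tip <- pmin(params$mt_cols[2] +
                  floor(params$growth_speed_px_per_frame * (seq_len(nr) - 1)),
                nc)
    for (t in seq_len(nr)) {
      span <- params$mt_cols[1]:tip[t]
      img[t, span] <- params$lattice_level
      if (!is.na(params$boundary_col)) {
        env <- span[span >= params$boundary_col]
        img[t, env] <- params$envelope_level
      }
    }
    if (!is.null(params$frap)) {
      fr <- params$frap
      cols <- max(fr$bleach_cols[1], 1):min(fr$bleach_cols[2], nc)
      post <- (fr$bleach_frame + 1L):nr
      dt <- (post - fr$bleach_frame - 1L) * params$frame_s
      rec <- fr$recovery_fraction * (1 - exp(-fr$recovery_rate_per_s * dt))
      for (j in seq_along(post)) {
        t <- post[j]
        decorated <- img[t, cols] - params$background_level
        img[t, cols] <- params$background_level + rec[j] * decorated
      }
    }
    ev_truth <- NULL
    if (!is.null(params$events) && params$events$n > 0) {
      ev <- params$events
      w <- ev$duration_mixture$weight / sum(ev$duration_mixture$weight)
      comp <- sample.int(nrow(ev$duration_mixture), ev$n, replace = TRUE,
                         prob = w)
      dur_s <- rexp(ev$n, rate = 1 / ev$duration_mixture$mean_s[comp])
      dur_f <- pmax(ceiling(dur_s / params$frame_s), 1L)
      start <- sample.int(nr, ev$n, replace = TRUE)
      col <- sample(seq(params$mt_cols[1], params$mt_cols[2]), ev$n,
                    replace = TRUE)
      dimer_fraction <- ev$dimer_fraction %||% 0
      cv <- ev$intensity_cv %||% 0
      is_dimer <- runif(ev$n) < dimer_fraction
      amp <- ev$intensity * ifelse(is_dimer, 2, 1)
      if (cv > 0) amp <- rnorm(ev$n, amp, cv * amp)
      for (e in seq_len(ev$n)) {
        rows <- start[e]:min(start[e] + dur_f[e] - 1L, nr)
        img[rows, col[e]] <- img[rows, col[e]] + amp[e]
      }
      ev_truth <- data.frame(start_frame = start, duration_frames = dur_f,
                             col = col, amplitude = amp, dimer = is_dimer,
                             censored = start + dur_f - 1L > nr)
    }
    clean_means <- list(background = params$background_level,
                        lattice = params$lattice_level,
                        envelope = params$envelope_level)
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, params$noise_sd), nr, nc)
    list(kymo = kymograph(img, params$pixel_nm, params$frame_s),
         truth = list(boundary_col = params$boundary_col,
                      mt_cols = params$mt_cols, tip_col = tip,
                      levels = clean_means, frap = params$frap,
                      events = ev_truth))
  })
}
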