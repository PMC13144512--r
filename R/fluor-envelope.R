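#' Detect the envelope/lattice boundary in a kymograph
#'
#' On the time-median spatial profile of the chosen frames, fits a
#' two-level step (piecewise constant with one change point) by least
#' squares over the microtubule's column span. The change point is
#' reported when the fitted step height exceeds 3x the residual SD;
#' otherwise no boundary is called.
#'
#' @param kymo A [kymograph()].
#' @param mt_cols 2-vector of columns spanned by the microtubule.
#' @param time_window Optional 2-vector of frames to use (default: all).
#' @return A list: `boundary_col` (NA when no credible step),
#'   `step_height`, `residual_sd`, `level_low`, `level_high` (means on the
#'   seed-proximal and tip-proximal side).
#' @export
detect_envelope_boundary <- function(kymo, mt_cols,
                                     time_window = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$intensity
  if (is.null(time_window)) time_window <- c(1L, nrow(img))
  if (time_window[1] > time_window[2] || time_window[1] < 1 ||
      time_window[2] > nrow(img))
    stop("empty or out-of-range time window", call. = FALSE)
  cols <- mt_cols[1]:mt_cols[2]
  prof <- apply(img[time_window[1]:time_window[2], cols, drop = FALSE],
                2L, stats::median)
  n <- length(prof)
  if (n < 3) stop("column span too narrow for a step fit", call. = FALSE)

  # least-squares single change point: minimise within-segment SSE
  cs <- cumsum(prof); cs2 <- cumsum(prof^2)
  best <- list(sse = Inf, cut = NA_integer_)
  for (cut in 1:(n - 1)) {
    n1 <- cut; n2 <- n - cut
    s1 <- cs[cut]; s2 <- cs[n] - s1
    sse <- (cs2[cut] - s1^2 / n1) + (cs2[n] - cs2[cut] - s2^2 / n2)
    if (sse < best$sse) best <- list(sse = sse, cut = cut)
  }
  cut <- best$cut
  m1 <- mean(prof[1:cut]); m2 <- mean(prof[(cut + 1):n])
  resid_sd <- sqrt(best$sse / max(n - 2, 1))
  height <- abs(m2 - m1)
  boundary <- if (height > 3 * resid_sd) cols[cut + 1L] else NA_integer_
  list(boundary_col = boundary, step_height = height,
       residual_sd = resid_sd, level_low = m1, level_high = m2)
}

#' Envelope/lattice intensity ratio
#'
#' Background-corrected intensity ratio of the tip-proximal envelope to
#' the rest of the lattice,
#' \eqn{(I_{env} - I_{BG}) / (I_{lat} - I_{BG})}, with all three
#' intensities measured as arithmetic means over boxed kymograph regions.
#'
#' @param kymo A [kymograph()].
#' @param envelope_roi,lattice_roi,bg_roi Lists with `rows` and `cols`
#'   (2-vectors) delimiting disjoint boxes; the background box sits next
#'   to the microtubule.
#' @return An object of class `envelope_measurement`: `I_envelope`,
#'   `I_lattice`, `I_BG`, `ratio`.
#' @export
envelope_ratio <- function(kymo, envelope_roi, lattice_roi, bg_roi) {
  stopifnot(inherits(kymo, "kymograph"))
  box_mean <- function(roi, what) {
    r <- roi$rows; cl <- roi$cols
    if (is.null(r) || is.null(cl) || r[1] > r[2] || cl[1] > cl[2] ||
        r[1] < 1 || r[2] > nrow(kymo$intensity) ||
        cl[1] < 1 || cl[2] > ncol(kymo$intensity))
      stop("invalid ", what, " ROI", call. = FALSE)
    mean(kymo$intensity[r[1]:r[2], cl[1]:cl[2]])
  }
  rois <- list(envelope = envelope_roi, lattice = lattice_roi, bg = bg_roi)
  cells <- lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    expand.grid(row = roi$rows[1]:roi$rows[2], col = roi$cols[1]:roi$cols[2],
                roi = nm)
  })
  all_cells <- do.call(rbind, cells)
  if (anyDuplicated(all_cells[, c("row", "col")]))
    stop("ROIs must be disjoint", call. = FALSE)
  ie <- box_mean(envelope_roi, "envelope")
  il <- box_mean(lattice_roi, "lattice")
  ib <- box_mean(bg_roi, "background")
  if (il <= ib)
    stop("undefined ratio: lattice intensity must exceed background",
         call. = FALSE)
  structure(list(I_envelope = ie, I_lattice = il, I_BG = ib,
                 ratio = (ie - ib) / (il - ib)),
            class = "envelope_measurement")
}
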