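#' Fitted microtubule axis and lattice cylinder
#'
#' Least-squares cylinder fit to all trace points of an end, using
#' iteratively re-weighted least squares with Tukey bisquare weights so
#' that flare points (large positive radial residuals) are down-weighted
#' and the fit reflects the intact lattice. The direction is oriented
#' toward the plus end (the direction of increasing point order).
#'
#' @param end An [mt_end()] with at least 3 protofilament traces of at
#'   least 4 points each.
#' @param config A [geometry_config()] (reserved for future options).
#' @param n_irls Number of re-weighting iterations.
#' @return An object of class `axis_model`: `origin` (point on the axis),
#'   `direction` (unit vector toward the plus end), `radius_nm`, and
#'   `boundary_z_nm`, the axial coordinate where the well-fitting lattice
#'   region ends.
#' @export
fit_axis <- function(end, config = geometry_config(), n_irls = 8L) {
  stopifnot(inherits(end, "mt_end"))
  if (length(end$traces) < 3L)
    stop("axis fit needs >= 3 protofilament traces", call. = FALSE)
  if (any(vapply(end$traces, function(tr) nrow(tr$points), 0L) < 4L))
    stop("axis fit needs >= 4 points per trace", call. = FALSE)
  pts <- do.call(rbind, lapply(end$traces, `[[`, "points"))

  # initialise from the minus-end portion of each trace: traces run
  # minus -> plus, so the first points lie on the intact lattice while
  # flares sit at the plus end and would tilt a naive first fit
  sub <- do.call(rbind, lapply(end$traces, function(tr) {
    n <- nrow(tr$points)
    tr$points[seq_len(max(4L, floor(0.6 * n))), , drop = FALSE]
  }))
  ctr <- colMeans(sub)
  sv <- svd(sweep(sub, 2L, ctr))
  v0 <- sv$v[, 1]
  # rotation taking v0 to +z
  rot <- rotation_to_z(v0)
  q <- pts %*% t(rot)
  qsub <- sub %*% t(rot)

  # degenerate (coplanar) input: no circular cross-section to fit
  ev <- eigen(stats::cov(q[, 1:2]), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-9 * max(ev[1], 1))
    stop("degenerate geometry: trace points are coplanar", call. = FALSE)

  par <- c(mean(qsub[, 1]), mean(qsub[, 2]), 0, 0)
  # robust starting weights so flare points never dominate an iteration
  d0 <- axis_point_dist(q, par)
  res0 <- d0 - stats::median(d0)
  s0 <- max(1.4826 * stats::median(abs(res0)), 1e-3)
  u0 <- res0 / (4.685 * s0)
  w <- ifelse(abs(u0) < 1, (1 - u0^2)^2, 0)
  if (sum(w > 0) < 6) w <- rep(1, nrow(q))
  for (it in seq_len(n_irls)) {
    obj <- function(p) {
      d <- axis_point_dist(q, p)
      r <- sum(w * d) / sum(w)
      sum(w * (d - r)^2)
    }
    par <- stats::optim(par, obj, method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 200))$par
    d <- axis_point_dist(q, par)
    r <- sum(w * d) / sum(w)
    res <- d - r
    s <- 1.4826 * stats::median(abs(res))
    s <- max(s, 1e-3)
    u <- res / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 6) { w <- rep(1, nrow(q)); break }
  }
  d <- axis_point_dist(q, par)
  radius <- sum(w * d) / sum(w)

  u <- unitize(c(par[3], par[4], 1))       # direction in rotated frame
  direction <- as.numeric(t(rot) %*% u)
  origin <- as.numeric(t(rot) %*% c(par[1], par[2], 0))

  # orient toward the plus end: increasing point order
  heads <- rowMeans(vapply(end$traces, function(tr)
    tr$points[nrow(tr$points), ] - tr$points[1, ], numeric(3)))
  if (sum(heads * direction) < 0) direction <- -direction

  zax <- (pts %*% direction) - sum(origin * direction)
  lattice_like <- w > 0.5
  boundary_z <- if (any(lattice_like)) max(zax[lattice_like]) else max(zax)

  structure(list(origin = origin, direction = direction,
                 radius_nm = radius, boundary_z_nm = boundary_z),
            class = "axis_model")
}

# rotation matrix R with R %*% v = e_z
rotation_to_z <- function(v) {
  v <- unitize(v)
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  ax <- unitize(c(v[2] * z[3] - v[3] * z[2],
                  v[3] * z[1] - v[1] * z[3],
                  v[1] * z[2] - v[2] * z[1]))
  s <- sqrt(1 - c_^2)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

# distances from points (rotated frame) to the axis line
# parametrised by p = (cx, cy, sx, sy): line (cx,cy,0) + t*(sx,sy,1)
axis_point_dist <- function(q, p) {
  u <- unitize(c(p[3], p[4], 1))
  w1 <- q[, 1] - p[1]
  w2 <- q[, 2] - p[2]
  w3 <- q[, 3]
  proj <- w1 * u[1] + w2 * u[2] + w3 * u[3]
  sqrt(pmax(w1^2 + w2^2 + w3^2 - proj^2, 0))
}

#' Axial and radial coordinates of points relative to a fitted axis
#'
#' @param axis An `axis_model` from [fit_axis()].
#' @param points An n x 3 matrix of coordinates (nm).
#' @return A data frame with `z_nm` (signed axial coordinate along the
#'   plus-end direction) and `r_nm` (distance from the axis).
#' @export
axis_coords <- function(axis, points) {
  stopifnot(inherits(axis, "axis_model"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  w <- sweep(points, 2L, axis$origin)
  z <- as.numeric(w %*% axis$direction)
  r <- sqrt(pmax(rowSums(w^2) - z^2, 0))
  data.frame(z_nm = z, r_nm = r)
}
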