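#' Detect single-molecule dwell events in a kymograph
#'
#' Thresholds the kymograph at background mean + `detection_sd` background
#' SDs (background estimated from off-microtubule columns) and groups
#' above-threshold pixels into 4-connected components in (time, position).
#' Event duration is the number of frames spanned times the frame
#' interval; events touching the first or last frame are flagged censored.
#'
#' @param kymo A [kymograph()].
#' @param mt_cols 2-vector of columns covered by the microtubule.
#' @param config A [dwell_config()].
#' @param bg_cols Optional explicit background columns; default: all
#'   columns outside `mt_cols`.
#' @return A `dwell_events` data frame: `start_s`, `duration_s`,
#'   `mean_intensity` (background-subtracted), `censored`, `position_px`.
#' @export
detect_dwell_events <- function(kymo, mt_cols, config = dwell_config(),
                                bg_cols = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$intensity
  if (is.null(bg_cols))
    bg_cols <- setdiff(seq_len(ncol(img)), mt_cols[1]:mt_cols[2])
  if (!length(bg_cols))
    stop("no off-microtubule region to estimate background from",
         call. = FALSE)
  bg <- img[, bg_cols, drop = FALSE]
  bg_mean <- mean(bg); bg_sd <- stats::sd(as.numeric(bg))
  thr <- bg_mean + config$detection_sd * max(bg_sd, 1e-12)

  cols <- mt_cols[1]:mt_cols[2]
  sub <- img[, cols, drop = FALSE]
  mask <- sub > thr
  lab <- label_components(mask)
  n_lab <- max(lab)
  if (n_lab == 0) {
    out <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                      mean_intensity = numeric(0), censored = logical(0),
                      position_px = integer(0))
    class(out) <- c("dwell_events", "data.frame")
    return(out)
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  rows_by <- split(idx[, 1], comp)
  cols_by <- split(idx[, 2], comp)
  vals_by <- split(sub[lab > 0], comp)
  ev <- data.frame(
    start_frame = vapply(rows_by, min, 0),
    end_frame = vapply(rows_by, max, 0),
    position_px = cols[vapply(cols_by, function(v)
      as.integer(round(stats::median(v))), 0L)],
    mean_intensity = vapply(vals_by, mean, 0) - bg_mean)
  ev$duration_frames <- ev$end_frame - ev$start_frame + 1
  ev <- ev[ev$duration_frames >= config$min_event_frames, , drop = FALSE]
  out <- data.frame(
    start_s = (ev$start_frame - 1) * kymo$frame_s,
    duration_s = ev$duration_frames * kymo$frame_s,
    mean_intensity = ev$mean_intensity,
    censored = ev$start_frame == 1 | ev$end_frame == nrow(img),
    position_px = ev$position_px)
  out <- out[order(out$start_s, out$position_px), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dwell_events", "data.frame")
  out
}

# 4-connected component labelling by flood fill (two-pass union-find)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      up <- if (i > 1) lab[i - 1, j] else 0L
      left <- if (j > 1) lab[i, j - 1] else 0L
      if (up == 0L && left == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else if (up != 0L && left != 0L) {
        ru <- find(up); rl <- find(left)
        if (ru != rl) parent[ru] <- rl
        lab[i, j] <- rl
      } else {
        lab[i, j] <- max(up, left)
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, 0L)
  relab <- match(roots, unique(roots))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

#' Short/long residence-time fractions
#'
#' Fractions of uncensored events at or below versus above the short/long
#' boundary (0.32 s by default), recomputed at the robustness thresholds.
#' Events longer than 1 s are included, not truncated.
#'
#' @param events A `dwell_events` data frame.
#' @param config A [dwell_config()].
#' @return A list: `fraction_short`, `fraction_long`, `n_used`
#'   (uncensored events), `n_censored`, and `robustness`, a data frame of
#'   the split at each alternative threshold.
#' @export
dwell_fractions <- function(events, config = dwell_config()) {
  if (!nrow(events)) stop("no events supplied", call. = FALSE)
  use <- events[!events$censored, , drop = FALSE]
  if (!nrow(use))
    stop("all events are censored; fractions are undefined", call. = FALSE)
  split_at <- function(thr) {
    long <- mean(use$duration_s > thr)
    c(fraction_short = 1 - long, fraction_long = long)
  }
  main <- split_at(config$long_threshold_s)
  rob <- t(vapply(config$robustness_thresholds_s, split_at, numeric(2)))
  list(fraction_short = unname(main["fraction_short"]),
       fraction_long = unname(main["fraction_long"]),
       n_used = nrow(use), n_censored = sum(events$censored),
       robustness = data.frame(threshold_s = config$robustness_thresholds_s,
                               fraction_short = rob[, "fraction_short"],
                               fraction_long = rob[, "fraction_long"]))
}

#' Classify event brightnesses into monomers and dimers
#'
#' Two-component Gaussian mixture with the dimer mean constrained to
#' twice the monomer mean (shared SD), fitted by EM; events are labelled
#' by posterior probability. A component with weight < 0.05 collapses the
#' fit to a single class.
#'
#' @param event_intensities Numeric brightness values, n >= 20.
#' @param max_iter,tol EM iteration controls.
#' @return A list: `labels` ("monomer"/"dimer"), `monomer_mean`,
#'   `dimer_mean`, `sd`, `weights`, `collapsed`.
#' @export
classify_stoichiometry <- function(event_intensities, max_iter = 200,
                                   tol = 1e-8) {
  x <- as.numeric(event_intensities)
  if (length(x) < 20)
    stop("need >= 20 events to fit a stoichiometry mixture", call. = FALSE)
  if (stats::sd(x) < 1e-12 * max(abs(mean(x)), 1)) {
    return(list(labels = rep("monomer", length(x)),
                monomer_mean = mean(x), dimer_mean = 2 * mean(x),
                sd = 0, weights = c(monomer = 1, dimer = 0),
                collapsed = TRUE))
  }
  mu <- stats::quantile(x, 0.25, names = FALSE)
  sg <- stats::sd(x) / 2
  w <- 0.5
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w * stats::dnorm(x, mu, sg)
    d2 <- (1 - w) * stats::dnorm(x, 2 * mu, sg)
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    w <- mean(g)
    # means constrained to ratio 2:1: weighted LS for the monomer mean
    mu <- sum(g * x + 2 * (1 - g) * x) / sum(g + 4 * (1 - g))
    sg <- sqrt(sum(g * (x - mu)^2 + (1 - g) * (x - 2 * mu)^2) / length(x))
    sg <- max(sg, 1e-9 * abs(mu))
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  weights <- c(monomer = w, dimer = 1 - w)
  if (min(weights) < 0.05) {
    lab <- if (weights["monomer"] >= weights["dimer"]) "monomer" else "dimer"
    mono <- if (lab == "monomer") mean(x) else mean(x) / 2
    return(list(labels = rep(lab, length(x)), monomer_mean = mono,
                dimer_mean = 2 * mono, sd = stats::sd(x),
                weights = weights, collapsed = TRUE))
  }
  post1 <- w * stats::dnorm(x, mu, sg) /
    (w * stats::dnorm(x, mu, sg) + (1 - w) * stats::dnorm(x, 2 * mu, sg))
  list(labels = ifelse(post1 >= 0.5, "monomer", "dimer"),
       monomer_mean = mu, dimer_mean = 2 * mu, sd = sg,
       weights = weights, collapsed = FALSE)
}

#' Fraction of seeds carrying a fluorescent extension
#'
#' @param seed_intervals List of 2-vectors (start/end pixel of each seed
#'   along the position axis), non-empty.
#' @param extension_mask Logical vector over position pixels marking
#'   fluorescent tubulin.
#' @param min_extension_px Minimal adjacent run length (pixels) that
#'   counts as an extension.
#' @return Fraction of seeds with a qualifying adjacent extension.
#' @export
seed_extension_fraction <- function(seed_intervals, extension_mask,
                                    min_extension_px = 3L) {
  if (!length(seed_intervals))
    stop("empty seed list", call. = FALSE)
  check_scalar(min_extension_px, "min_extension_px", positive = TRUE,
               integerish = TRUE)
  n <- length(extension_mask)
  run_from <- function(start, dir) {
    len <- 0L
    i <- start
    while (i >= 1 && i <= n && isTRUE(extension_mask[i])) {
      len <- len + 1L
      i <- i + dir
    }
    len
  }
  has_ext <- vapply(seed_intervals, function(iv) {
    right <- run_from(iv[2] + 1L, +1L)
    left <- run_from(iv[1] - 1L, -1L)
    max(left, right) >= min_extension_px
  }, TRUE)
  mean(has_ext)
}
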