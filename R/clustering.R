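#' Weighted lateral-overlap score of two bent protofilaments
#'
#' Samples the two flares at matched arclengths — positions with the same
#' arclength coordinate inside the interval where both protofilaments are
#' bent — measures the Euclidean distance between matched points, and
#' scores the pair by the arclength-weighted fraction of matched distances
#' that deviate from the lattice neighbour spacing `d_ref` by less than
#' the tolerance, multiplied by the mutual overlap fraction of the two
#' bent segments:
#' \deqn{\Omega = \frac{\sum_i w_i \, 1[\,|d_i - d_{ref}|/d_{ref} < \delta\,]}
#'   {\sum_i w_i} \times \frac{\mathrm{shared\ bent\ arclength}}
#'   {\mathrm{shorter\ bent\ length}}}
#' The shared bent arclength is the overlap of the two bent segments in
#' global arclength; two flares that never co-exist along the filament
#' score 0. With the default tolerance 0.2 and threshold 0.1, linking two
#' protofilaments requires at least 50% of the weighted distances to
#' deviate by less than 20% over their full mutual overlap.
#'
#' @param seg_a,seg_b [segment_bend()] results for two angular-neighbour
#'   protofilaments; both must be bent.
#' @param d_ref_nm Reference lateral spacing (nm), see [d_ref()].
#' @param config A [cluster_config()].
#' @return An object of class `pair_overlap`: `pf_a`, `pf_b`, `omega`,
#'   `within_fraction`, `mutual_overlap_fraction`, and the matched
#'   distances/deviations/weights.
#' @export
pair_overlap <- function(seg_a, seg_b, d_ref_nm,
                         config = cluster_config()) {
  stopifnot(inherits(seg_a, "bend_segmentation"),
            inherits(seg_b, "bend_segmentation"))
  if (!seg_a$bent || !seg_b$bent)
    stop("pair_overlap requires two bent protofilaments", call. = FALSE)
  check_scalar(d_ref_nm, "d_ref_nm", positive = TRUE)

  la <- seg_a$bent_length_nm; lb <- seg_b$bent_length_nm
  shorter <- min(la, lb)
  lo <- max(seg_a$onset_arclength_nm, seg_b$onset_arclength_nm)
  hi <- min(seg_a$onset_arclength_nm + la, seg_b$onset_arclength_nm + lb)
  shared <- hi - lo
  mof <- max(0, min(shared / shorter, 1))

  empty <- function(mofv) structure(
    list(pf_a = seg_a$pf_id, pf_b = seg_b$pf_id, omega = 0,
         within_fraction = 0, mutual_overlap_fraction = mofv,
         distances_nm = numeric(0), deviations = numeric(0),
         weights = numeric(0)),
    class = "pair_overlap")
  if (mof <= 0 || shorter <= 0) return(empty(max(mof, 0)))

  step <- stats::median(diff(seg_a$arclength))
  s_abs <- seq(lo, hi, by = step)
  if (s_abs[length(s_abs)] < hi) s_abs <- c(s_abs, hi)
  pa <- trace_point_at(seg_a$trace, s_abs)
  pb <- trace_point_at(seg_b$trace, s_abs)
  d <- sqrt(rowSums((pa - pb)^2))
  dev <- abs(d - d_ref_nm) / d_ref_nm

  # local-arclength (trapezoidal) weights, normalised to sum to 1
  w <- diff(s_abs)
  w <- c(w[1] / 2, (w[-1] + w[-length(w)]) / 2, w[length(w)] / 2)
  w <- w / sum(w)

  within <- sum(w * (dev < config$deviation_tolerance))
  structure(list(pf_a = seg_a$pf_id, pf_b = seg_b$pf_id,
                 omega = within * mof, within_fraction = within,
                 mutual_overlap_fraction = mof,
                 distances_nm = d, deviations = dev, weights = w),
            class = "pair_overlap")
}

# interpolate trace points at given arclength values (clamped to range)
trace_point_at <- function(trace, s_values) {
  s <- trace$arclength
  s_values <- pmin(pmax(s_values, s[1]), s[length(s)])
  out <- vapply(seq_len(3L),
                function(j) stats::approx(s, trace$points[, j],
                                          xout = s_values)$y,
                numeric(length(s_values)))
  if (!is.matrix(out)) out <- matrix(out, ncol = 3L)
  out
}

# all angular-neighbour overlap scores of one end (computed once; the
# threshold is applied afterwards, so sweeps reuse these)
compute_pair_overlaps <- function(end, segmentations, lattice,
                                  config = cluster_config()) {
  n_pf <- end$n_pf
  dref <- if (inherits(lattice, "lattice_model")) d_ref(lattice)
          else d_ref(lattice, n_pf = n_pf)
  ids <- vapply(segmentations, `[[`, 0L, "pf_id")
  bent <- vapply(segmentations, `[[`, TRUE, "bent")
  seg_by_id <- stats::setNames(segmentations, ids)
  bent_ids <- ids[bent]
  pairs <- NULL
  for (i in bent_ids) {
    j <- (i %% n_pf) + 1L          # clockwise angular neighbour
    if (j %in% bent_ids && (n_pf > 2L || i < j)) {
      po <- pair_overlap(seg_by_id[[as.character(i)]],
                         seg_by_id[[as.character(j)]], dref, config)
      pairs <- rbind(pairs, data.frame(pf_a = i, pf_b = j,
                                       omega = po$omega))
    }
  }
  pairs %||% data.frame(pf_a = integer(0), pf_b = integer(0),
                        omega = numeric(0))
}

#' Threshold adjacency graph of bent protofilaments
#'
#' Nodes are the bent protofilaments of one end; an edge joins two
#' angular neighbours whose overlap score reaches the threshold
#' (ties count as edges).
#'
#' @param end An [mt_end()].
#' @param segmentations List of [segment_bend()] results for the end.
#' @param lattice A [lattice_model()], or the fitted `axis_model` (its
#'   radius then defines `d_ref` together with the end's protofilament
#'   count).
#' @param theta Overlap threshold in (0, 1].
#' @param config A [cluster_config()].
#' @return An object of class `pf_adjacency`: `nodes` (bent pf ids),
#'   `edges` (2-column matrix), `pair_scores` (all neighbour scores),
#'   `theta`, `end_id`.
#' @export
adjacency_graph <- function(end, segmentations, lattice,
                            theta = cluster_config()$overlap_threshold,
                            config = cluster_config()) {
  stopifnot(inherits(end, "mt_end"))
  scores <- compute_pair_overlaps(end, segmentations, lattice, config)
  bent <- vapply(segmentations, `[[`, TRUE, "bent")
  nodes <- vapply(segmentations, `[[`, 0L, "pf_id")[bent]
  keep <- scores$omega >= theta
  structure(list(nodes = sort(nodes),
                 edges = as.matrix(scores[keep, c("pf_a", "pf_b"),
                                          drop = FALSE]),
                 pair_scores = scores, theta = theta,
                 end_id = end$end_id),
            class = "pf_adjacency")
}

#' Connected-component clusters of laterally associated protofilaments
#'
#' @param graph A `pf_adjacency` from [adjacency_graph()], or any list
#'   with `nodes` and a 2-column `edges` matrix.
#' @return An object of class `cluster_assignment`: `end_id`, `clusters`
#'   (list of sorted integer vectors; bent protofilaments without edges
#'   are singleton clusters), and `sizes`.
#' @export
connected_clusters <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(edges) && nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(match(edges[e, 1], nodes))
      b <- find(match(edges[e, 2], nodes))
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  comp <- split(nodes, roots)
  comp <- lapply(comp, function(v) sort(as.integer(v)))
  comp <- comp[order(vapply(comp, min, 0L))]
  structure(list(end_id = graph$end_id %||% NA_character_,
                 clusters = unname(comp),
                 sizes = vapply(comp, length, 0L)),
            class = "cluster_assignment")
}

#' Cluster-size distribution per condition
#'
#' Pools protofilament-level counts over the ends of each condition into
#' the size categories singleton, pair, and large (>= 3 protofilaments).
#'
#' @param assignments List of [connected_clusters()] results.
#' @param condition_labels Named character vector mapping `end_id` to a
#'   condition; every assignment's end must be present.
#' @return A data frame with one row per condition and category:
#'   `condition`, `category` ("1", "2", ">=3"), `count`, `fraction`
#'   (normalised within condition).
#' @export
cluster_distribution <- function(assignments, condition_labels) {
  if (!length(assignments))
    stop("no cluster assignments supplied", call. = FALSE)
  rows <- lapply(assignments, function(a) {
    lab <- unname(condition_labels[a$end_id])
    if (length(lab) != 1L || is.na(lab))
      stop("unknown condition label for end ", a$end_id, call. = FALSE)
    if (!length(a$sizes)) return(NULL)
    data.frame(condition = lab,
               category = cut(a$sizes, c(0, 1, 2, Inf),
                              labels = c("1", "2", ">=3")),
               n_pf = a$sizes)
  })
  tab <- do.call(rbind, rows)
  out <- expand.grid(condition = unique(tab$condition),
                     category = c("1", "2", ">=3"),
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(cond, cat)
    sum(tab$n_pf[tab$condition == cond & tab$category == cat]),
    out$condition, out$category)
  totals <- tapply(out$count, out$condition, sum)
  out$fraction <- out$count / as.numeric(totals[out$condition])
  out[order(out$condition, out$category), ]
}

#' Cluster distributions and comparisons across overlap thresholds
#'
#' Recomputes the clustering at every threshold of the sweep, reports the
#' per-condition category distribution and the clustered-protofilament
#' fraction (non-increasing in the threshold), and compares conditions by
#' a chi-squared test on the pooled category counts.
#'
#' @param ends List of [mt_end()] objects.
#' @param segmentations List (parallel to `ends`) of per-end segmentation
#'   lists.
#' @param lattice A [lattice_model()] or per-end list of fitted axes.
#' @param config A [cluster_config()]; `sweep_thresholds` defines the
#'   sweep.
#' @param condition_labels Named character vector mapping `end_id` to
#'   condition.
#' @return A list with `distributions` (data frame over thresholds,
#'   conditions and categories, with `clustered_fraction`) and `tests`
#'   (data frame of chi-squared results per threshold; NA when fewer than
#'   two conditions are present).
#' @export
threshold_sweep <- function(ends, segmentations, lattice,
                            config = cluster_config(), condition_labels) {
  stopifnot(length(ends) == length(segmentations))
  scores <- lapply(seq_along(ends), function(i) {
    lat <- if (inherits(lattice, "lattice_model")) lattice else lattice[[i]]
    list(end = ends[[i]],
         scores = compute_pair_overlaps(ends[[i]], segmentations[[i]], lat,
                                        config),
         nodes = {
           bent <- vapply(segmentations[[i]], `[[`, TRUE, "bent")
           vapply(segmentations[[i]], `[[`, 0L, "pf_id")[bent]
         })
  })
  dist_rows <- NULL
  test_rows <- NULL
  for (theta in config$sweep_thresholds) {
    assigns <- lapply(scores, function(sc) {
      keep <- sc$scores$omega >= theta
      connected_clusters(list(
        nodes = sort(sc$nodes),
        edges = as.matrix(sc$scores[keep, c("pf_a", "pf_b"), drop = FALSE]),
        end_id = sc$end$end_id))
    })
    nonempty <- vapply(assigns, function(a) length(a$sizes) > 0, TRUE)
    if (!any(nonempty)) next
    dist <- cluster_distribution(assigns[nonempty], condition_labels)
    clustered <- tapply(dist$count * (dist$category != "1"), dist$condition,
                        sum) / tapply(dist$count, dist$condition, sum)
    dist$clustered_fraction <- as.numeric(clustered[dist$condition])
    dist$theta <- theta
    dist_rows <- rbind(dist_rows, dist)

    conds <- unique(dist$condition)
    if (length(conds) >= 2) {
      tab <- t(vapply(conds, function(cc)
        dist$count[dist$condition == cc], numeric(3)))
      colnames(tab) <- c("1", "2", ">=3")
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      test <- chi_squared_table(tab)
      test_rows <- rbind(test_rows,
                         data.frame(theta = theta,
                                    statistic = test$statistic,
                                    df = test$df, p = test$p))
    }
  }
  list(distributions = dist_rows, tests = test_rows)
}
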