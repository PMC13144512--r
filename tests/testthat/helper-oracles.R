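# independent oracles and small constructors used across the test files

# brute-force connected components by depth-first search
dfs_components <- function(nodes, edges) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)),
                                as.character(nodes)), identity)
  if (!is.null(edges) && nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- as.character(edges[e, 1]); b <- as.character(edges[e, 2])
      adj[[a]] <- c(adj[[a]], edges[e, 2])
      adj[[b]] <- c(adj[[b]], edges[e, 1])
    }
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), as.character(nodes))
  comps <- list()
  for (v in nodes) {
    if (seen[as.character(v)]) next
    stack <- v
    comp <- integer(0)
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[as.character(u)]) next
      seen[as.character(u)] <- TRUE
      comp <- c(comp, u)
      stack <- c(stack, adj[[as.character(u)]])
    }
    comps[[length(comps) + 1L]] <- sort(as.integer(comp))
  }
  comps[order(vapply(comps, min, 0L))]
}

partition_key <- function(clusters)
  unname(sort(vapply(clusters, function(v) paste(sort(v), collapse = ","), "")))

same_partition <- function(a, b) identical(partition_key(a), partition_key(b))

# random undirected graph on n labelled nodes
random_graph <- function(n, p_edge) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  list(nodes = seq_len(n), edges = pairs[keep, , drop = FALSE])
}

# straight-line bend segmentation at given x-offset, for overlap tests:
# the "flare" runs along z from (x0, 0, 0), bent from `onset` onward
line_seg <- function(pf_id, x0, total_len, onset, step = 1) {
  z <- seq(0, total_len, by = step)
  if (z[length(z)] < total_len) z <- c(z, total_len)
  tr <- mtflare::pf_trace("toy", pf_id, cbind(x0, 0, z))
  structure(list(pf_id = pf_id, bent = TRUE,
                 onset_arclength_nm = onset,
                 bent_length_nm = total_len - onset,
                 onset_z_nm = onset, terminus_z_nm = total_len,
                 arclength = tr$arclength, radial_excess = NULL,
                 trace = tr),
            class = "bend_segmentation")
}

# direct-summation overlap score, independent of pair_overlap()'s code path
brute_omega <- function(seg_a, seg_b, dref, delta = 0.2, step = 1) {
  la <- seg_a$bent_length_nm; lb <- seg_b$bent_length_nm
  lo <- max(seg_a$onset_arclength_nm, seg_b$onset_arclength_nm)
  hi <- min(seg_a$onset_arclength_nm + la, seg_b$onset_arclength_nm + lb)
  if (hi <= lo) return(0)
  s <- seq(lo, hi, by = step)
  if (s[length(s)] < hi) s <- c(s, hi)
  interp <- function(tr, sv) {
    sapply(1:3, function(j)
      stats::approx(tr$arclength, tr$points[, j], xout = sv)$y)
  }
  pa <- interp(seg_a$trace, s); pb <- interp(seg_b$trace, s)
  d <- sqrt(rowSums((pa - pb)^2))
  w <- diff(s)
  w <- c(w[1] / 2, (w[-1] + w[-length(w)]) / 2, w[length(w)] / 2)
  w <- w / sum(w)
  within <- sum(w * (abs(d - dref) / dref < delta))
  within * min((hi - lo) / min(la, lb), 1)
}

# full geometry pipeline for one generated end: fitted axis, segmentations,
# estimated partition at the given threshold
analyze_end <- function(gen, theta = 0.1, lattice = mtflare::lattice_model()) {
  ax <- mtflare::fit_axis(gen$end)
  segs <- lapply(gen$end$traces, mtflare::segment_bend, axis = ax)
  graph <- mtflare::adjacency_graph(gen$end, segs, lattice, theta)
  list(axis = ax, segs = segs, graph = graph,
       assignment = mtflare::connected_clusters(graph))
}

# brute-force two-sample KS statistic by scanning both ECDFs
brute_ks_D <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  Fa <- vapply(xs, function(x) mean(a <= x), 0)
  Fb <- vapply(xs, function(x) mean(b <= x), 0)
  max(abs(Fa - Fb))
}
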