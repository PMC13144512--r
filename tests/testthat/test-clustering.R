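dref_toy <- 5

test_that("overlap score hits its anchor values on constructed pairs", {
  # parallel co-bent lines at exactly d_ref, identical onsets: full overlap
  a <- line_seg(1L, 0, 60, 10)
  b <- line_seg(2L, dref_toy, 60, 10)
  expect_equal(pair_overlap(a, b, dref_toy)$omega, 1.0)

  # constant distance 1.5 * d_ref: every deviation is 50% > 20%
  c2 <- line_seg(2L, 1.5 * dref_toy, 60, 10)
  expect_equal(pair_overlap(a, c2, dref_toy)$omega, 0.0)

  # same geometry, onsets offset so the shared bent interval is half the
  # shorter bent length: omega = 1 x 0.5
  d2 <- line_seg(2L, dref_toy, 85, 35)   # bent 35..85, a bent 10..60
  po <- pair_overlap(a, d2, dref_toy)
  expect_equal(po$mutual_overlap_fraction, 0.5)
  expect_equal(po$omega, 0.5)

  # no mutual bent overlap at all
  e2 <- line_seg(2L, dref_toy, 200, 150)
  expect_equal(pair_overlap(a, e2, dref_toy)$omega, 0)

  # unbent input is the caller's mistake
  ub <- a; ub$bent <- FALSE
  expect_error(pair_overlap(ub, b, dref_toy), "bent")
})

test_that("overlap score equals direct summation and is symmetric", {
  set.seed(21)
  for (i in 1:20) {
    on_a <- runif(1, 5, 40); on_b <- runif(1, 5, 40)
    len_a <- on_a + runif(1, 10, 60); len_b <- on_b + runif(1, 10, 60)
    # jittered near-d_ref pair so deviations straddle the tolerance
    za <- seq(0, len_a, by = 1); zb <- seq(0, len_b, by = 1)
    a <- line_seg(1L, 0, len_a, on_a)
    b <- line_seg(2L, dref_toy, len_b, on_b)
    b$trace$points[, 1] <- dref_toy + runif(nrow(b$trace$points), -2, 2)
    ab <- pair_overlap(a, b, dref_toy)
    ba <- pair_overlap(b, a, dref_toy)
    expect_equal(ab$omega, ba$omega, tolerance = 1e-12)
    expect_equal(ab$omega, brute_omega(a, b, dref_toy), tolerance = 1e-9)
    expect_gte(ab$omega, 0); expect_lte(ab$omega, 1)
  }
})

test_that("adjacency edges appear exactly inside generated sheets and shrink with theta", {
  g <- generate_end(end_gen_params(cluster_spec = 3, unbent_fraction = 1,
                                   point_noise_sd_nm = 0, seed = 31))
  res <- analyze_end(g, theta = 0.1)
  sheet <- sort(g$truth$partition[[which.max(lengths(g$truth$partition))]])
  in_sheet <- apply(res$graph$edges, 1, function(e) all(e %in% sheet))
  expect_true(all(in_sheet))
  expect_equal(nrow(res$graph$edges), length(sheet) - 1)

  # theta above 1 can keep no edge
  g2 <- adjacency_graph(g$end, res$segs, lattice_model(), 1.01)
  expect_equal(nrow(g2$edges), 0)

  # monotone thresholding on the same scores
  thetas <- c(0.03, 0.1, 0.3, 0.5)
  edge_counts <- vapply(thetas, function(th)
    nrow(adjacency_graph(g$end, res$segs, lattice_model(), th)$edges), 0)
  expect_true(all(diff(edge_counts) <= 0))
})

test_that("connected components match a depth-first-search oracle", {
  # exhaustive on up to 5 nodes
  for (n in 2:5) {
    pairs <- t(utils::combn(n, 2))
    for (mask in 0:(2^nrow(pairs) - 1)) {
      edges <- pairs[bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0, ,
                     drop = FALSE]
      mine <- connected_clusters(list(nodes = 1:n, edges = edges))
      expect_true(same_partition(mine$clusters, dfs_components(1:n, edges)))
    }
  }
  # randomised on up to 13 nodes
  set.seed(77)
  for (i in 1:300) {
    n <- sample(2:13, 1)
    gr <- random_graph(n, runif(1, 0.05, 0.5))
    mine <- connected_clusters(gr)
    expect_true(same_partition(mine$clusters, dfs_components(gr$nodes, gr$edges)))
  }
})

test_that("connected components agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (i in 1:50) {
    n <- sample(3:13, 1)
    gr <- random_graph(n, 0.25)
    mine <- connected_clusters(gr)
    ig <- igraph::graph_from_edgelist(gr$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    memb <- igraph::components(ig)$membership
    ref <- split(seq_len(n), memb)
    expect_true(same_partition(mine$clusters, ref))
  }
})

test_that("cluster distributions count protofilaments per category and condition", {
  asg <- function(id, sizes) {
    nodes <- seq_len(sum(sizes))
    cl <- split(nodes, rep(seq_along(sizes), sizes))
    structure(list(end_id = id, clusters = unname(cl),
                   sizes = lengths(cl)), class = "cluster_assignment")
  }
  labels <- c(a = "ctrl", b = "ctrl", c = "treated")
  dist <- cluster_distribution(
    list(asg("a", c(3, 2, rep(1, 8))), asg("b", rep(1, 13)),
         asg("c", c(4, 4))), labels)
  ctrl <- dist[dist$condition == "ctrl", ]
  expect_equal(ctrl$count[ctrl$category == "1"], 21)
  expect_equal(ctrl$count[ctrl$category == "2"], 2)
  expect_equal(ctrl$count[ctrl$category == ">=3"], 3)
  expect_equal(sum(ctrl$fraction), 1, tolerance = 1e-12)
  tr <- dist[dist$condition == "treated", ]
  expect_equal(tr$count[tr$category == ">=3"], 8)
  expect_error(cluster_distribution(list(asg("zz", 2)), labels), "zz")
})

test_that("threshold sweeps keep clustered fractions monotone and compare conditions", {
  gens <- lapply(1:8, function(i)
    generate_end(end_gen_params(
      cluster_spec = if (i %% 2) 3 else integer(0),
      unbent_fraction = 0.4, point_noise_sd_nm = 0.5, seed = 600 + i),
      end_id = sprintf("e%d", i),
      condition = if (i %% 2) "sheeted" else "plain"))
  ends <- lapply(gens, `[[`, "end")
  segs <- lapply(gens, function(g) {
    ax <- fit_axis(g$end)
    lapply(g$end$traces, segment_bend, axis = ax)
  })
  labels <- vapply(ends, `[[`, "", "end_id")
  labels <- stats::setNames(vapply(ends, `[[`, "", "condition"), labels)
  sw <- threshold_sweep(ends, segs, lattice_model(),
                        cluster_config(), labels)
  for (cond in unique(sw$distributions$condition)) {
    cf <- unique(sw$distributions[sw$distributions$condition == cond,
                                  c("theta", "clustered_fraction")])
    cf <- cf[order(cf$theta), ]
    expect_true(all(diff(cf$clustered_fraction) <= 1e-12))
  }
  expect_true(all(sw$tests$p >= 0 & sw$tests$p <= 1))
})
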