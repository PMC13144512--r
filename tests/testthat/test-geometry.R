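test_that("resampling preserves endpoints and arclength", {
  z <- seq(0, 10, by = 2.5)
  tr <- pf_trace("e", 1L, cbind(0, 0, z))
  rs <- resample_trace(tr, 1)
  expect_equal(nrow(rs$points), 11)
  expect_equal(rs$points[1, ], c(0, 0, 0))
  expect_equal(rs$points[11, ], c(0, 0, 10))
  # a step larger than the trace keeps only the endpoints
  rs2 <- resample_trace(tr, 50)
  expect_equal(nrow(rs2$points), 2)
  # arclength conserved within one step on random smooth curves
  set.seed(1)
  for (i in 1:5) {
    t <- seq(0, 2 * pi, length.out = 100)
    pts <- cbind(cos(t) * 10, sin(t) * 10, t * 3)
    trc <- pf_trace("e", 1L, pts)
    total <- trc$arclength[length(trc$arclength)]
    rs <- resample_trace(trc, 0.5)
    expect_lt(abs(rs$arclength[length(rs$arclength)] - total), 0.5)
  }
})

test_that("axis fit recovers the generator cylinder and is equivariant", {
  g <- generate_end(end_gen_params(cluster_spec = 3, point_noise_sd_nm = 0,
                                   seed = 5))
  ax <- fit_axis(g$end)
  expect_lt(acos(min(1, abs(ax$direction[3]))) * 180 / pi, 0.1)
  expect_lt(abs(ax$radius_nm - 11), 0.05)
  expect_gt(ax$direction[3], 0)          # oriented toward the plus end

  # rigid motion: rotate + translate, the fitted axis must follow
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(0.4), -sin(0.4), 0, sin(0.4), cos(0.4)), 3, 3)
  M <- R2 %*% R
  shift <- c(100, -50, 20)
  moved <- g$end
  moved$traces <- lapply(moved$traces, function(tr) {
    tr$points <- t(M %*% t(tr$points)) + rep(shift, each = nrow(tr$points))
    tr
  })
  ax2 <- fit_axis(moved)
  expect_lt(abs(abs(sum(ax2$direction * (M %*% ax$direction))) - 1), 1e-6)
  expect_lt(abs(ax2$radius_nm - ax$radius_nm), 1e-3)

  few <- mt_end("few", g$end$traces[1:2])
  expect_error(fit_axis(few), ">= 3")
})

test_that("bend segmentation matches generator onsets and never hallucinates", {
  # noiseless straight end: no bends at all
  g0 <- generate_end(end_gen_params(unbent_fraction = 1, point_noise_sd_nm = 0,
                                    seed = 1))
  ax0 <- fit_axis(g0$end)
  segs0 <- lapply(g0$end$traces, segment_bend, axis = ax0)
  expect_false(any(vapply(segs0, `[[`, TRUE, "bent")))
  expect_true(all(vapply(segs0, `[[`, 0, "bent_length_nm") == 0))

  # noiseless flared end: onset within one resample step of the truth
  g <- generate_end(end_gen_params(unbent_fraction = 0, point_noise_sd_nm = 0,
                                   taper_sd_nm = 10, seed = 4))
  ax <- fit_axis(g$end)
  segs <- lapply(g$end$traces, segment_bend, axis = ax)
  est <- vapply(segs, `[[`, 0, "onset_arclength_nm")
  expect_lt(max(abs(est - g$truth$per_pf$onset_arclength_nm)), 1)
  # bent length bookkeeping
  for (s in segs)
    expect_equal(s$bent_length_nm,
                 s$arclength[length(s$arclength)] - s$onset_arclength_nm)

  # trace lying entirely off the cylinder: onset at the first sample
  far <- pf_trace("e", 1L, cbind(20, 0, seq(0, 50, by = 1)))
  seg_far <- segment_bend(far, ax0)
  expect_true(seg_far$bent)
  expect_lt(seg_far$onset_arclength_nm, 1)
})

test_that("end summaries count, conserve, and measure raggedness as a population SD", {
  g <- generate_end(end_gen_params(seed = 12, cluster_spec = 2))
  ax <- fit_axis(g$end)
  segs <- lapply(g$end$traces, segment_bend, axis = ax)
  summ <- end_summary(g$end, segs)
  n_bent <- sum(vapply(segs, `[[`, TRUE, "bent"))
  expect_equal(summ$fraction_unbent * summ$n_pf + n_bent, summ$n_pf)
  expect_length(summ$bent_lengths_nm, n_bent)
  expect_gte(summ$raggedness_nm, 0)
  expect_error(end_summary(g$end, list()), "empty")

  # arithmetic anchor: onset heights {0, 0, 8.2, 8.2} give SD 4.1
  mk <- function(id, z) {
    structure(list(pf_id = id, bent = TRUE, onset_arclength_nm = z,
                   bent_length_nm = 10, onset_z_nm = z,
                   terminus_z_nm = z + 10,
                   arclength = seq(0, z + 10), radial_excess = NULL,
                   trace = NULL), class = "bend_segmentation")
  }
  four <- list(mk(1L, 0), mk(2L, 0), mk(3L, 8.2), mk(4L, 8.2))
  toy_end <- mt_end("toy", g$end$traces[1:4])
  expect_equal(end_summary(toy_end, four)$raggedness_nm, 4.1)

  # all unbent with identical terminus: fraction_unbent 1, raggedness 0
  g1 <- generate_end(end_gen_params(unbent_fraction = 1, taper_sd_nm = 0,
                                    point_noise_sd_nm = 0, seed = 2))
  ax1 <- fit_axis(g1$end)
  segs1 <- lapply(g1$end$traces, segment_bend, axis = ax1)
  s1 <- end_summary(g1$end, segs1)
  expect_equal(s1$fraction_unbent, 1)
  expect_lt(s1$raggedness_nm, 1e-6)
})

test_that("mean estimated raggedness matches the analytic expectation of a population SD", {
  # taper SD 20 nm; for n = 13 normal draws the population SD has
  # expectation sigma * sqrt(2/n) * gamma(n/2) / gamma((n-1)/2)
  n <- 13
  expected <- 20 * sqrt(2 / n) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
  est <- vapply(1:60, function(i) {
    g <- generate_end(end_gen_params(unbent_fraction = 0, taper_sd_nm = 20,
                                     point_noise_sd_nm = 0.3,
                                     seed = 4000 + i))
    ax <- fit_axis(g$end)
    segs <- lapply(g$end$traces, segment_bend, axis = ax)
    end_summary(g$end, segs)$raggedness_nm
  }, 0)
  expect_lt(abs(mean(est) - expected) / expected, 0.05)
})

test_that("lattice spacing is recovered from periodic profiles and flagged on noise", {
  # pure cosine at 4.1 nm
  x <- seq(0, 4.1 * 20, by = 0.2)
  prof <- list(intensity = cos(2 * pi * x / 4.1), step_nm = 0.2)
  est <- estimate_lattice_spacing(prof)
  expect_true(est$resolved)
  expect_lt(abs(est$spacing_nm - 4.1), 0.01)

  # scale equivariance: stretch coordinates (and window) by s
  s <- 1.05
  prof_s <- list(intensity = prof$intensity, step_nm = 0.2 * s)
  est_s <- estimate_lattice_spacing(prof_s, window_nm = c(3.5, 5.0) * s)
  expect_equal(est_s$spacing_nm, est$spacing_nm * s, tolerance = 1e-6)

  # white noise: unresolved
  set.seed(3)
  wn <- list(intensity = rnorm(600), step_nm = 0.25)
  expect_false(estimate_lattice_spacing(wn)$resolved)

  # too-short profile errors
  short <- list(intensity = cos(seq(0, 10, by = 0.2)), step_nm = 0.2)
  expect_error(estimate_lattice_spacing(short), "8")
})

test_that("seed filtering applies the length x spacing rule", {
  mk <- function(len, sp) structure(
    list(end_id = "x", length_um = len, lattice_spacing_nm = sp),
    class = "end_shape_summary")
  expect_equal(filter_seed_like(mk(1.0, 4.20))$decision, "exclude")
  expect_equal(filter_seed_like(mk(6.0, 4.20))$decision, "keep")
  expect_equal(filter_seed_like(mk(1.0, 4.10))$decision, "keep")
  expect_warning(res <- filter_seed_like(mk(1.0, NA)), "ambiguous")
  expect_equal(res$decision, "keep")
  expect_true(res$ambiguous)
})

test_that("decoration thickness is recovered and classified against the dimer size", {
  for (case in list(c(0, 1), c(18, 1), c(30, 0))) {
    pr <- generate_radial_profile(decoration_thickness_nm = case[1], seed = 7)
    dt <- decoration_thickness(pr)
    expect_lt(abs(dt$thickness_nm - case[1]), 1)
    expect_identical(dt$layer_class,
                     if (case[2] == 1) "within_single_dimer" else "multi_layer")
  }
  flat <- generate_radial_profile(decoration_thickness_nm = 0, seed = 1)
  flat$intensity[] <- rnorm(length(flat$intensity), 0, 0.01)
  expect_error(decoration_thickness(flat), "wall")
})

test_that("train lengths convert to copy numbers by fencepost counting", {
  expect_identical(train_copy_number(0), 1L)
  expect_identical(train_copy_number(41.0), 11L)
  expect_identical(train_copy_number(65.6), 17L)
  expect_error(train_copy_number(-1), "train_length_nm")
})

test_that("oligomer position uses the 50 nm contact rule inclusively", {
  expect_identical(classify_oligomer_position(50, 80), "at_end")   # gap 30
  expect_identical(classify_oligomer_position(20, 80), "distal")   # gap 60
  expect_identical(classify_oligomer_position(30, 80), "at_end")   # gap 50
})
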