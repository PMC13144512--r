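test_that("generators are deterministic and validate their parameters", {
  p <- end_gen_params(cluster_spec = 3, seed = 11)
  g1 <- generate_end(p); g2 <- generate_end(p)
  expect_identical(g1, g2)

  k <- kymo_gen_params(noise_sd = 1, seed = 4)
  expect_identical(generate_kymograph(k), generate_kymograph(k))

  d <- dwell_gen_params(n_events = 200, seed = 5)
  expect_identical(generate_dwell_dataset(d), generate_dwell_dataset(d))

  expect_identical(generate_intensity_profile(4.1, 10, 0.3, seed = 2),
                   generate_intensity_profile(4.1, 10, 0.3, seed = 2))
  expect_identical(generate_radial_profile(decoration_thickness_nm = 5, seed = 3),
                   generate_radial_profile(decoration_thickness_nm = 5, seed = 3))

  expect_error(end_gen_params(seed = 1, unbent_fraction = 1.4), "unbent_fraction")
  expect_error(end_gen_params(seed = 1, cluster_spec = c(7, 7)), "cluster_spec")
  expect_error(end_gen_params(seed = 1, sample_step_nm = 0), "sample_step_nm")
  expect_error(end_gen_params(cluster_spec = 3), "seed")
  expect_error(kymo_gen_params(envelope_level = 5, lattice_level = 20, seed = 1),
               "envelope_level")
  expect_error(dwell_gen_params(mixture = data.frame(weight = 1, mean_dwell_s = -1),
                                seed = 1), "mixture")
  expect_error(generate_intensity_profile(4.1, 5, seed = 1), "n_repeats")
  expect_error(generate_radial_profile(decoration_thickness_nm = -2, seed = 1),
               "decoration_thickness_nm")
})

test_that("an all-unbent noiseless end lies exactly on the lattice cylinder", {
  g <- generate_end(end_gen_params(unbent_fraction = 1, point_noise_sd_nm = 0,
                                   taper_sd_nm = 0, seed = 1))
  for (tr in g$end$traces) {
    r <- sqrt(tr$points[, 1]^2 + tr$points[, 2]^2)
    expect_lt(max(abs(r - 11)), 1e-9)
  }
  expect_false(any(g$truth$per_pf$bent))
  expect_length(g$truth$partition, 0)
})

test_that("clustered flares stay exactly d_ref apart at matched arclengths", {
  g <- generate_end(end_gen_params(cluster_spec = 3, unbent_fraction = 1,
                                   point_noise_sd_nm = 0, seed = 2))
  members <- g$truth$partition[[1]]
  expect_length(members, 3)
  dref <- d_ref(lattice_model())
  for (k in 1:2) {
    t1 <- g$end$traces[[members[k]]]; t2 <- g$end$traces[[members[k + 1]]]
    n <- min(nrow(t1$points), nrow(t2$points))
    d <- sqrt(rowSums((t1$points[1:n, ] - t2$points[1:n, ])^2))
    expect_lt(max(abs(d - dref)), 1e-9)
  }
})

test_that("ground truth is consistent with the emitted geometry at zero noise", {
  g <- generate_end(end_gen_params(unbent_fraction = 0.3, cluster_spec = 2,
                                   point_noise_sd_nm = 0, seed = 9))
  tt <- g$truth$per_pf
  for (i in seq_len(nrow(tt))) {
    tr <- g$end$traces[[i]]
    total <- tr$arclength[length(tr$arclength)]
    if (tt$bent[i]) {
      # polyline chords slightly undercut the true arc; well under one step
      expect_lt(abs(total - (tt$onset_arclength_nm[i] + tt$flare_length_nm[i])),
                0.05)
    } else {
      expect_lt(abs(total - tt$terminus_z_nm[i]), 1e-9)
    }
  }
  # the partition covers exactly the bent protofilaments
  expect_setequal(unlist(g$truth$partition), which(tt$bent))
})

test_that("generated flare lengths follow the requested distribution", {
  p <- end_gen_params(unbent_fraction = 0, taper_sd_nm = 0,
                      flare_length_mean_nm = 40, flare_length_sd_nm = 15,
                      point_noise_sd_nm = 0, seed = 33)
  lens <- unlist(lapply(1:80, function(i) {
    pi <- p; pi$seed <- 1000 + i
    generate_end(pi)$truth$per_pf$flare_length_nm
  }))
  lens <- lens[!is.na(lens)]
  expect_gte(length(lens), 1000)
  sdlog <- sqrt(log1p((15 / 40)^2))
  meanlog <- log(40) - sdlog^2 / 2
  ks <- suppressWarnings(stats::ks.test(lens, "plnorm", meanlog, sdlog))
  expect_gt(ks$p.value, 0.01)
})

test_that("noiseless kymographs have exactly the constructed levels", {
  g <- generate_kymograph(kymo_gen_params(noise_sd = 0, seed = 1))
  vals <- sort(unique(as.numeric(g$kymo$intensity)))
  expect_identical(vals, c(10, 20, 30))
  img <- g$kymo$intensity
  expect_true(all(img[, 1:19] == 10))
  expect_true(all(img[, 20:109] == 20))
  expect_true(all(img[, 110:160] == 30))
})

test_that("generated FRAP region recovers to the constructed plateau", {
  fr <- list(bleach_frame = 40, bleach_cols = c(120, 150),
             recovery_fraction = 0.6, recovery_rate_per_s = 0.2)
  g <- generate_kymograph(kymo_gen_params(n_rows = 400, noise_sd = 0,
                                          frame_s = 0.5, frap = fr, seed = 2))
  img <- g$kymo$intensity
  pre <- mean(img[1:40, 120:150])
  post <- mean(img[41, 120:150])
  plateau <- mean(img[380:400, 120:150])
  expect_equal(post, 10)                      # bleached to background
  expect_equal((plateau - post) / (pre - post), 0.6, tolerance = 0.01)
})

test_that("dwell durations follow the discretised exponential with sub-frame drop", {
  p <- dwell_gen_params(n_events = 10000,
                        mixture = data.frame(weight = 1, mean_dwell_s = 0.1),
                        frame_s = 0.04, movie_len_s = 5000, seed = 7)
  g <- generate_dwell_dataset(p)
  ev <- g$events
  expect_true(all(ev$duration_s >= 0.04))
  expect_lt(max(abs(ev$duration_s / 0.04 - round(ev$duration_s / 0.04))), 1e-9)
  # analytic mean of ceil(T/delta)*delta given T >= delta, T ~ Exp(0.1)
  x <- 0.04 / 0.1
  q <- exp(-x)
  k <- 2:2000                  # k = 1 events (T < delta) are dropped
  e_frames <- sum(k * (q^(k - 1) - q^k)) / q
  expected_mean <- e_frames * 0.04
  se <- stats::sd(ev$duration_s) / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$duration_s) - expected_mean), 3 * se + 1e-12)
  expect_equal(g$truth$n_dropped + nrow(ev), 10000)
})

test_that("dwell intensities respect the stoichiometry classes", {
  p0 <- dwell_gen_params(n_events = 500, dimer_fraction = 0,
                         intensity_cv = 0, seed = 3)
  g0 <- generate_dwell_dataset(p0)
  expect_true(all(g0$events$mean_intensity == 1))
  p1 <- dwell_gen_params(n_events = 500, dimer_fraction = 1,
                         intensity_cv = 0, seed = 3)
  g1 <- generate_dwell_dataset(p1)
  expect_true(all(g1$events$mean_intensity == 2))
})

test_that("radial profiles place the decoration shell where stated", {
  pr0 <- generate_radial_profile(decoration_thickness_nm = 0, noise_sd = 0,
                                 seed = 1)
  outside <- pr0$radius_nm > pr0$mt_radius_nm + pr0$wall_half_width_nm
  expect_true(all(pr0$intensity[outside] == 0))
  pr <- generate_radial_profile(decoration_thickness_nm = 18, noise_sd = 0,
                                seed = 1)
  shell_edge <- max(pr$radius_nm[pr$intensity > 0])
  expect_equal(shell_edge, pr$mt_radius_nm + pr$wall_half_width_nm + 18)
})
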