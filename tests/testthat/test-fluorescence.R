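test_that("envelope boundaries are found exactly on clean steps and not on flat profiles", {
  g <- generate_kymograph(kymo_gen_params(noise_sd = 0, seed = 1))
  b <- detect_envelope_boundary(g$kymo, g$truth$mt_cols)
  expect_identical(b$boundary_col, 110L)
  flat <- generate_kymograph(kymo_gen_params(noise_sd = 0, boundary_col = NA,
                                             seed = 1))
  expect_true(is.na(detect_envelope_boundary(flat$kymo, flat$truth$mt_cols)$boundary_col))
  expect_error(detect_envelope_boundary(g$kymo, g$truth$mt_cols,
                                        time_window = c(50, 10)), "window")
})

test_that("envelope ratios follow the background-corrected formula", {
  g <- generate_kymograph(kymo_gen_params(noise_sd = 0, seed = 1))
  rois <- list(envelope = list(rows = c(1, 200), cols = c(115, 155)),
               lattice = list(rows = c(1, 200), cols = c(25, 105)),
               bg = list(rows = c(1, 200), cols = c(165, 200)))
  er <- envelope_ratio(g$kymo, rois$envelope, rois$lattice, rois$bg)
  expect_equal(er$ratio, 2.0)               # (30 - 10) / (20 - 10)
  # I_envelope = I_lattice gives 1
  er1 <- envelope_ratio(g$kymo, list(rows = c(1, 200), cols = c(30, 60)),
                        list(rows = c(1, 200), cols = c(65, 105)), rois$bg)
  expect_equal(er1$ratio, 1.0)
  # lattice at background level is undefined
  expect_error(envelope_ratio(g$kymo, rois$envelope,
                              list(rows = c(1, 200), cols = c(166, 180)),
                              list(rows = c(1, 200), cols = c(181, 200))),
               "undefined")
  # overlapping boxes are rejected
  expect_error(envelope_ratio(g$kymo, rois$envelope,
                              list(rows = c(1, 200), cols = c(100, 120)),
                              rois$bg), "disjoint")
})

test_that("FRAP fitting recovers constructed recovery fractions", {
  mk_trace <- function(frac, rate, noise, n = 240, bleach = 40, seed = 1) {
    set.seed(seed)
    pre <- rep(1, bleach)
    t <- (0:(n - bleach - 1))
    post <- 0.2 + frac * (1 - 0.2) * (1 - exp(-rate * t))
    y <- c(pre, post)
    y + rnorm(n, 0, noise)
  }
  r <- frap_recovery(mk_trace(0.6, 0.05, 0), 40)
  expect_equal(r$recovery_fraction, 0.6, tolerance = 1e-6)
  expect_equal(r$rate_per_s, 0.05, tolerance = 1e-4)
  # plateau at the pre-bleach level is full recovery
  r1 <- frap_recovery(mk_trace(1, 0.05, 0), 40)
  expect_equal(r1$recovery_fraction, 1.0, tolerance = 1e-6)
  # arithmetic anchor: pre 1.0, post 0.2, plateau 0.68
  y <- c(rep(1, 20), 0.2 + 0.48 * (1 - exp(-0.1 * (0:99))))
  expect_equal(frap_recovery(y, 20)$recovery_fraction, 0.6, tolerance = 1e-6)
  # no bleach: error
  expect_error(frap_recovery(c(rep(1, 20), rep(1.2, 40)), 20), "bleach")
  expect_error(frap_recovery(rep(1, 100), 5), "10")
})

test_that("dwell events are detected with exact durations and censoring flags", {
  kp <- kymo_gen_params(n_rows = 600, n_cols = 100, mt_cols = c(20, 60),
                        boundary_col = NA, background_level = 10,
                        lattice_level = 10, envelope_level = 10,
                        noise_sd = 0.5, frame_s = 0.1, seed = 3,
                        events = list(n = 30,
                                      duration_mixture = data.frame(
                                        weight = 1, mean_s = 0.4),
                                      intensity = 20, dimer_fraction = 0,
                                      intensity_cv = 0.05))
  g <- generate_kymograph(kp)
  ev <- detect_dwell_events(g$kymo, c(20, 60))
  tr <- g$truth$events
  # isolated true events (no same-column overlap) must all be recovered
  # with exact frame durations
  key <- paste(tr$col)
  iso <- vapply(seq_len(nrow(tr)), function(i) {
    same <- which(tr$col == tr$col[i])
    same <- setdiff(same, i)
    !any(tr$start_frame[same] <= tr$start_frame[i] + tr$duration_frames[i] &
           tr$start_frame[same] + tr$duration_frames[same] >= tr$start_frame[i])
  }, TRUE)
  found <- 0
  for (i in which(iso)) {
    hit <- which(ev$position_px == tr$col[i] &
                   abs(ev$start_s - (tr$start_frame[i] - 1) * 0.1) < 1e-9)
    if (length(hit) == 1) {
      found <- found + 1
      expect_equal(ev$duration_s[hit],
                   min(tr$duration_frames[i],
                       600 - tr$start_frame[i] + 1) * 0.1)
    }
  }
  expect_gte(found / sum(iso), 0.98)
  expect_true(all(ev$duration_s >= g$kymo$frame_s))

  # an event spanning the final frame carries the censored flag
  img <- matrix(rnorm(100 * 50, 10, 0.3), 100, 50)
  img[95:100, 25] <- 40
  ev2 <- detect_dwell_events(kymograph(img, 100, 0.1), c(20, 30))
  expect_equal(nrow(ev2), 1)
  expect_true(ev2$censored)
  expect_equal(ev2$duration_s, 0.6)

  # empty kymograph: zero events
  quiet <- kymograph(matrix(rnorm(5000, 10, 0.5), 100, 50), 100, 0.1)
  expect_equal(nrow(detect_dwell_events(quiet, c(10, 30))), 0)
  expect_error(detect_dwell_events(quiet, c(1, 50)), "off-microtubule")
})

test_that("dwell fractions split at the threshold and respect censoring", {
  ev <- data.frame(start_s = c(0, 1, 2, 3), duration_s = c(0.1, 0.2, 0.5, 1.2),
                   mean_intensity = 1, censored = FALSE)
  class(ev) <- c("dwell_events", "data.frame")
  fr <- dwell_fractions(ev)
  expect_equal(fr$fraction_long, 0.5)
  expect_equal(fr$fraction_short, 0.5)
  expect_equal(fr$robustness$fraction_long[fr$robustness$threshold_s == 0.2],
               0.5)                       # 0.5 and 1.2 exceed 0.2
  ev$duration_s <- c(0.1, 0.2, 0.3, 0.32)
  expect_equal(dwell_fractions(ev)$fraction_long, 0)   # boundary inclusive
  ev$censored <- TRUE
  expect_error(dwell_fractions(ev), "censored")
})

test_that("stoichiometry classification separates constructed monomer/dimer mixes", {
  set.seed(5)
  x <- c(rnorm(120, 1, 0.05), rnorm(120, 2, 0.1))
  st <- classify_stoichiometry(x)
  expect_false(st$collapsed)
  expect_equal(st$monomer_mean, 1, tolerance = 0.05)
  truth <- rep(c("monomer", "dimer"), each = 120)
  expect_gte(mean(st$labels == truth), 0.98)
  # all-identical intensities collapse
  st1 <- classify_stoichiometry(rep(2, 30))
  expect_true(st1$collapsed)
  expect_equal(length(unique(st1$labels)), 1)
  # pure monomer collapses to one class
  st2 <- classify_stoichiometry(rnorm(200, 1, 0.05))
  expect_true(st2$collapsed)
  expect_error(classify_stoichiometry(rnorm(10)), "20")
})

test_that("seed extension fractions count qualifying adjacent runs", {
  mask <- rep(FALSE, 100)
  mask[21:30] <- TRUE                      # extension after seed 1
  mask[61:62] <- TRUE                      # too short for seed 2
  seeds <- list(c(11, 20), c(51, 60), c(81, 90))
  expect_equal(seed_extension_fraction(seeds, mask, 3), 1 / 3)
  expect_equal(seed_extension_fraction(seeds, rep(FALSE, 100), 3), 0)
  expect_error(seed_extension_fraction(list(), mask), "empty")
})

test_that("envelope ratio is invariant under affine intensity maps", {
  g <- generate_kymograph(kymo_gen_params(noise_sd = 2, seed = 9))
  rois <- list(envelope = list(rows = c(1, 200), cols = c(115, 155)),
               lattice = list(rows = c(1, 200), cols = c(25, 105)),
               bg = list(rows = c(1, 200), cols = c(165, 200)))
  r0 <- envelope_ratio(g$kymo, rois$envelope, rois$lattice, rois$bg)$ratio
  k2 <- g$kymo
  k2$intensity <- 3.7 * k2$intensity + 42
  r1 <- envelope_ratio(k2, rois$envelope, rois$lattice, rois$bg)$ratio
  expect_lt(abs(r1 - r0), 1e-12)
})
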