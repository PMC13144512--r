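#' Run the full end-shape analysis over a set of microtubule ends
#'
#' Chains, per end: axis fit, seed filtering, bend segmentation, shape
#' summary, lateral clustering, per-condition cluster distributions, the
#' threshold sweep, and pairwise condition statistics. The run is
#' deterministic for fixed inputs and configuration; excluded ends are
#' listed with their reasons rather than dropped silently.
#'
#' @param ends A list of [mt_end()] objects, or a path to a traces CSV
#'   readable by [read_traces()].
#' @param lattice The [lattice_model()] the ends come from (used for
#'   `d_ref` and angular order).
#' @param geometry A [geometry_config()].
#' @param clustering A [cluster_config()].
#' @param seed_filter A [seed_filter_config()]; applied only to ends whose
#'   `length_um` is known.
#' @param spacings Optional named numeric vector of measured lattice
#'   spacings (nm) per end id.
#' @param seed Seed recorded in the provenance (the analysis itself is
#'   deterministic).
#' @return A [result_bundle()] with `end_summaries`, `per_pf`,
#'   `cluster_assignments`, `distributions`, `sweep`, `tests`,
#'   `exclusions`.
#' @export
run_end_analysis <- function(ends, lattice = lattice_model(),
                             geometry = geometry_config(),
                             clustering = cluster_config(),
                             seed_filter = seed_filter_config(),
                             spacings = NULL, seed = NA_integer_) {
  if (is.character(ends)) ends <- read_traces(ends)
  if (!length(ends)) stop("no ends supplied", call. = FALSE)

  exclusions <- NULL
  kept <- list(); summaries <- NULL; per_pf <- NULL
  segs_kept <- list(); labels <- character(0)

  for (e in ends) {
    sp <- if (!is.null(spacings)) unname(spacings[e$end_id]) else NA_real_
    res <- tryCatch({
      axis <- fit_axis(e, geometry)
      segs <- lapply(e$traces, segment_bend, axis = axis, config = geometry)
      summ <- end_summary(e, segs, geometry, lattice_spacing_nm = sp)
      list(axis = axis, segs = segs, summ = summ)
    }, error = function(err) err)
    if (inherits(res, "error")) {
      exclusions <- rbind(exclusions,
                          data.frame(end_id = e$end_id, stage = "geometry",
                                     reason = conditionMessage(res)))
      next
    }
    if (!is.na(e$length_um)) {
      keep <- withCallingHandlers(
        filter_seed_like(res$summ, seed_filter),
        warning = function(w) invokeRestart("muffleWarning"))
      if (keep$decision == "exclude") {
        exclusions <- rbind(exclusions,
                            data.frame(end_id = e$end_id,
                                       stage = "seed_filter",
                                       reason = keep$reason))
        next
      }
    }
    kept[[e$end_id]] <- e
    segs_kept[[e$end_id]] <- res$segs
    labels[e$end_id] <- e$condition
    summaries <- rbind(summaries, data.frame(
      end_id = res$summ$end_id, condition = res$summ$condition,
      n_pf = res$summ$n_pf, fraction_unbent = res$summ$fraction_unbent,
      raggedness_nm = res$summ$raggedness_nm,
      mean_bent_length_nm = if (length(res$summ$bent_lengths_nm))
        mean(res$summ$bent_lengths_nm) else NA_real_,
      lattice_spacing_nm = res$summ$lattice_spacing_nm,
      length_um = res$summ$length_um))
    per_pf <- rbind(per_pf, data.frame(
      end_id = e$end_id,
      pf_id = vapply(res$segs, `[[`, 0L, "pf_id"),
      bent = vapply(res$segs, `[[`, TRUE, "bent"),
      onset_arclength_nm = vapply(res$segs, `[[`, 0, "onset_arclength_nm"),
      bent_length_nm = vapply(res$segs, `[[`, 0, "bent_length_nm")))
  }
  if (!length(kept)) stop("all ends excluded", call. = FALSE)

  assignments <- lapply(names(kept), function(id) {
    g <- adjacency_graph(kept[[id]], segs_kept[[id]], lattice,
                         clustering$overlap_threshold, clustering)
    connected_clusters(g)
  })
  nonempty <- vapply(assignments, function(a) length(a$sizes) > 0, TRUE)
  distributions <- if (any(nonempty))
    cluster_distribution(assignments[nonempty], labels) else NULL

  sweep <- threshold_sweep(unname(kept), unname(segs_kept), lattice,
                           clustering, labels)

  tests <- NULL
  conds <- unique(stats::na.omit(labels))
  if (length(conds) >= 2 && !is.null(distributions)) {
    tab <- t(vapply(conds, function(cc)
      distributions$count[distributions$condition == cc], numeric(3)))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) >= 2 && all(rowSums(tab) > 0)) {
      ct <- chi_squared_table(tab)
      tests <- data.frame(test = "chisq", groups = paste(conds, collapse = " vs "),
                          statistic = ct$statistic, df = ct$df, p = ct$p)
    }
  }

  result_bundle(end_summaries = summaries, per_pf = per_pf,
                cluster_assignments = lapply(assignments, unclass),
                distributions = distributions,
                sweep = sweep$distributions, tests = tests %||% sweep$tests,
                exclusions = exclusions %||%
                  data.frame(end_id = character(0), stage = character(0),
                             reason = character(0)),
                seed = seed,
                config = list(geometry = unclass(geometry),
                              clustering = unclass(clustering),
                              seed_filter = unclass(seed_filter)))
}

#' Run the fluorescence analysis over a set of kymographs
#'
#' Per movie: envelope boundary detection and envelope/lattice ratio;
#' optionally FRAP recovery on a supplied column range, and dwell-event
#' detection with short/long fractions and stoichiometry classification.
#'
#' @param movies A list; each element has `kymo` (a [kymograph()] or TIFF
#'   path), `mt_cols`, and optionally `rois` (list of `envelope`,
#'   `lattice`, `bg` boxes), `frap` (list with `bleach_frame`, `cols`),
#'   `dwell` (TRUE to run event detection).
#' @param dwell_cfg A [dwell_config()].
#' @param seed Seed recorded in provenance.
#' @return A [result_bundle()] with `envelope`, `frap`, `dwell_summary`,
#'   `events`, `exclusions`.
#' @export
run_fluorescence_analysis <- function(movies, dwell_cfg = dwell_config(),
                                      seed = NA_integer_) {
  if (!length(movies)) stop("no movies supplied", call. = FALSE)
  envelope <- NULL; frap <- NULL; dwell_sum <- NULL
  events_all <- NULL; exclusions <- NULL
  for (i in seq_along(movies)) {
    mv <- movies[[i]]
    id <- mv$id %||% sprintf("movie%d", i)
    kymo <- if (is.character(mv$kymo)) read_kymograph(mv$kymo) else mv$kymo
    res <- tryCatch({
      b <- detect_envelope_boundary(kymo, mv$mt_cols)
      row <- data.frame(movie = id, boundary_col = b$boundary_col,
                        step_height = b$step_height, ratio = NA_real_)
      if (!is.null(mv$rois)) {
        er <- envelope_ratio(kymo, mv$rois$envelope, mv$rois$lattice,
                             mv$rois$bg)
        row$ratio <- er$ratio
      } else if (!is.na(b$boundary_col)) {
        # automatic boxes from the detected boundary, background outside
        nr <- nrow(kymo$intensity)
        bcol <- b$boundary_col
        pad <- 2L
        env_roi <- list(rows = c(1, nr),
                        cols = c(min(bcol + pad, mv$mt_cols[2]), mv$mt_cols[2]))
        lat_roi <- list(rows = c(1, nr),
                        cols = c(mv$mt_cols[1], max(bcol - pad, mv$mt_cols[1])))
        # background: the larger contiguous off-microtubule block
        nc <- ncol(kymo$intensity)
        left <- if (mv$mt_cols[1] > 1) c(1, mv$mt_cols[1] - 1L) else NULL
        right <- if (mv$mt_cols[2] < nc) c(mv$mt_cols[2] + 1L, nc) else NULL
        if (is.null(left) && is.null(right))
          stop("no off-microtubule region for a background box", call. = FALSE)
        bg_cols <- if (is.null(left)) right
                   else if (is.null(right)) left
                   else if (diff(right) >= diff(left)) right else left
        bg_roi <- list(rows = c(1, nr), cols = bg_cols)
        er <- envelope_ratio(kymo, env_roi, lat_roi, bg_roi)
        row$ratio <- er$ratio
      }
      row
    }, error = function(err) err)
    if (inherits(res, "error")) {
      exclusions <- rbind(exclusions,
                          data.frame(movie = id, stage = "envelope",
                                     reason = conditionMessage(res)))
    } else envelope <- rbind(envelope, res)

    if (!is.null(mv$frap)) {
      fr <- tryCatch({
        cols <- mv$frap$cols
        trace <- rowMeans(kymo$intensity[, cols[1]:cols[2], drop = FALSE])
        r <- frap_recovery(trace, mv$frap$bleach_frame, kymo$frame_s)
        data.frame(movie = id, recovery_fraction = r$recovery_fraction,
                   plateau = r$plateau, rate_per_s = r$rate_per_s)
      }, error = function(err) err)
      if (inherits(fr, "error")) {
        exclusions <- rbind(exclusions,
                            data.frame(movie = id, stage = "frap",
                                       reason = conditionMessage(fr)))
      } else frap <- rbind(frap, fr)
    }

    if (isTRUE(mv$dwell)) {
      dw <- tryCatch({
        ev <- detect_dwell_events(kymo, mv$mt_cols, dwell_cfg)
        fr <- dwell_fractions(ev, dwell_cfg)
        st <- if (sum(!ev$censored) >= 20)
          classify_stoichiometry(ev$mean_intensity[!ev$censored]) else NULL
        list(events = cbind(movie = id, as.data.frame(ev)),
             summary = data.frame(
               movie = id, n_events = nrow(ev), n_used = fr$n_used,
               n_censored = fr$n_censored,
               fraction_short = fr$fraction_short,
               fraction_long = fr$fraction_long,
               monomer_mean = if (is.null(st)) NA_real_ else st$monomer_mean,
               dimer_weight = if (is.null(st)) NA_real_
                              else unname(st$weights["dimer"])))
      }, error = function(err) err)
      if (inherits(dw, "error")) {
        exclusions <- rbind(exclusions,
                            data.frame(movie = id, stage = "dwell",
                                       reason = conditionMessage(dw)))
      } else {
        events_all <- rbind(events_all, dw$events)
        dwell_sum <- rbind(dwell_sum, dw$summary)
      }
    }
  }
  result_bundle(envelope = envelope, frap = frap,
                dwell_summary = dwell_sum, events = events_all,
                exclusions = exclusions %||%
                  data.frame(movie = character(0), stage = character(0),
                             reason = character(0)),
                seed = seed, config = list(dwell = unclass(dwell_cfg)))
}
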