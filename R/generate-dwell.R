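#' Parameters for synthetic dwell-event generation
#'
#' Draws single-molecule residence times from an exponential mixture,
#' discretises them to camera frames by ceiling, drops events shorter than
#' one frame (below the detection limit), flags events overlapping the
#' movie boundaries as censored, and assigns intensities by stoichiometry
#' class (dimer brightness is twice monomer brightness).
#'
#' @param n_events Number of events drawn (before the short-event drop).
#' @param mixture Data frame with columns `weight` and `mean_dwell_s`;
#'   weights must be positive and are normalised to sum to 1.
#' @param frame_s Acquisition interval (s).
#' @param movie_len_s Movie duration (s).
#' @param intensity_monomer Mean monomer brightness (arbitrary units); the
#'   dimer class mean is twice this.
#' @param intensity_cv Coefficient of variation of event brightness.
#' @param dimer_fraction Probability an event is a dimer.
#' @param seed RNG seed (mandatory).
#' @return A list of class `dwell_gen_params`.
#' @export
dwell_gen_params <- function(n_events = 1000L,
                             mixture = data.frame(weight = 1, mean_dwell_s = 0.2),
                             frame_s = 0.04, movie_len_s = 120,
                             intensity_monomer = 1, intensity_cv = 0.1,
                             dimer_fraction = 0, seed = NULL) {
  check_scalar(n_events, "n_events", positive = TRUE, integerish = TRUE)
  if (!is.data.frame(mixture) ||
      !all(c("weight", "mean_dwell_s") %in% names(mixture)))
    stop_field("mixture", "needs columns `weight` and `mean_dwell_s`")
  if (any(mixture$weight < 0) || sum(mixture$weight) <= 0)
    stop_field("mixture", "weights must be >= 0 with a positive sum")
  if (any(mixture$mean_dwell_s <= 0))
    stop_field("mixture", "mean dwells must be > 0")
  check_scalar(frame_s, "frame_s", positive = TRUE)
  check_scalar(movie_len_s, "movie_len_s", positive = TRUE)
  check_scalar(intensity_monomer, "intensity_monomer", positive = TRUE)
  check_scalar(intensity_cv, "intensity_cv", nonneg = TRUE)
  check_scalar(dimer_fraction, "dimer_fraction", unit = TRUE)
  seed <- check_seed(seed)
  mixture$weight <- mixture$weight / sum(mixture$weight)
  structure(list(n_events = as.integer(n_events), mixture = mixture,
                 frame_s = frame_s, movie_len_s = movie_len_s,
                 intensity_monomer = intensity_monomer,
                 intensity_cv = intensity_cv,
                 dimer_fraction = dimer_fraction, seed = seed),
            class = "dwell_gen_params")
}

#' Generate a synthetic dwell-event dataset with ground truth
#'
#' @param params A [dwell_gen_params()].
#' @return A list with `events` (a `dwell_events` data frame: `start_s`,
#'   `duration_s`, `mean_intensity`, `censored`) and `truth` (the
#'   continuous durations, component ids, stoichiometry classes, and the
#'   number of sub-frame events dropped).
#' @export
generate_dwell_dataset <- function(params) {
  stopifnot(inherits(params, "dwell_gen_params"))
  with_seed(params$seed, {
    comp <- sample.int(nrow(params$mixture), params$n_events, replace = TRUE,
                       prob = params$mixture$weight)
    true_dur <- rexp(params$n_events,
                     rate = 1 / params$mixture$mean_dwell_s[comp])
    start <- runif(params$n_events, 0, params$movie_len_s)
    is_dimer <- runif(params$n_events) < params$dimer_fraction
    mean_amp <- params$intensity_monomer * ifelse(is_dimer, 2, 1)
    amp <- if (params$intensity_cv > 0)
      rnorm(params$n_events, mean_amp, params$intensity_cv * mean_amp)
    else mean_amp

    detected <- true_dur >= params$frame_s      # sub-frame events are missed
    dur_obs <- ceiling(true_dur / params$frame_s) * params$frame_s
    censored <- start + dur_obs > params$movie_len_s

    events <- data.frame(start_s = start[detected],
                         duration_s = dur_obs[detected],
                         mean_intensity = amp[detected],
                         censored = censored[detected])
    events <- events[order(events$start_s), , drop = FALSE]
    rownames(events) <- NULL
    class(events) <- c("dwell_events", "data.frame")
    list(events = events,
         truth = list(true_duration_s = true_dur, component = comp,
                      dimer = is_dimer, n_dropped = sum(!detected)))
  })
}
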