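#' Generate a paracrystal calibration field
#'
#' Paracrystals — laterally aligned filament bundles with suppressed
#' structural variation — are the measurement-error standard: their true
#' pitch is constant (structural SD 0, mean 36.5 nm), so all apparent
#' pitch variance in the rendered field comes from peak localization
#' jitter, orientation offset and pixel noise. Measuring a rendered
#' paracrystal field with the standard pipeline therefore calibrates the
#' measurement-error SD that [subtract_measurement_variance()] removes
#' from free-filament distributions.
#'
#' Filaments are rendered as parallel straight rows,
#' `filament_spacing_nm` apart; every frame re-renders the same models
#' with fresh jitter and noise, so pooling pitches across frames yields
#' independent error draws.
#'
#' @param config an [afm_config()]; the `paracrystal` state supplies the
#'   pitch/height parameters and must have zero structural pitch SD.
#' @param n_filaments number of parallel filaments (>= 1).
#' @param n_half_helices half helices per filament.
#' @param n_frames frames to render (defaults to `config$n_frames`).
#' @param seed integer seed; `config$seed` when `NULL`.
#' @return object of class `afm_simulation` with `movie`, per-frame
#'   ground truth in `states_history`, an empty event log, and the
#'   per-frame, per-filament truth attached to each frame.
#' @export
make_paracrystal_field <- function(config, n_filaments,
                                   n_half_helices = 25L,
                                   n_frames = NULL, seed = NULL) {
  config <- validate_afm_config(config)
  n_filaments <- as.integer(n_filaments)
  if (n_filaments < 1L) stop("`n_filaments` must be >= 1")
  if (is.null(n_frames)) n_frames <- config$n_frames
  if (is.null(seed)) seed <- config$seed
  set.seed(derive_seed(seed, 0))

  models <- lapply(seq_len(n_filaments), function(i) {
    m <- build_filament_model(config, n_half_helices, state = "paracrystal")
    m$row_id <- i
    m
  })

  frames <- lapply(seq_len(n_frames), function(f)
    render_frame(models, config, seed = derive_seed(seed, 15013 * f),
                 t_s = (f - 1L) * config$frame_interval_s))

  history <- rep(list(lapply(models, function(m)
    list(global_index = m$global_index,
         states = m$half_helices$state,
         pitch_true_nm = m$half_helices$pitch_true_nm,
         arcs_true_nm = model_peak_arcs(m)))), n_frames)

  structure(
    list(movie = afm_movie(frames, frame_interval_s = config$frame_interval_s),
         log = list(growth = bind_event_rows(list(),
                                             c("frame", "direction",
                                               "global_index")),
                    severing = bind_event_rows(list(),
                                               c("frame", "global_index",
                                                 "category", "arc_nm"))),
         states_history = history,
         polarity = "pointed_at_start",
         config = config,
         seed = as.integer(seed)),
    class = "afm_simulation"
  )
}

#' Measure half-helical pitches of a rendered simulation
#'
#' Runs the full measurement chain (preprocess, trace, detect, refine,
#' difference) over every frame and filament of a rendered simulation and
#' returns the pooled pitch table, aligned with ground truth so each
#' measured pitch carries its true value and state. Half helices whose
#' bounding peaks were missed are omitted; filaments that could not be
#' traced or matched at all are counted in the `n_dropped` attribute.
#'
#' @param sim an `afm_simulation` with a rendered movie.
#' @param params an [afm_params()].
#' @param frames frame indices to measure (default all).
#' @return data frame of measured half helices with truth columns
#'   (`pitch_nm`, `mean_peak_height_nm`, `state_true`, `pitch_true_nm`,
#'   `global_index`, `frame`, `filament`).
#' @export
measure_simulation_pitches <- function(sim, params = afm_params(),
                                       frames = NULL) {
  stopifnot(inherits(sim, "afm_simulation"))
  if (is.null(sim$movie)) stop("simulation has no rendered movie")
  if (is.null(frames)) frames <- seq_along(sim$movie$frames)
  out <- list()
  dropped <- 0L
  for (f in frames) {
    fr0 <- sim$movie$frames[[f]]
    fr <- preprocess_frame(fr0,
                           spike_window_px = params$spike_window_px,
                           spike_threshold_nm = params$spike_threshold_nm,
                           flatten = params$flatten,
                           foreground_threshold_nm =
                             params$foreground_threshold_nm)
    truths <- attr(fr0, "truth")
    for (k in seq_along(truths)) {
      tru <- truths[[k]]
      trc <- tryCatch(
        trace_backbone(fr, tru$seed_xy,
                       height_floor_nm = params$height_floor_nm,
                       band_radius_px = params$band_radius_px),
        error = function(e) NULL)
      if (is.null(trc)) { dropped <- dropped + 1L; next }
      pk <- detect_peaks_along_trace(fr, trc,
                                     min_separation_nm =
                                       params$min_separation_nm,
                                     height_floor_nm =
                                       params$height_floor_nm,
                                     min_prominence_nm =
                                       params$min_prominence_nm,
                                     window_px = params$window_px,
                                     height_mode = params$height_mode)
      hh <- half_pitches_with_truth(pk, tru)
      if (is.null(hh)) { dropped <- dropped + 1L; next }
      hh$frame <- f
      hh$filament <- k
      out[[length(out) + 1L]] <- hh
    }
  }
  res <- if (length(out)) do.call(rbind, out) else NULL
  attr(res, "n_dropped") <- dropped
  res
}

#' Calibrate the injected localization jitter against the pipeline
#'
#' The measured pitch error has two parts: the injected per-peak
#' localization jitter (the orientation/structure-induced displacement of
#' the apparent peak from the true crossover) and the detection error of
#' the center-of-mass refinement itself, which depends on pixel size and
#' noise. Mirroring the paracrystal calibration logic, this renders a
#' zero-jitter paracrystal field, measures the detection-only pitch error
#' SD, and solves for the injected jitter that makes the total pitch
#' error of the full pipeline equal `target_pitch_error_nm` in
#' quadrature:
#' `sigma_p = sqrt((target^2 - sd_detect^2) / 2)`.
#'
#' @param config an [afm_config()].
#' @param target_pitch_error_nm total pitch-level measurement error to
#'   calibrate to (default 3.0 nm, the paracrystal value).
#' @param n_filaments,n_half_helices,n_frames size of the calibration
#'   field.
#' @param seed integer seed.
#' @param params an [afm_params()].
#' @return `config` with `localization_jitter_nm` set; attributes
#'   `sd_detection_pitch_nm` (measured detection-only pitch error SD) and
#'   `n_pitches`.
#' @export
calibrate_localization_jitter <- function(config,
                                          target_pitch_error_nm = 3.0,
                                          n_filaments = 8L,
                                          n_half_helices = 25L,
                                          n_frames = 2L,
                                          seed = NULL,
                                          params = afm_params()) {
  config <- validate_afm_config(config)
  if (is.null(seed)) seed <- config$seed
  cfg0 <- config
  cfg0$localization_jitter_nm <- 0
  sim <- make_paracrystal_field(cfg0, n_filaments, n_half_helices,
                                n_frames = n_frames, seed = seed)
  hh <- measure_simulation_pitches(sim, params)
  if (is.null(hh) || nrow(hh) < 50L)
    stop("calibration field yielded too few pitches")
  sd_det <- stats::sd(hh$pitch_nm - hh$pitch_true_nm)
  if (sd_det >= target_pitch_error_nm)
    stop(sprintf(paste0("detection error alone (%.2f nm) exceeds the ",
                        "calibration target (%.2f nm); reduce noise or ",
                        "pixel size"), sd_det, target_pitch_error_nm))
  out <- config
  out$localization_jitter_nm <- sqrt((target_pitch_error_nm^2 - sd_det^2) / 2)
  attr(out, "sd_detection_pitch_nm") <- sd_det
  attr(out, "n_pitches") <- nrow(hh)
  out
}

#' Generate a field of free filaments (control or clustered)
#'
#' Renders `n_filaments` parallel filaments drawn independently from the
#' generator, as static frames (no growth/severing dynamics; use
#' [simulate_dynamics()] for those). The workhorse for measurement
#' validation: control fields (all bare) reproduce the free-filament
#' pitch distribution, cluster fields with `cluster_specs` reproduce the
#' boundary-asymmetry conditions.
#'
#' @param config an [afm_config()].
#' @param n_filaments number of filaments.
#' @param n_half_helices half helices per filament.
#' @param state default half-helix state (usually `"bare"`).
#' @param cluster_specs either `NULL`, or one cluster spec (list of
#'   `c(first, last)` intervals) applied to every filament, or a list of
#'   per-filament specs.
#' @param n_frames frames to render (fresh jitter/noise each).
#' @param seed integer seed.
#' @return an `afm_simulation` with rendered movie and per-frame truth.
#' @export
make_filament_field <- function(config, n_filaments, n_half_helices = 25L,
                                state = "bare", cluster_specs = NULL,
                                n_frames = 1L, seed = NULL) {
  config <- validate_afm_config(config)
  n_filaments <- as.integer(n_filaments)
  if (n_filaments < 1L) stop("`n_filaments` must be >= 1")
  if (is.null(seed)) seed <- config$seed
  set.seed(derive_seed(seed, 1))

  per_fil <- if (is.null(cluster_specs)) rep(list(list()), n_filaments)
  else if (length(cluster_specs) && is.numeric(cluster_specs[[1L]]))
    rep(list(cluster_specs), n_filaments)
  else rep_len(cluster_specs, n_filaments)

  models <- lapply(seq_len(n_filaments), function(i) {
    m <- build_filament_model(config, n_half_helices,
                              cluster_spec = per_fil[[i]], state = state)
    m$row_id <- i
    m
  })

  frames <- lapply(seq_len(n_frames), function(f)
    render_frame(models, config, seed = derive_seed(seed, 27011 * f),
                 t_s = (f - 1L) * config$frame_interval_s))

  history <- rep(list(lapply(models, function(m)
    list(global_index = m$global_index,
         states = m$half_helices$state,
         pitch_true_nm = m$half_helices$pitch_true_nm,
         arcs_true_nm = model_peak_arcs(m)))), n_frames)

  structure(
    list(movie = afm_movie(frames, frame_interval_s = config$frame_interval_s),
         log = list(growth = bind_event_rows(list(),
                                             c("frame", "direction",
                                               "global_index")),
                    severing = bind_event_rows(list(),
                                               c("frame", "global_index",
                                                 "category", "arc_nm"))),
         states_history = history,
         polarity = "pointed_at_start",
         config = config,
         seed = as.integer(seed)),
    class = "afm_simulation"
  )
}

#' Neighbor-asymmetry table of a rendered simulation
#'
#' Measures every filament of a rendered simulation, maps ground-truth
#' decoration onto the measured half helices (cluster identity at the
#' paper's own semi-manual certainty; pitches stay fully image-based) and
#' pools the bare neighbors of every cluster into the P1/P2/B1/B2 table
#' via [neighbor_pitch_table()]. Unmeasured half helices enter as `NA`
#' and are excluded from the pools.
#'
#' @param sim an `afm_simulation` with a rendered movie.
#' @param params an [afm_params()].
#' @param frames frame indices to measure (default all).
#' @return the pooled neighbor table (see [neighbor_pitch_table()]).
#' @export
measure_neighbor_table <- function(sim, params = afm_params(),
                                   frames = NULL) {
  stopifnot(inherits(sim, "afm_simulation"))
  if (is.null(sim$movie)) stop("simulation has no rendered movie")
  if (is.null(frames)) frames <- seq_along(sim$movie$frames)
  tables <- list()
  for (f in frames) {
    fr0 <- sim$movie$frames[[f]]
    fr <- preprocess_frame(fr0,
                           spike_window_px = params$spike_window_px,
                           spike_threshold_nm = params$spike_threshold_nm,
                           flatten = params$flatten,
                           foreground_threshold_nm =
                             params$foreground_threshold_nm)
    for (tru in attr(fr0, "truth")) {
      trc <- tryCatch(
        trace_backbone(fr, tru$seed_xy,
                       height_floor_nm = params$height_floor_nm,
                       band_radius_px = params$band_radius_px),
        error = function(e) NULL)
      if (is.null(trc)) next
      pk <- detect_peaks_along_trace(fr, trc,
                                     min_separation_nm =
                                       params$min_separation_nm,
                                     height_floor_nm =
                                       params$height_floor_nm,
                                     min_prominence_nm =
                                       params$min_prominence_nm,
                                     window_px = params$window_px,
                                     height_mode = params$height_mode)
      hh <- half_pitches_with_truth(pk, tru)
      tables[[length(tables) + 1L]] <- complete_half_helix_table(hh, tru)
    }
  }
  if (!length(tables)) stop("no filaments could be measured")
  neighbor_pitch_table(tables, sim$polarity)
}
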