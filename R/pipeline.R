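#' Analysis parameter set
#'
#' All tunable parameters of the measurement pipeline in one validated
#' list; every analysis entry point takes one of these, so a run is fully
#' described by (movie, params, seed).
#'
#' @param spike_window_px,spike_threshold_nm spike filter, see
#'   [remove_spike_noise()].
#' @param flatten apply [flatten_plane()] after spike removal.
#' @param foreground_threshold_nm mask threshold for the plane fit (nm).
#' @param height_floor_nm filament/background floor for tracing, peak
#'   picking and gap detection (nm).
#' @param band_radius_px lateral re-centering radius of the tracer.
#' @param min_separation_nm minimum arc separation of crossover peaks.
#' @param min_prominence_nm minimum peak prominence, see
#'   [detect_peaks_along_trace()].
#' @param window_px peak search/refinement window edge (pixels).
#' @param height_mode `"interpolated"` or `"max_pixel"`, see
#'   [refine_peak()].
#' @param decoration_threshold_nm bare/decorated height threshold (nm).
#' @param max_displacement_nm frame-to-frame linking cutoff (nm).
#' @param gap_threshold_nm,persistence_frames severing gap rules, see
#'   [detect_breaks()].
#' @return a named list of class `afm_params`.
#' @export
afm_params <- function(spike_window_px = 3L,
                       spike_threshold_nm = 2.0,
                       flatten = TRUE,
                       foreground_threshold_nm = 2.0,
                       height_floor_nm = 4.0,
                       band_radius_px = 3,
                       min_separation_nm = 15,
                       min_prominence_nm = 0.6,
                       window_px = 5L,
                       height_mode = "interpolated",
                       decoration_threshold_nm = 9.6,
                       max_displacement_nm = 10,
                       gap_threshold_nm = 10,
                       persistence_frames = 2L) {
  structure(as.list(environment()), class = "afm_params")
}

#' Detect filament seed points in a frame
#'
#' Finds connected regions above the height floor and returns the highest
#' pixel of each — one seed per filament for [trace_backbone()]. Regions
#' smaller than `min_pixels` are discarded as debris.
#'
#' @param frame an `afm_frame` (preprocessed).
#' @param height_floor_nm region threshold (nm).
#' @param min_pixels minimum region size.
#' @return matrix with one row per region: columns `x_nm`, `y_nm`.
#' @export
find_filament_seeds <- function(frame, height_floor_nm = 4.0,
                                min_pixels = 20L) {
  g <- frame$grid
  px <- frame$pixel_size_nm
  nr <- nrow(g); nc <- ncol(g)
  fg <- g >= height_floor_nm
  label <- matrix(0L, nr, nc)
  cur <- 0L
  seeds <- list()
  todo <- which(fg & label == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    frontier <- todo[1L]
    label[frontier] <- cur
    comp <- frontier
    while (length(frontier)) {
      i <- ((frontier - 1L) %% nr) + 1L
      j <- ((frontier - 1L) %/% nr) + 1L
      nb <- c(frontier - 1L, frontier + 1L,
              frontier - nr, frontier + nr)
      ok <- c(i > 1L, i < nr, j > 1L, j < nc)
      nb <- nb[ok]
      nb <- nb[fg[nb] & label[nb] == 0L]
      nb <- unique(nb)
      label[nb] <- cur
      comp <- c(comp, nb)
      frontier <- nb
    }
    if (length(comp) >= min_pixels) {
      top <- comp[which.max(g[comp])]
      seeds[[length(seeds) + 1L]] <-
        c(x_nm = ((((top - 1L) %/% nr) + 1L) - 1L) * px,
          y_nm = ((((top - 1L) %% nr) + 1L) - 1L) * px)
    }
    todo <- which(fg & label == 0L)
  }
  if (!length(seeds))
    return(matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("x_nm", "y_nm"))))
  do.call(rbind, seeds)
}

#' Measure one frame: trace, peaks, half helices, decoration
#'
#' Applies the preprocessing chain, traces a backbone from each seed,
#' detects and refines crossover peaks along it, converts them to half
#' helices and classifies decoration. Filaments are numbered by seed
#' order.
#'
#' @param frame an `afm_frame`.
#' @param seeds matrix/data frame of seed positions (`x_nm`, `y_nm`
#'   columns or two columns), or `NULL` to auto-detect.
#' @param params an [afm_params()].
#' @param polarity polarity annotation applied to every trace.
#' @return list with `peaks` and `half_helices` data frames (both with a
#'   `filament` column) and the list of `traces`; filaments whose trace
#'   fails (e.g. fully severed away) are skipped.
#' @export
analyze_frame <- function(frame, seeds = NULL, params = afm_params(),
                          polarity = "unknown") {
  fr <- preprocess_frame(frame,
                         spike_window_px = params$spike_window_px,
                         spike_threshold_nm = params$spike_threshold_nm,
                         flatten = params$flatten,
                         foreground_threshold_nm =
                           params$foreground_threshold_nm)
  if (is.null(seeds))
    seeds <- find_filament_seeds(fr, params$height_floor_nm)
  seeds <- as.matrix(seeds)
  peaks <- list(); hh <- list(); traces <- list()
  for (k in seq_len(nrow(seeds))) {
    tr <- tryCatch(
      trace_backbone(fr, as.numeric(seeds[k, 1:2]),
                     height_floor_nm = params$height_floor_nm,
                     band_radius_px = params$band_radius_px,
                     polarity = polarity),
      error = function(e) NULL)
    if (is.null(tr)) next
    pk <- detect_peaks_along_trace(fr, tr,
                                   min_separation_nm =
                                     params$min_separation_nm,
                                   height_floor_nm = params$height_floor_nm,
                                   min_prominence_nm =
                                     params$min_prominence_nm,
                                   window_px = params$window_px,
                                   height_mode = params$height_mode)
    h <- half_pitches(pk)
    if (nrow(pk)) {
      pk$filament <- k
      peaks[[length(peaks) + 1L]] <- pk
    }
    if (nrow(h)) {
      h$state <- classify_decoration(h, params$decoration_threshold_nm)
      h$filament <- k
      hh[[length(hh) + 1L]] <- h
    }
    traces[[k]] <- tr
  }
  list(peaks = if (length(peaks)) do.call(rbind, peaks) else empty_peaks(),
       half_helices = if (length(hh)) do.call(rbind, hh) else NULL,
       traces = traces)
}

#' Measure a movie end to end
#'
#' Runs [analyze_frame()] on every frame (seeds re-used across frames —
#' filaments are immobilized on the supported bilayer), links crossover
#' peaks into tracks per filament, finds clusters per frame and detects
#' image-domain growth events from the cluster half-helix spans.
#'
#' @param movie an `afm_movie`.
#' @param seeds seed matrix as in [analyze_frame()]; when `NULL`, seeds
#'   are auto-detected on the first frame.
#' @param params an [afm_params()].
#' @param polarity polarity annotation (from the ground-truth sidecar or
#'   an S1-based manual call).
#' @return list of class `afm_analysis`: `peaks` (with `frame`,
#'   `filament`, `track_id`), `half_helices` (with `frame`, `state`),
#'   `clusters` (per frame/filament spans), `growth_events`, `params`.
#' @export
afm_analyze <- function(movie, seeds = NULL, params = afm_params(),
                        polarity = "unknown") {
  stopifnot(inherits(movie, "afm_movie"))
  if (is.null(seeds)) {
    fr1 <- preprocess_frame(movie$frames[[1L]],
                            spike_window_px = params$spike_window_px,
                            spike_threshold_nm = params$spike_threshold_nm,
                            flatten = params$flatten,
                            foreground_threshold_nm =
                              params$foreground_threshold_nm)
    seeds <- find_filament_seeds(fr1, params$height_floor_nm)
  }
  res <- lapply(seq_along(movie$frames), function(f) {
    a <- analyze_frame(movie$frames[[f]], seeds, params, polarity)
    if (nrow(a$peaks)) a$peaks$frame <- f
    if (!is.null(a$half_helices) && nrow(a$half_helices))
      a$half_helices$frame <- f
    a
  })
  pk_list <- Filter(function(x) !is.null(x) && nrow(x) > 0,
                    lapply(res, `[[`, "peaks"))
  peaks <- if (length(pk_list)) do.call(rbind, pk_list) else {
    p <- empty_peaks(); p$filament <- integer(0); p$frame <- integer(0); p
  }
  hh_list <- Filter(function(x) !is.null(x) && nrow(x) > 0,
                    lapply(res, `[[`, "half_helices"))
  hh <- if (length(hh_list)) do.call(rbind, hh_list) else NULL
  # link per filament; track ids offset to stay globally unique
  linked <- list()
  id_base <- 0L
  for (k in unique(peaks$filament)) {
    sub <- peaks[peaks$filament == k, , drop = FALSE]
    lk <- link_peaks(sub, max_displacement_nm = params$max_displacement_nm)
    lk$track_id <- lk$track_id + id_base
    id_base <- id_base + max(lk$track_id - id_base, 0L)
    linked[[length(linked) + 1L]] <- lk
  }
  peaks <- if (length(linked)) do.call(rbind, linked) else peaks
  clusters <- NULL
  growth <- NULL
  if (!is.null(hh) && nrow(hh)) {
    cl <- lapply(split(hh, list(hh$frame, hh$filament), drop = FALSE),
                 function(x) find_clusters(x$state))
    clusters <- do.call(rbind, lapply(names(cl), function(nm) {
      x <- cl[[nm]]
      if (!nrow(x)) return(NULL)
      fk <- strsplit(nm, ".", fixed = TRUE)[[1L]]
      data.frame(frame = as.integer(fk[1L]), filament = as.integer(fk[2L]),
                 first = x$first, last = x$last)
    }))
    if (polarity %in% c("pointed_at_start", "pointed_at_end")) {
      growth <- do.call(rbind, lapply(unique(hh$filament), function(k) {
        byf <- lapply(sort(unique(hh$frame)), function(f)
          find_clusters(hh$state[hh$frame == f & hh$filament == k]))
        ev <- detect_growth_events(byf, polarity)
        if (nrow(ev)) ev$filament <- k
        ev
      }))
    }
  }
  structure(list(peaks = peaks, half_helices = hh, clusters = clusters,
                 growth_events = growth, params = params,
                 polarity = polarity),
            class = "afm_analysis")
}

#' Summarize an analysis into the standard condition statistics
#'
#' Pools half helices by decoration state and reports the distribution
#' summaries, the measurement-error decomposition of the pitch SDs
#' against a calibrated error SD, and the supertwist statistics when both
#' states are present.
#'
#' @param analysis an `afm_analysis` (or a half-helix data frame with
#'   `pitch_nm`, `mean_peak_height_nm`, `state`).
#' @param sd_err_nm calibrated measurement-error SD for the pitch
#'   (default 3.0 nm, the paracrystal value).
#' @return list: per-state `pitch` and `height` summaries,
#'   `decomposition` (per state, where defined), `supertwist` (or
#'   `NULL`).
#' @export
afm_summarize <- function(analysis, sd_err_nm = 3.0) {
  hh <- if (inherits(analysis, "afm_analysis")) analysis$half_helices
  else analysis
  if (is.null(hh) || !nrow(hh)) stop("no half helices to summarize")
  out <- list(pitch = list(), height = list(), decomposition = list())
  for (s in unique(hh$state)) {
    v <- hh[hh$state == s, , drop = FALSE]
    if (nrow(v) < 2L) next
    out$pitch[[s]] <- summarize_distribution(v$pitch_nm)
    out$height[[s]] <- summarize_distribution(v$mean_peak_height_nm)
    if (out$pitch[[s]]$sd >= sd_err_nm)
      out$decomposition[[s]] <-
        subtract_measurement_variance(out$pitch[[s]]$sd, sd_err_nm)
  }
  out$supertwist <-
    if (!is.null(out$pitch$bare) && !is.null(out$pitch$decorated))
      supertwist_stats(out$pitch$bare$mean, out$pitch$decorated$mean)
  else NULL
  out
}
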