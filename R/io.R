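#' Write a movie as multi-page TIFF with a JSON calibration sidecar
#'
#' Heights (nm) are stored as 32-bit TIFF samples scaled into the
#' `[z_min, z_max]` range recorded in the sidecar
#' (`<path>.json`: pixel size, frame interval, timestamps, z range),
#' which preserves heights to ~1e-9 nm. The sidecar is what makes the
#' file self-calibrating; [read_movie()] refuses to guess missing
#' calibration.
#'
#' @param movie an `afm_movie`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "afm_movie"))
  zr <- range(vapply(movie$frames, function(f) range(f$grid),
                     numeric(2)))
  if (diff(zr) == 0) zr[2L] <- zr[1L] + 1
  pages <- lapply(movie$frames, function(f)
    (f$grid - zr[1L]) / (zr[2L] - zr[1L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(
    format = "afmhelix-movie",
    pixel_size_nm = movie$pixel_size_nm,
    frame_interval_s = movie$frame_interval_s,
    t_s = vapply(movie$frames, function(f) f$t_s, numeric(1)),
    z_min_nm = zr[1L], z_max_nm = zr[2L],
    height_units = "nm"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated movie from TIFF
#'
#' Reads a multi-page TIFF written by [write_movie()] (calibration taken
#' from the `<path>.json` sidecar) or any plain multi-page TIFF whose
#' pixel values are already heights in nm, in which case `pixel_size_nm`
#' (and optionally `frame_interval_s`) must be given explicitly — missing
#' calibration is an error, never guessed.
#'
#' @param path TIFF path.
#' @param pixel_size_nm pixel size override (nm).
#' @param frame_interval_s frame interval override (s).
#' @return an `afm_movie`.
#' @export
read_movie <- function(path, pixel_size_nm = NULL, frame_interval_s = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read `%s`", path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  px <- pixel_size_nm %||% meta$pixel_size_nm
  if (is.null(px))
    stop("missing calibration: supply `pixel_size_nm` or a JSON sidecar")
  dt <- frame_interval_s %||% meta$frame_interval_s %||% NA_real_
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  if (!is.null(meta$z_min_nm) && !is.null(meta$z_max_nm)) {
    pages <- lapply(pages, function(p)
      p * (meta$z_max_nm - meta$z_min_nm) + meta$z_min_nm)
  }
  ts <- if (!is.null(meta$t_s)) unlist(meta$t_s)
  else (seq_along(pages) - 1L) * (if (is.na(dt)) 1 else dt)
  frames <- lapply(seq_along(pages), function(i)
    height_frame(pages[[i]], as.numeric(px), t_s = ts[i]))
  afm_movie(frames, frame_interval_s = as.numeric(dt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation ground truth as a JSON sidecar
#'
#' Serializes the event log, polarity and the per-frame lattice states of
#' an [simulate_dynamics()] / [make_paracrystal_field()] result, so that
#' analyses of a written movie can be validated without re-running the
#' generator.
#'
#' @param sim an `afm_simulation`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  stopifnot(inherits(sim, "afm_simulation"))
  jsonlite::write_json(
    list(polarity = sim$polarity,
         seed = sim$seed,
         growth_events = sim$log$growth,
         severing_events = sim$log$severing,
         frames = lapply(sim$states_history, function(frs)
           lapply(frs, function(fr)
             list(global_index = fr$global_index,
                  states = fr$states,
                  pitch_true_nm = fr$pitch_true_nm,
                  arcs_true_nm = fr$arcs_true_nm)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Echo a generator/analysis configuration to YAML
#'
#' @param config an [afm_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_afm_config(config)
  x <- unclass(config)
  x$severing_rates <- as.list(x$severing_rates)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' @param path YAML path written by [write_config()] (unknown fields are
#'   rejected; missing fields take [afm_config()] defaults).
#' @return an `afm_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(afm_config))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop(sprintf("unknown config fields: %s", paste(bad, collapse = ", ")))
  if (!is.null(x$severing_rates))
    x$severing_rates <- unlist(x$severing_rates)
  do.call(afm_config, x)
}
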