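#' Default per-state helical parameters
#'
#' Each conformational state of a half helix carries a structural pitch
#' distribution and a crossover peak-height distribution. Defaults are the
#' published HS-AFM statistics for actin/cofilactin:
#' bare F-actin 36.8 nm pitch (structural SD 3.1 nm after removing the
#' 3.0 nm measurement error measured on paracrystals) and 8.6 +/- 0.8 nm
#' peak height; cofilin-decorated segments 26.9 nm (structural SD 2.3 nm)
#' and 10.6 +/- 1.0 nm; the first bare neighbor on the pointed-end side of
#' a cluster 28.8 nm / 9.2 nm; the first neighbor on the barbed-end side
#' 37.3 nm / 9.0 nm. Neighbor structural SDs are obtained from the observed
#' SDs (4.5, 4.6 nm) by the same quadrature subtraction of the 3.0 nm
#' calibration error. The `paracrystal` state has zero structural pitch SD
#' by construction: paracrystals are the measurement-error standard.
#'
#' @return named list of states, each a list with `pitch_mean_nm`,
#'   `pitch_sd_struct_nm`, `peak_height_mean_nm`, `peak_height_sd_nm`.
#' @export
afm_default_states <- function() {
  list(
    bare = list(pitch_mean_nm = 36.8, pitch_sd_struct_nm = 3.1,
                peak_height_mean_nm = 8.6, peak_height_sd_nm = 0.8),
    decorated = list(pitch_mean_nm = 26.9, pitch_sd_struct_nm = 2.3,
                     peak_height_mean_nm = 10.6, peak_height_sd_nm = 1.0),
    p_neighbor = list(pitch_mean_nm = 28.8,
                      pitch_sd_struct_nm = sqrt(4.5^2 - 3.0^2),
                      peak_height_mean_nm = 9.2, peak_height_sd_nm = 1.0),
    b_neighbor = list(pitch_mean_nm = 37.3,
                      pitch_sd_struct_nm = sqrt(4.6^2 - 3.0^2),
                      peak_height_mean_nm = 9.0, peak_height_sd_nm = 0.9),
    paracrystal = list(pitch_mean_nm = 36.5, pitch_sd_struct_nm = 0,
                       peak_height_mean_nm = 8.6, peak_height_sd_nm = 0.8)
  )
}

#' Generator configuration
#'
#' Parameters of the synthetic HS-AFM movie generator. All defaults
#' reproduce the study conditions of the source measurements; see
#' `vignette("afm-filament-analysis")` for the rationale behind values that
#' are not pinned by published numbers.
#'
#' @param pixel_size_nm pixel size, nm (default 1.5, i.e. a 5x5 pixel search
#'   window spans 7.5 x 7.5 nm^2).
#' @param frame_interval_s time between frames, s (default 0.5 = 2 frames/s).
#' @param n_frames default number of frames simulated.
#' @param states per-state helical parameters, see [afm_default_states()].
#' @param localization_jitter_nm per-peak axial localization error SD
#'   (sigma_p). Default `3.0/sqrt(2)` so that a pitch — the difference of two
#'   independently jittered peak positions — carries a 3.0 nm error SD,
#'   matching the paracrystal calibration.
#' @param tip_radius_nm spherical tip radius used for grayscale dilation.
#' @param noise_sd_nm i.i.d. per-pixel height noise SD.
#' @param growth_bias_pointed probability beta that a cluster growth step is
#'   toward the pointed end.
#' @param growth_rate_per_s per-cluster growth rate (half helices per
#'   second).
#' @param severing_rates named per-category severing rates, per half helix
#'   per second; categories `far_bare`, `neighbor_bare`, `end_cluster`,
#'   `inner_cluster`.
#' @param orientation_phase_deg filament azimuth on the support. Mapped by a
#'   triangular wave to a constant axial offset of all apparent peaks in
#'   \[-2.5, +2.5\] nm (a uniformly distributed phase gives a uniformly
#'   distributed offset), emulating the orientation-dependent displacement of
#'   the apparent peak from the true crossover.
#' @param envelope_floor inter-peak height minimum as a fraction of the
#'   local peak height.
#' @param envelope_ref_pitch_nm fixed axial width of a rendered crossover
#'   bump (cosine main lobe of period twice this value, cross-faded to the
#'   substrate at this distance); default the mean bare pitch, 36.8 nm.
#'   Fixed — not pitch-scaled — widths keep every summit locally symmetric,
#'   as the subunit structure dictates.
#' @param margin_nm background margin around rendered filaments.
#' @param filament_spacing_nm center-to-center spacing of parallel filaments
#'   in multi-filament fields.
#' @param seed integer seed used when no explicit seed is handed to a
#'   generator call.
#' @return object of class `afm_config` (a validated named list).
#' @export
afm_config <- function(pixel_size_nm = 1.5,
                       frame_interval_s = 0.5,
                       n_frames = 10L,
                       states = afm_default_states(),
                       localization_jitter_nm = 3.0 / sqrt(2),
                       tip_radius_nm = 2.0,
                       noise_sd_nm = 0.15,
                       growth_bias_pointed = 0.8,
                       growth_rate_per_s = 0.1,
                       severing_rates = c(far_bare = 2e-5,
                                          neighbor_bare = 1.5e-3,
                                          end_cluster = 1.5e-3,
                                          inner_cluster = 1e-4),
                       orientation_phase_deg = 0,
                       envelope_floor = 0.65,
                       envelope_ref_pitch_nm = 36.8,
                       margin_nm = 15,
                       filament_spacing_nm = 12,
                       seed = 1L) {
  cfg <- structure(
    list(pixel_size_nm = pixel_size_nm,
         frame_interval_s = frame_interval_s,
         n_frames = as.integer(n_frames),
         states = states,
         localization_jitter_nm = localization_jitter_nm,
         tip_radius_nm = tip_radius_nm,
         noise_sd_nm = noise_sd_nm,
         growth_bias_pointed = growth_bias_pointed,
         growth_rate_per_s = growth_rate_per_s,
         severing_rates = severing_rates,
         orientation_phase_deg = orientation_phase_deg,
         envelope_floor = envelope_floor,
         envelope_ref_pitch_nm = envelope_ref_pitch_nm,
         margin_nm = margin_nm,
         filament_spacing_nm = filament_spacing_nm,
         seed = as.integer(seed)),
    class = "afm_config"
  )
  validate_afm_config(cfg)
}

validate_afm_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos <- c("pixel_size_nm", "frame_interval_s",
           "envelope_ref_pitch_nm", "margin_nm", "filament_spacing_nm")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number", p))
  }
  nonneg <- c("localization_jitter_nm", "noise_sd_nm", "growth_rate_per_s",
              "tip_radius_nm")
  for (p in nonneg) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("`%s` must be a single non-negative number", p))
  }
  b <- cfg$growth_bias_pointed
  if (!is.numeric(b) || length(b) != 1L || b < 0 || b > 1)
    stop("`growth_bias_pointed` must lie in [0, 1]")
  if (cfg$n_frames < 1L)
    stop("`n_frames` must be >= 1")
  f <- cfg$envelope_floor
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f >= 1)
    stop("`envelope_floor` must lie in [0, 1)")
  need <- c("far_bare", "neighbor_bare", "end_cluster", "inner_cluster")
  if (!all(need %in% names(cfg$severing_rates)))
    stop("`severing_rates` must name all four severing categories")
  if (any(cfg$severing_rates < 0))
    stop("severing rates must be non-negative")
  for (nm in names(cfg$states)) {
    st <- cfg$states[[nm]]
    if (st$pitch_mean_nm <= 0 || st$peak_height_mean_nm <= 0)
      stop(sprintf("state `%s`: means must be positive", nm))
    if (st$pitch_sd_struct_nm < 0 || st$peak_height_sd_nm < 0)
      stop(sprintf("state `%s`: SDs must be non-negative", nm))
  }
  if (!is.null(cfg$states$paracrystal) &&
      cfg$states$paracrystal$pitch_sd_struct_nm != 0)
    stop("the paracrystal state must have zero structural pitch SD")
  cfg
}

#' @export
print.afm_config <- function(x, ...) {
  cat(sprintf(paste0("<afm_config> px %.2f nm, dt %.2f s, jitter %.3f nm, ",
                     "tip %.1f nm, noise %.2f nm, beta %.2f\n"),
              x$pixel_size_nm, x$frame_interval_s, x$localization_jitter_nm,
              x$tip_radius_nm, x$noise_sd_nm, x$growth_bias_pointed))
  invisible(x)
}

# Triangular-wave mapping from filament azimuth to the constant axial offset
# of apparent peaks; amplitude 2.5 nm, so a uniform phase yields an offset
# uniform in [-2.5, 2.5] nm.
orientation_offset_nm <- function(phase_deg, amplitude_nm = 2.5) {
  amplitude_nm * (2 / pi) * asin(sin(phase_deg * pi / 180))
}
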