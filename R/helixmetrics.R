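#' Half-helical pitches from an ordered peak series
#'
#' Consecutive crossover peaks bound one half helix; its pitch is the arc
#' distance between them and its representative peak height is the mean of
#' the two bounding peak heights (the granularity at which decoration,
#' growth and severing are resolved).
#'
#' @param peaks data frame with strictly increasing `arc_nm` and
#'   `height_nm` (e.g. from [detect_peaks_along_trace()]).
#' @return data frame of half helices: `index`, `arc_start_nm`,
#'   `arc_end_nm`, `pitch_nm`, `mean_peak_height_nm`; zero rows when fewer
#'   than two peaks are supplied.
#' @export
half_pitches <- function(peaks) {
  stopifnot(all(c("arc_nm", "height_nm") %in% names(peaks)))
  n <- nrow(peaks)
  if (n < 2L)
    return(data.frame(index = integer(0), arc_start_nm = numeric(0),
                      arc_end_nm = numeric(0), pitch_nm = numeric(0),
                      mean_peak_height_nm = numeric(0)))
  if (any(diff(peaks$arc_nm) <= 0))
    stop("peak arc coordinates must be strictly increasing")
  data.frame(
    index = seq_len(n - 1L),
    arc_start_nm = peaks$arc_nm[-n],
    arc_end_nm = peaks$arc_nm[-1L],
    pitch_nm = diff(peaks$arc_nm),
    mean_peak_height_nm = (peaks$height_nm[-n] + peaks$height_nm[-1L]) / 2
  )
}

#' Summary of a measured distribution
#'
#' Sample statistics plus the Gaussian overlay used for histogram figures.
#' With a normal likelihood the ML location/scale coincide with the sample
#' mean and SD, so `gauss_mu`/`gauss_sigma` equal `mean`/`sd`; the display
#' fit range is mu +/- 3 sigma (the 99.73% band).
#'
#' @param values numeric vector, `n >= 2`.
#' @return object of class `afm_summary`: list with `n`, `mean`, `sd`,
#'   `gauss_mu`, `gauss_sigma`, `fit_range`, `min`, `max`.
#' @export
summarize_distribution <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("need at least 2 finite values")
  m <- mean(values); s <- stats::sd(values)
  structure(
    list(n = length(values), mean = m, sd = s,
         gauss_mu = m, gauss_sigma = s,
         fit_range = c(m - 3 * s, m + 3 * s),
         min = min(values), max = max(values)),
    class = "afm_summary"
  )
}

#' @export
print.afm_summary <- function(x, ...) {
  cat(sprintf("<afm_summary> n = %d, mean = %.1f, sd = %.1f, range [%.1f, %.1f]\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Subtract calibrated measurement variance
#'
#' Paracrystals suppress structural pitch variation, so their measured
#' pitch SD is the upper limit of the measurement error. Assuming normal,
#' independent true pitches and measurement errors, the structural SD of a
#' measured distribution is obtained by subtracting variances in
#' quadrature: `sd_true = sqrt(sd_obs^2 - sd_err^2)`. The decomposition is
#' undefined when `sd_obs < sd_err` (an imaginary root) and errors out.
#'
#' @param sd_obs observed SD (nm).
#' @param sd_err calibrated measurement-error SD (nm).
#' @return object of class `afm_error_decomposition`: list with `sd_obs`,
#'   `sd_err`, `sd_true`.
#' @export
subtract_measurement_variance <- function(sd_obs, sd_err) {
  if (!is.numeric(sd_obs) || !is.numeric(sd_err) ||
      length(sd_obs) != 1L || length(sd_err) != 1L)
    stop("`sd_obs` and `sd_err` must be single numbers")
  if (sd_obs < 0 || sd_err < 0)
    stop("standard deviations must be non-negative")
  if (sd_obs < sd_err)
    stop(sprintf(paste0("undefined decomposition: observed SD (%.3g) is ",
                        "smaller than the measurement-error SD (%.3g)"),
                 sd_obs, sd_err))
  structure(
    list(sd_obs = sd_obs, sd_err = sd_err,
         sd_true = sqrt(sd_obs^2 - sd_err^2)),
    class = "afm_error_decomposition"
  )
}

#' @export
print.afm_error_decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> sd_obs %.1f nm = sd_true %.1f (+) sd_err %.1f nm\n",
              x$sd_obs, x$sd_true, x$sd_err))
  invisible(x)
}

#' Supertwist ratio and percent pitch shortening
#'
#' Summary statistics of the cofilin-induced supertwist: the ratio of the
#' bare to the decorated mean half-helical pitch, and the percent
#' shortening. Reported at the conventional precision (ratio to 2
#' decimals, percent to the nearest integer); raw values are included so
#' the exact identity `percent = 100 (1 - 1/ratio)` stays checkable.
#'
#' @param mean_bare,mean_decorated mean pitches (nm), both > 0.
#' @return list with `ratio`, `percent_shortening` (rounded) and
#'   `ratio_raw`, `percent_raw`.
#' @export
supertwist_stats <- function(mean_bare, mean_decorated) {
  if (mean_bare <= 0 || mean_decorated <= 0)
    stop("mean pitches must be positive")
  ratio <- mean_bare / mean_decorated
  pct <- 100 * (mean_bare - mean_decorated) / mean_bare
  list(ratio = round(ratio, 2L), percent_shortening = round(pct),
       ratio_raw = ratio, percent_raw = pct)
}

#' Longer-to-shorter pitch ratio around a site
#'
#' Polarity-free asymmetry statistic for sparsely bound ligands: the pitch
#' on one side of a site divided by the pitch on the other, larger over
#' smaller, so the ratio is >= 1 by construction and needs no polarity
#' call. Symmetric filaments give ratios near 1; a supertwisted side
#' against a normal side gives about 36.8/26.9 = 1.37.
#'
#' @param left_pitch_nm,right_pitch_nm pitches flanking the site (nm).
#' @return ratio >= 1.
#' @export
pitch_ratio <- function(left_pitch_nm, right_pitch_nm) {
  if (any(c(left_pitch_nm, right_pitch_nm) <= 0))
    stop("pitches must be positive")
  pmax(left_pitch_nm, right_pitch_nm) / pmin(left_pitch_nm, right_pitch_nm)
}

#' Pitch ratio around a site on a peak series
#'
#' Snaps the site to its nearest crossover peak and compares the two
#' flanking half-helical pitches with [pitch_ratio()]. The flanking span
#' (number of half helices pooled per side) is configurable; with
#' `span = 1` the two immediately adjacent pitches are compared, larger
#' spans average over that many half helices per side.
#'
#' @param peaks data frame with strictly increasing `arc_nm`.
#' @param site_arc_nm arc coordinate of the site (nm).
#' @param span half helices pooled on each side (default 1).
#' @return ratio >= 1.
#' @export
pitch_ratio_around_site <- function(peaks, site_arc_nm, span = 1L) {
  stopifnot(nrow(peaks) >= 3L)
  if (any(diff(peaks$arc_nm) <= 0))
    stop("peak arc coordinates must be strictly increasing")
  span <- as.integer(span)
  i <- which.min(abs(peaks$arc_nm - site_arc_nm))
  if (i - span < 1L || i + span > nrow(peaks))
    stop("no measurable pitch on one side of the site")
  left <- (peaks$arc_nm[i] - peaks$arc_nm[i - span]) / span
  right <- (peaks$arc_nm[i + span] - peaks$arc_nm[i]) / span
  pitch_ratio(left, right)
}

#' Piecewise-constant substep fit of a peak-height track
#'
#' Cluster growth raises a crossover peak from the bare (~8.6 nm) to the
#' decorated (~10.6 nm) level, sometimes via an intermediate plateau when
#' the two strands are decorated with a lag. This fits piecewise-constant
#' models with 0, 1 or 2 steps by exhaustive changepoint search
#' (least squares) and selects among them with the Bayesian information
#' criterion; parameters counted are the segment levels plus the
#' changepoints.
#'
#' @param heights numeric vector of peak heights over frames (>= 8).
#' @param times optional timestamps, same length; frame indices if `NULL`.
#' @param min_segment minimum frames per segment.
#' @return list: `n_steps` (0, 1 or 2), `step_index` (first frame of each
#'   new level), `step_times`, `levels` (per-segment means), `bic`
#'   (named vector for the three models).
#' @export
rise_substep_fit <- function(heights, times = NULL, min_segment = 3L) {
  n <- length(heights)
  if (n < 8L) stop("track too short: need >= 8 frames")
  if (is.null(times)) times <- seq_len(n)
  stopifnot(length(times) == n)
  ms <- as.integer(min_segment)

  cs <- cumsum(heights); cs2 <- cumsum(heights^2)
  seg_rss <- function(a, b) { # inclusive indices
    s <- cs[b] - if (a > 1L) cs[a - 1L] else 0
    s2 <- cs2[b] - if (a > 1L) cs2[a - 1L] else 0
    s2 - s^2 / (b - a + 1L)
  }

  rss0 <- seg_rss(1L, n)
  best1 <- list(rss = Inf, cp = integer(0))
  if (n >= 2L * ms) {
    for (c1 in (ms + 1L):(n - ms + 1L)) {
      r <- seg_rss(1L, c1 - 1L) + seg_rss(c1, n)
      if (r < best1$rss) best1 <- list(rss = r, cp = c1)
    }
  }
  best2 <- list(rss = Inf, cp = integer(0))
  if (n >= 3L * ms) {
    for (c1 in (ms + 1L):(n - 2L * ms + 1L)) {
      r1 <- seg_rss(1L, c1 - 1L)
      for (c2 in (c1 + ms):(n - ms + 1L)) {
        r <- r1 + seg_rss(c1, c2 - 1L) + seg_rss(c2, n)
        if (r < best2$rss) best2 <- list(rss = r, cp = c(c1, c2))
      }
    }
  }

  # BIC with gaussian errors; k segments-1 changepoints + k levels
  bic <- function(rss, k_steps) {
    rss <- max(rss, 1e-12)
    n * log(rss / n) + (2L * k_steps + 1L) * log(n)
  }
  bics <- c(`0` = bic(rss0, 0L),
            `1` = if (is.finite(best1$rss)) bic(best1$rss, 1L) else Inf,
            `2` = if (is.finite(best2$rss)) bic(best2$rss, 2L) else Inf)
  k <- as.integer(names(which.min(bics)))
  cp <- switch(as.character(k), `0` = integer(0), `1` = best1$cp,
               `2` = best2$cp)
  bounds <- c(1L, cp, n + 1L)
  levels <- vapply(seq_len(k + 1L), function(j)
    mean(heights[bounds[j]:(bounds[j + 1L] - 1L)]), numeric(1))
  list(n_steps = k, step_index = cp, step_times = times[cp],
       levels = levels, bic = bics)
}
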