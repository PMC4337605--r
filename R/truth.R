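#' Match detected peaks to ground-truth crossovers
#'
#' Traced arc coordinates have an arbitrary origin and direction, so
#' validation against generator ground truth goes through xy positions:
#' each detected peak is assigned the nearest true crossover of one
#' rendered filament. The assignment also yields the trace orientation
#' relative to the model's polarity.
#'
#' @param peaks data frame of detected peaks (`x_nm`, `y_nm`, `arc_nm`).
#' @param truth one element of a frame's `"truth"` attribute (see
#'   [render_frame()]).
#' @return `peaks` with columns added: `true_index` (crossover number,
#'   1-based from the pointed end), `true_arc_nm`, `match_dist_nm`
#'   (planar distance to the matched crossover), plus attribute
#'   `orientation` (`1` if the trace runs pointed-to-barbed, `-1` if
#'   reversed, `NA` if undetermined) and attribute `aligned` (`TRUE` when
#'   the match is a clean one-to-one, consecutive assignment).
#' @export
match_peaks_to_truth <- function(peaks, truth) {
  stopifnot(all(c("x_nm", "y_nm", "arc_nm") %in% names(peaks)))
  txy <- truth$peak_xy_true
  n <- nrow(peaks)
  idx <- integer(n); dist <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (txy[, 1L] - peaks$x_nm[i])^2 + (txy[, 2L] - peaks$y_nm[i])^2
    idx[i] <- which.min(d2)
    dist[i] <- sqrt(min(d2))
  }
  peaks$true_index <- idx
  peaks$true_arc_nm <- truth$arcs_true_nm[idx]
  peaks$match_dist_nm <- dist
  dd <- diff(idx)
  orientation <- if (all(dd == 1L)) 1L else if (all(dd == -1L)) -1L
  else NA_integer_
  attr(peaks, "orientation") <- orientation
  attr(peaks, "aligned") <- !anyNA(orientation) && !anyDuplicated(idx) &&
    n == length(truth$arcs_true_nm)
  peaks
}

#' Measured half helices annotated with ground-truth states
#'
#' Builds the half-helix table from detected peaks and attaches, for each
#' measured half helix, the generator's true state, true pitch and global
#' index, via [match_peaks_to_truth()]. A measured half helix is kept
#' only when its two bounding peaks matched *consecutive* true crossovers
#' (each within `max_dist_nm`), so an occasional missed or spurious
#' detection drops the affected half helices instead of contaminating
#' the statistics or discarding the whole filament; the `aligned`
#' attribute reports whether the filament matched one-to-one throughout.
#'
#' Polarity is resolved from the match orientation: the returned table is
#' ordered with index 1 at the pointed end regardless of the trace
#' direction.
#'
#' @param peaks detected peaks of one filament in one frame.
#' @param truth the matching truth entry.
#' @param max_dist_nm maximum planar distance between a detected peak and
#'   its matched crossover (default half the shortest reported pitch).
#' @return half-helix data frame with `state_true`, `pitch_true_nm`,
#'   `global_index` columns, ordered pointed-to-barbed, or `NULL` when
#'   nothing matched.
#' @export
half_pitches_with_truth <- function(peaks, truth, max_dist_nm = 13) {
  m <- match_peaks_to_truth(peaks, truth)
  if (nrow(m) < 2L) return(NULL)
  dd <- diff(m$true_index)
  if (sum(dd > 0) < sum(dd < 0)) {  # majority orientation: reverse trace
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    m$arc_nm <- max(m$arc_nm) - m$arc_nm
  }
  good_pair <- diff(m$true_index) == 1L &
    m$match_dist_nm[-nrow(m)] <= max_dist_nm &
    m$match_dist_nm[-1L] <= max_dist_nm
  if (!any(good_pair)) return(NULL)
  hh <- half_pitches(m)
  k <- m$true_index[-nrow(m)]  # pointed-side crossover of each half helix
  hh$global_index <- truth$global_index[k]
  hh$state_true <- truth$states[k]
  hh$pitch_true_nm <- truth$pitch_true_nm[k]
  hh <- hh[good_pair, , drop = FALSE]
  rownames(hh) <- NULL
  attr(hh, "aligned") <- isTRUE(attr(m, "aligned"))
  hh
}

#' Reconstruct a complete half-helix table from partial measurements
#'
#' Expands a truth-annotated measurement table (from
#' [half_pitches_with_truth()]) to one row per true half helix, with `NA`
#' pitch/height where the measurement is missing and the true state
#' everywhere — the layout [neighbor_pitch_table()] consumes, which
#' excludes `NA` entries from its pools.
#'
#' @param hh output of [half_pitches_with_truth()] for one filament.
#' @param truth the matching truth entry.
#' @return data frame with one row per half helix of the true filament.
#' @export
complete_half_helix_table <- function(hh, truth) {
  n <- length(truth$global_index)
  out <- data.frame(
    global_index = truth$global_index,
    state = ifelse(truth$states == "decorated", "decorated", "bare"),
    state_true = truth$states,
    pitch_true_nm = truth$pitch_true_nm,
    pitch_nm = NA_real_,
    mean_peak_height_nm = NA_real_
  )
  if (!is.null(hh) && nrow(hh)) {
    i <- match(hh$global_index, out$global_index)
    out$pitch_nm[i] <- hh$pitch_nm
    out$mean_peak_height_nm[i] <- hh$mean_peak_height_nm
  }
  out
}
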