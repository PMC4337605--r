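#' Build a ground-truth filament model
#'
#' Draws the structural state of one filament: an ordered run of half
#' helices (index 1 = pointed end), each with a true pitch and a true peak
#' height sampled from its state's distributions. Decorated (cofilin-bound)
#' intervals are given explicitly; the single bare half helix immediately on
#' the pointed-end side of each decorated run automatically becomes a
#' `p_neighbor` (short, supertwisted pitch) and the one on the barbed side a
#' `b_neighbor` (slightly overlong pitch) — the asymmetric boundary
#' conformation. Structural variation is sampled here; measurement error
#' (localization jitter, tip dilation, pixel noise) is added only at render
#' time.
#'
#' Pitches are drawn from per-state normals truncated at > 10 nm (more than
#' 8 SD below every state mean; guards against non-physical draws).
#'
#' @param config an [afm_config()].
#' @param n_half_helices number of half helices (>= 1).
#' @param cluster_spec list of decorated intervals, each `c(first, last)`
#'   (1-based, inclusive). Intervals must be in range, non-overlapping and
#'   separated by at least 2 bare half helices so boundary states are
#'   unambiguous.
#' @param state default state for unclustered half helices (`"bare"`, or
#'   `"paracrystal"` for calibration fields).
#' @param origin_nm physical position of the pointed-end terminal crossover;
#'   assigned at render time when `NULL`.
#' @param angle_deg filament axis direction in the xy plane.
#' @param curvature_per_nm signed curvature of the backbone (0 = straight).
#' @return object of class `afm_filament_model`.
#' @export
build_filament_model <- function(config, n_half_helices,
                                 cluster_spec = list(),
                                 state = "bare",
                                 origin_nm = NULL,
                                 angle_deg = 0,
                                 curvature_per_nm = 0) {
  config <- validate_afm_config(config)
  n <- as.integer(n_half_helices)
  if (is.na(n) || n < 1L)
    stop("`n_half_helices` must be >= 1")
  if (!state %in% names(config$states))
    stop(sprintf("unknown state `%s`", state))

  states <- rep(state, n)
  if (length(cluster_spec)) {
    iv <- do.call(rbind, lapply(cluster_spec, function(x) {
      if (length(x) != 2L) stop("each cluster interval must be c(first, last)")
      as.integer(x)
    }))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[, 1L] > iv[, 2L]))
      stop("cluster intervals must have first <= last")
    if (any(iv < 1L) || any(iv > n))
      stop("cluster intervals out of range")
    if (nrow(iv) > 1L && any(iv[-1L, 1L] - iv[-nrow(iv), 2L] <= 2L))
      stop("cluster intervals must be non-overlapping and separated by >= 2 bare half helices")
    for (k in seq_len(nrow(iv))) {
      states[iv[k, 1L]:iv[k, 2L]] <- "decorated"
      if (iv[k, 1L] > 1L) states[iv[k, 1L] - 1L] <- "p_neighbor"
      if (iv[k, 2L] < n) states[iv[k, 2L] + 1L] <- "b_neighbor"
    }
  }

  pitches <- heights <- numeric(n)
  for (s in unique(states)) {
    idx <- which(states == s)
    st <- config$states[[s]]
    pitches[idx] <- rnorm_trunc(length(idx), st$pitch_mean_nm,
                                st$pitch_sd_struct_nm, lower = 10)
    heights[idx] <- rnorm_trunc(length(idx), st$peak_height_mean_nm,
                                st$peak_height_sd_nm, lower = 1)
  }

  structure(
    list(half_helices = data.frame(index = seq_len(n),
                                   state = states,
                                   pitch_true_nm = pitches,
                                   peak_height_true_nm = heights,
                                   stringsAsFactors = FALSE),
         polarity = "pointed_at_start",
         global_index = seq_len(n),
         arc_offset_nm = 0,
         severed_ends = c(start = FALSE, end = FALSE),
         row_id = 1L,  # raster row slot; fragments of one filament share it
         origin_nm = origin_nm,
         angle_deg = angle_deg,
         curvature_per_nm = curvature_per_nm),
    class = "afm_filament_model"
  )
}

#' @export
print.afm_filament_model <- function(x, ...) {
  st <- table(x$half_helices$state)
  cat(sprintf("<afm_filament_model> %d half helices (%s), length %.1f nm\n",
              nrow(x$half_helices),
              paste(names(st), st, sep = ":", collapse = ", "),
              sum(x$half_helices$pitch_true_nm)))
  invisible(x)
}

# normal draws truncated below at `lower` (rejection; tails are ~8 SD away
# from every default mean so resampling is rare)
rnorm_trunc <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean <= lower) stop("degenerate truncated draw below the bound")
    return(rep(mean, n))
  }
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated sampling failed to converge")
  }
  x
}

#' True crossover arc coordinates of a model
#'
#' Crossover (peak) `k` bounds half helices `k - 1` and `k`; there are
#' `n + 1` crossovers for `n` half helices. Arc 0 is the pointed-end
#' terminal crossover of the original, unsevered filament, so fragment
#' models keep their global coordinates via `arc_offset_nm`.
#'
#' @param model an `afm_filament_model`.
#' @return numeric vector of arc positions (nm).
#' @export
model_peak_arcs <- function(model) {
  model$arc_offset_nm + c(0, cumsum(model$half_helices$pitch_true_nm))
}

#' True crossover peak heights of a model
#'
#' A crossover is shared by its two flanking half helices; its true height
#' is the mean of the two per-half-helix height draws (terminal crossovers
#' take the single flanking draw). Cluster-boundary crossovers therefore
#' come out intermediate between the bare and decorated modes.
#'
#' @param model an `afm_filament_model`.
#' @return numeric vector of `n + 1` peak heights (nm).
#' @export
model_peak_heights <- function(model) {
  h <- model$half_helices$peak_height_true_nm
  n <- length(h)
  if (n == 1L) return(c(h, h))
  c(h[1L], (h[-n] + h[-1L]) / 2, h[n])
}
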