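#' Trace a filament backbone from a seed point
#'
#' Ridge-following centerline tracer. Starting from a seed on the filament,
#' the tracer marches in 1-pixel steps along the local ridge direction; at
#' each step the position is re-centered laterally on the height-weighted
#' centroid of nearby above-floor pixels (weights `height - floor`), which
#' keeps the polyline on the crest without being attracted to neighboring
#' filaments. Marching runs from the seed toward both ends and stops where
#' the interpolated height drops below `height_floor_nm`. The combined
#' polyline is resampled at 1-pixel arc steps.
#'
#' @param frame an `afm_frame` (preprocessed).
#' @param seed_xy_nm numeric length-2, physical seed position (nm); must lie
#'   on a pixel above the floor.
#' @param height_floor_nm minimum height regarded as filament (nm).
#' @param band_radius_px lateral re-centering radius in pixels.
#' @param polarity optional polarity annotation
#'   (`"pointed_at_start"`, `"pointed_at_end"`, `"unknown"`).
#' @return object of class `afm_trace`: a data frame with columns
#'   `x_nm`, `y_nm`, `arc_nm` (strictly increasing cumulative arc length)
#'   and a `polarity` attribute.
#' @export
trace_backbone <- function(frame, seed_xy_nm, height_floor_nm = 4.0,
                           band_radius_px = 3, polarity = "unknown") {
  stopifnot(inherits(frame, "afm_frame"))
  px <- frame$pixel_size_nm
  g <- frame$grid
  if (frame_height_at(frame, seed_xy_nm[1L], seed_xy_nm[2L]) < height_floor_nm)
    stop("seed point lies below the height floor (background)")

  rb <- band_radius_px * px
  centroid_near <- function(p) {
    # height-weighted centroid of above-floor pixels within `rb` of p
    i0 <- max(1L, floor((p[2L] - rb) / px) + 1L)
    i1 <- min(nrow(g), ceiling((p[2L] + rb) / px) + 1L)
    j0 <- max(1L, floor((p[1L] - rb) / px) + 1L)
    j1 <- min(ncol(g), ceiling((p[1L] + rb) / px) + 1L)
    ii <- i0:i1; jj <- j0:j1
    sub <- g[ii, jj, drop = FALSE]
    xs <- (jj - 1L) * px; ys <- (ii - 1L) * px
    d2 <- outer((ys - p[2L])^2, (xs - p[1L])^2, "+")
    w <- sub - height_floor_nm
    w[w < 0 | d2 > rb^2] <- 0
    sw <- sum(w)
    if (sw <= 0) return(NULL)
    c(sum(w * rep(xs, each = length(ii))) / sw,
      sum(w * rep(ys, times = length(jj))) / sw)
  }

  # initial tangent from the height-weighted covariance around the seed
  init_dir <- function(p) {
    r2 <- 5 * px
    i0 <- max(1L, floor((p[2L] - r2) / px) + 1L)
    i1 <- min(nrow(g), ceiling((p[2L] + r2) / px) + 1L)
    j0 <- max(1L, floor((p[1L] - r2) / px) + 1L)
    j1 <- min(ncol(g), ceiling((p[1L] + r2) / px) + 1L)
    ii <- i0:i1; jj <- j0:j1
    sub <- g[ii, jj, drop = FALSE]
    w <- pmax(sub - height_floor_nm, 0)
    if (sum(w) <= 0) stop("no filament pixels near the seed")
    xs <- rep((jj - 1L) * px, each = length(ii))
    ys <- rep((ii - 1L) * px, times = length(jj))
    mx <- sum(w * xs) / sum(w); my <- sum(w * ys) / sum(w)
    cv <- matrix(c(sum(w * (xs - mx)^2), sum(w * (xs - mx) * (ys - my)),
                   sum(w * (xs - mx) * (ys - my)), sum(w * (ys - my)^2)),
                 2L, 2L) / sum(w)
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
    ev / sqrt(sum(ev^2))
  }

  start <- centroid_near(seed_xy_nm)
  if (is.null(start)) stop("no filament pixels near the seed")
  tan0 <- init_dir(start)

  march <- function(p0, dir) {
    pts <- list()
    p <- p0; tn <- dir
    max_steps <- nrow(g) + ncol(g) + 64L
    for (step in seq_len(max_steps)) {
      cand <- p + tn * px
      if (cand[1L] < 0 || cand[2L] < 0 ||
          cand[1L] > (ncol(g) - 1L) * px || cand[2L] > (nrow(g) - 1L) * px)
        break
      if (frame_height_at(frame, cand[1L], cand[2L]) < height_floor_nm)
        break
      ctr <- centroid_near(cand)
      if (is.null(ctr)) break
      # lateral correction only: keep the axial advance, recenter crosswise
      lat <- (ctr - cand) - sum((ctr - cand) * tn) * tn
      newp <- cand + lat
      stepv <- newp - p
      ns <- sqrt(sum(stepv^2))
      if (ns < px / 4) break
      tn <- 0.7 * tn + 0.3 * stepv / ns
      tn <- tn / sqrt(sum(tn^2))
      pts[[step]] <- newp
      p <- newp
    }
    if (length(pts)) do.call(rbind, pts) else NULL
  }

  fwd <- march(start, tan0)
  bwd <- march(start, -tan0)
  pts <- rbind(if (!is.null(bwd)) bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(start, 1L), fwd)
  if (nrow(pts) < 2L)
    stop("traced region too short (need at least 2 points)")

  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  # resample at 1-px arc steps
  s_out <- seq(0, arc[length(arc)], by = px)
  tr <- data.frame(
    x_nm = stats::approx(arc, pts[, 1L], xout = s_out)$y,
    y_nm = stats::approx(arc, pts[, 2L], xout = s_out)$y,
    arc_nm = s_out
  )
  structure(tr, class = c("afm_trace", "data.frame"), polarity = polarity)
}

#' Refine a crossover peak position by center of mass
#'
#' The semi-automatic peak refinement: (1) the highest pixel within the
#' `window_px` x `window_px` window centered on the approximate point is
#' located (ties broken toward the smallest row, then column index);
#' (2) the position is replaced by the height-weighted center of mass of
#' the `window_px` x `window_px` window around that maximum, with weights
#' `height - window minimum` so the estimate is invariant under height
#' offsets; (3) the reported height is the bilinearly interpolated height
#' at the refined position (`height_mode = "interpolated"`, default) or
#' the maximum-pixel height (`"max_pixel"`).
#'
#' @param frame an `afm_frame`.
#' @param approx_xy_nm numeric length-2 approximate peak position (nm).
#' @param window_px odd window edge (default 5, i.e. 7.5 x 7.5 nm^2 at
#'   1.5 nm/px).
#' @param height_mode `"interpolated"` or `"max_pixel"`.
#' @return one-row data frame: `x_nm`, `y_nm`, `height_nm`, `degenerate`
#'   (`TRUE` when the window was flat and the tie-break pixel was
#'   returned).
#' @export
refine_peak <- function(frame, approx_xy_nm, window_px = 5L,
                        height_mode = c("interpolated", "max_pixel")) {
  stopifnot(inherits(frame, "afm_frame"))
  height_mode <- match.arg(height_mode)
  w <- as.integer(window_px)
  if (w < 3L || w %% 2L == 0L) stop("`window_px` must be odd and >= 3")
  h <- (w - 1L) %/% 2L
  g <- frame$grid
  px <- frame$pixel_size_nm
  jc <- round(approx_xy_nm[1L] / px) + 1L
  ic <- round(approx_xy_nm[2L] / px) + 1L
  if (ic - h < 1L || ic + h > nrow(g) || jc - h < 1L || jc + h > ncol(g))
    stop("search window does not fit inside the frame")

  sub <- g[(ic - h):(ic + h), (jc - h):(jc + h), drop = FALSE]
  mx <- max(sub)
  cand <- which(sub == mx)
  ai <- arrayInd(cand, dim(sub))
  pick <- order(ai[, 1L], ai[, 2L])[1L]
  im <- ai[pick, 1L] + ic - h - 1L
  jm <- ai[pick, 2L] + jc - h - 1L
  if (im - h < 1L || im + h > nrow(g) || jm - h < 1L || jm + h > ncol(g))
    stop("center-of-mass window does not fit inside the frame")

  win <- g[(im - h):(im + h), (jm - h):(jm + h), drop = FALSE]
  wts <- win - min(win)
  degenerate <- sum(wts) <= 0
  if (degenerate) {
    x <- (jm - 1L) * px; y <- (im - 1L) * px
  } else {
    xs <- ((jm - h):(jm + h) - 1L) * px
    ys <- ((im - h):(im + h) - 1L) * px
    x <- sum(wts * rep(xs, each = w)) / sum(wts)
    y <- sum(wts * rep(ys, times = w)) / sum(wts)
  }
  ht <- if (height_mode == "interpolated" && !degenerate)
    frame_height_at(frame, x, y) else g[im, jm]
  data.frame(x_nm = x, y_nm = y, height_nm = ht, degenerate = degenerate)
}

#' Detect crossover peaks along a traced backbone
#'
#' Automates the per-half-helix peak picking: the height profile sampled
#' along the trace is scanned for local maxima above the floor, maxima
#' closer than `min_separation_nm` along the arc are suppressed (highest
#' kept), and each surviving maximum is refined with [refine_peak()]. The
#' default separation of 15 nm is about half the shortest reported pitch
#' (26.9 nm) minus a margin, so even supertwisted crossovers are resolved.
#'
#' @param frame an `afm_frame`.
#' @param trace an `afm_trace` from [trace_backbone()].
#' @param min_separation_nm minimum arc separation between peaks.
#' @param height_floor_nm minimum peak height considered.
#' @param min_prominence_nm minimum topographic prominence of a candidate
#'   above the deepest saddle separating it from a higher profile point,
#'   evaluated on a lightly smoothed (3-sample moving average) profile;
#'   rejects noise wrinkles on the inter-crossover envelope (prominence ~
#'   pixel noise) while keeping even weak boundary crossovers, which rise
#'   at least ~1 nm above their valleys.
#' @param window_px refinement window, see [refine_peak()].
#' @param height_mode see [refine_peak()].
#' @return data frame of peak records ordered by arc coordinate:
#'   `x_nm`, `y_nm`, `arc_nm`, `height_nm`, `degenerate`.
#' @export
detect_peaks_along_trace <- function(frame, trace, min_separation_nm = 15,
                                     height_floor_nm = 4.0,
                                     min_prominence_nm = 0.6,
                                     window_px = 5L,
                                     height_mode = "interpolated") {
  stopifnot(inherits(frame, "afm_frame"), inherits(trace, "afm_trace"))
  prof <- frame_height_at(frame, trace$x_nm, trace$y_nm)
  n <- length(prof)
  if (n < 3L) return(empty_peaks())
  # candidates come from a lightly smoothed profile; refinement below uses
  # the raw frame
  sm <- as.numeric(stats::filter(prof, rep(1 / 3, 3L), sides = 2L))
  sm[c(1L, n)] <- prof[c(1L, n)]
  is_max <- c(FALSE, sm[2:(n - 1L)] > sm[1:(n - 2L)] &
                sm[2:(n - 1L)] >= sm[3:n], FALSE) &
    sm >= height_floor_nm
  idx <- which(is_max)
  if (!length(idx)) return(empty_peaks())
  prom <- vapply(idx, function(i) profile_prominence(sm, i), numeric(1))
  idx <- idx[prom >= min_prominence_nm]
  if (!length(idx)) return(empty_peaks())
  # greedy non-maximum suppression by height
  idx <- idx[order(sm[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in idx) {
    if (!length(kept) ||
        all(abs(trace$arc_nm[i] - trace$arc_nm[kept]) >= min_separation_nm))
      kept <- c(kept, i)
  }
  kept <- sort(kept)

  out <- lapply(kept, function(i) {
    pk <- tryCatch(
      refine_peak(frame, c(trace$x_nm[i], trace$y_nm[i]),
                  window_px = window_px, height_mode = height_mode),
      error = function(e) NULL)
    if (is.null(pk)) return(NULL)
    pk$arc_nm <- project_to_trace(trace, c(pk$x_nm, pk$y_nm), i)
    pk
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) return(empty_peaks())
  out <- out[order(out$arc_nm), , drop = FALSE]
  # refinement can merge neighbors; suppress again, keeping the higher
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1L]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (out$arc_nm[i] - out$arc_nm[prev] < min_separation_nm) {
      if (out$height_nm[i] > out$height_nm[prev]) keep[prev] <- FALSE
      else keep[i] <- FALSE
    }
  }
  out <- out[keep, c("x_nm", "y_nm", "arc_nm", "height_nm", "degenerate")]
  rownames(out) <- NULL
  out
}

# Topographic prominence of profile point i: height above the higher of
# the two deepest saddles toward the nearest higher profile point on each
# side (profile minimum on sides with no higher point).
profile_prominence <- function(prof, i) {
  h <- prof[i]
  left <- prof[seq_len(i - 1L)]
  right <- prof[seq.int(i + 1L, length(prof))]
  saddle <- -Inf
  hl <- which(left > h)
  if (length(hl)) saddle <- max(saddle, min(left[(max(hl) + 1L):(i - 1L)]))
  hr <- which(right > h)
  if (length(hr)) saddle <- max(saddle, min(right[seq_len(min(hr) - 1L)]))
  if (!is.finite(saddle)) saddle <- min(prof)
  h - saddle
}

empty_peaks <- function() {
  data.frame(x_nm = numeric(0), y_nm = numeric(0), arc_nm = numeric(0),
             height_nm = numeric(0), degenerate = logical(0))
}

# Arc coordinate of a point: its projection on the trace near vertex i.
project_to_trace <- function(trace, p, i) {
  n <- nrow(trace)
  i2 <- min(i, n - 1L)
  t_vec <- c(trace$x_nm[i2 + 1L] - trace$x_nm[i2],
             trace$y_nm[i2 + 1L] - trace$y_nm[i2])
  tl <- sqrt(sum(t_vec^2))
  if (tl == 0) return(trace$arc_nm[i])
  t_hat <- t_vec / tl
  trace$arc_nm[i2] +
    sum((p - c(trace$x_nm[i2], trace$y_nm[i2])) * t_hat)
}

#' Link peaks across frames into tracks
#'
#' Greedy nearest-neighbor assignment between consecutive frames: closest
#' pairs (in the xy plane) are matched first, pairs farther apart than
#' `max_displacement_nm` are never matched, and unmatched peaks start new
#' tracks. Suited to lipid-bilayer-immobilized filaments, where crossover
#' peaks move by at most a few nm per frame; a peak jumping farther than
#' the cutoff (e.g. two peaks swapping places) terminates both tracks
#' rather than teleporting an assignment.
#'
#' @param peaks data frame of peak records with columns `frame`, `x_nm`,
#'   `y_nm`, `height_nm` (e.g. rbind of per-frame
#'   [detect_peaks_along_trace()] outputs with a `frame` column added), or
#'   a list of per-frame data frames.
#' @param max_displacement_nm maximum frame-to-frame displacement.
#' @return the input peaks as one data frame with an integer `track_id`
#'   column; tracks are time-ordered within id.
#' @export
link_peaks <- function(peaks, max_displacement_nm = 10) {
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- do.call(rbind, lapply(seq_along(peaks), function(f) {
      p <- peaks[[f]]
      if (!nrow(p)) return(NULL)
      p$frame <- f
      p
    }))
  }
  if (is.null(peaks) || !nrow(peaks)) {
    peaks <- empty_peaks(); peaks$frame <- integer(0)
    peaks$track_id <- integer(0)
    return(peaks)
  }
  stopifnot(all(c("frame", "x_nm", "y_nm") %in% names(peaks)))
  peaks <- peaks[order(peaks$frame), , drop = FALSE]
  peaks$track_id <- NA_integer_
  frames <- sort(unique(peaks$frame))
  next_id <- 1L
  prev_idx <- integer(0)
  for (f in frames) {
    cur_idx <- which(peaks$frame == f)
    if (length(prev_idx)) {
      d <- outer(seq_along(prev_idx), seq_along(cur_idx),
                 Vectorize(function(a, b) {
                   sqrt((peaks$x_nm[prev_idx[a]] - peaks$x_nm[cur_idx[b]])^2 +
                          (peaks$y_nm[prev_idx[a]] - peaks$y_nm[cur_idx[b]])^2)
                 }))
      repeat {
        m <- which.min(d)
        if (!length(m) || d[m] > max_displacement_nm || !is.finite(d[m]))
          break
        a <- ((m - 1L) %% nrow(d)) + 1L
        b <- ((m - 1L) %/% nrow(d)) + 1L
        peaks$track_id[cur_idx[b]] <- peaks$track_id[prev_idx[a]]
        d[a, ] <- Inf; d[, b] <- Inf
      }
    }
    new <- cur_idx[is.na(peaks$track_id[cur_idx])]
    if (length(new)) {
      peaks$track_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  rownames(peaks) <- NULL
  peaks
}
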