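#' Render filament models into a synthetic AFM height frame
#'
#' Renders one or more ground-truth filament models into a calibrated
#' height raster the way a tapping-mode AFM would image them:
#'
#' 1. The height profile along the backbone is a periodic envelope peaking
#'    at the crossovers of the two-start helix (cosine of period twice the
#'    local pitch, inter-peak minimum `envelope_floor` of the local peak
#'    height), tapering to the substrate over `cap_length_nm` beyond the
#'    terminal crossovers.
#' 2. Apparent peak positions are the true crossover arcs shifted by one
#'    orientation-dependent axial offset per filament (see
#'    [afm_config()]`$orientation_phase_deg`) plus independent per-peak
#'    localization jitter of SD `localization_jitter_nm` — the two
#'    measurement-error sources the paracrystal calibration quantifies.
#' 3. The filament cross-section is a cylinder lying on the substrate
#'    (apex height equals the envelope height).
#' 4. The surface is dilated by a spherical tip of `tip_radius_nm`
#'    (grayscale dilation: summit heights are preserved, widths broaden).
#' 5. I.i.d. normal pixel noise of SD `noise_sd_nm` is added; the
#'    background is 0 nm.
#'
#' Rendering is deterministic given `(models, config, seed)`.
#'
#' @param models a single `afm_filament_model` or a list of them. Multiple
#'   models are laid out as parallel filaments spaced
#'   `filament_spacing_nm` apart; models with `angle_deg != 0` or nonzero
#'   curvature must be rendered singly.
#' @param config an [afm_config()].
#' @param seed integer seed for jitter and pixel noise; `config$seed` when
#'   `NULL`.
#' @param t_s timestamp stored in the frame.
#' @return An `afm_frame` whose `"truth"` attribute holds, per model, the
#'   true and apparent crossover arcs, true peak heights and world
#'   positions, states, polarity and a backbone polyline.
#' @export
render_frame <- function(models, config, seed = NULL, t_s = 0) {
  config <- validate_afm_config(config)
  if (inherits(models, "afm_filament_model")) models <- list(models)
  if (!length(models) || !all(vapply(models, inherits, logical(1),
                                     "afm_filament_model")))
    stop("`models` must be one or more afm_filament_model objects")
  if (is.null(seed)) seed <- config$seed
  set.seed(as.integer(seed))

  px <- config$pixel_size_nm
  margin <- config$margin_nm
  ref <- config$envelope_ref_pitch_nm
  maxh <- max(vapply(models, function(m)
    max(m$half_helices$peak_height_true_nm), numeric(1)))
  if (margin < config$tip_radius_nm + maxh / 2 + 2)
    stop("raster too small: `margin_nm` must exceed the tip radius plus the filament half-width")

  bent <- vapply(models, function(m)
    m$angle_deg != 0 || m$curvature_per_nm != 0, logical(1))
  if (any(bent) && length(models) > 1L)
    stop("curved or rotated models must be rendered singly")

  smin <- min(vapply(models, function(m) m$arc_offset_nm, numeric(1)))
  smax <- max(vapply(models, function(m)
    m$arc_offset_nm + sum(m$half_helices$pitch_true_nm), numeric(1)))
  ext <- end_extension_nm(config)
  x_axis_origin <- margin + ext - smin  # world x of arc coordinate 0

  if (!any(bent)) {
    rows <- vapply(models, function(m) as.integer(m$row_id), integer(1))
    nx <- ceiling((2 * margin + 2 * ext + (smax - smin)) / px) + 1L
    ny <- ceiling((2 * margin + (max(rows) - 1L) *
                     config$filament_spacing_nm) / px) + 1L
    y_pos <- margin + (rows - 1L) * config$filament_spacing_nm
  } else {
    # bounding box of the curved backbone plus margins
    m <- models[[1L]]
    ss <- seq(m$arc_offset_nm - ext,
              m$arc_offset_nm + sum(m$half_helices$pitch_true_nm) + ext,
              by = px / 2)
    pts <- backbone_xy(m, ss, origin = c(0, 0))
    nx <- ceiling((diff(range(pts[, 1L])) + 2 * margin) / px) + 1L
    ny <- ceiling((diff(range(pts[, 2L])) + 2 * margin) / px) + 1L
    y_pos <- margin - min(pts[, 2L])
    x_axis_origin <- margin - min(pts[, 1L])
  }

  grid <- matrix(0, nrow = ny, ncol = nx)
  xv <- (seq_len(nx) - 1L) * px
  yv <- (seq_len(ny) - 1L) * px
  offset <- orientation_offset_nm(config$orientation_phase_deg)

  truth <- vector("list", length(models))
  for (k in seq_along(models)) {
    m <- models[[k]]
    arcs <- model_peak_arcs(m)
    jitter <- stats::rnorm(length(arcs), 0, config$localization_jitter_nm)
    apparent <- sort(arcs + offset + jitter)
    hts <- model_peak_heights(m)
    env <- make_axial_envelope(apparent, hts, config$envelope_floor, ref,
                               severed = m$severed_ends)

    if (!bent[k]) {
      y0 <- y_pos[k]
      grid <- add_straight_filament(grid, xv, yv, x_axis_origin, y0, env)
      pk_xy <- cbind(x_axis_origin + arcs, rep(y0, length(arcs)))
      bb <- cbind(x_axis_origin + c(arcs[1L], arcs[length(arcs)]),
                  rep(y0, 2L))
    } else {
      org <- c(x_axis_origin, y_pos[1L])
      grid <- add_curved_filament(grid, xv, yv, m, env, org, px,
                                  apparent, ext)
      pk_xy <- backbone_xy(m, arcs, origin = org)
      bb <- backbone_xy(m, seq(arcs[1L], arcs[length(arcs)], by = px),
                        origin = org)
    }
    app_xy <- if (!bent[k])
      cbind(x_axis_origin + apparent, rep(y_pos[k], length(apparent)))
    else backbone_xy(m, apparent, origin = c(x_axis_origin, y_pos[1L]))
    truth[[k]] <- list(
      global_index = m$global_index,
      states = m$half_helices$state,
      pitch_true_nm = m$half_helices$pitch_true_nm,
      arcs_true_nm = arcs,
      arcs_apparent_nm = apparent,
      peak_heights_true_nm = hts,
      peak_xy_true = pk_xy,
      peak_xy_apparent = app_xy,
      backbone_xy = bb,
      polarity = m$polarity,
      seed_xy = app_xy[which.max(hts), ],
      axis_origin_x_nm = x_axis_origin
    )
  }

  grid <- dilate_tip(grid, px, config$tip_radius_nm)
  if (config$noise_sd_nm > 0)
    grid <- grid + stats::rnorm(length(grid), 0, config$noise_sd_nm)

  fr <- height_frame(grid, px, t_s = t_s)
  attr(fr, "truth") <- truth
  fr
}

# Envelope along the backbone: every crossover contributes one symmetric
# bump of *fixed* axial width (reference pitch `ref`, the mean bare pitch):
# a cosine main lobe of period 2*ref dropping to `floor_frac` of the peak
# height at ref/2, cross-faded to the substrate at ref. The envelope is the
# pointwise max over bumps. A fixed width makes each summit locally
# symmetric whatever its neighbors' heights and pitches — the physical
# situation, where the crossover shape is set by subunit structure, and the
# property that keeps center-of-mass peak refinement unbiased. Natural
# terminal crossovers taper to the substrate through the same bump tails;
# ends newly created by severing are cut with a short (4 nm) rolloff just
# past the terminal crossover, so a severed half helix leaves a clear gap
# between the fragments. Returns a vectorized function of arc s.
make_axial_envelope <- function(apparent, heights, floor_frac, ref,
                                severed = c(start = FALSE, end = FALSE)) {
  np <- length(apparent)
  force(heights); force(floor_frac); force(ref)
  roll <- 4
  bump <- function(delta, height) {
    height <- rep_len(height, length(delta))
    out <- numeric(length(delta))
    main <- delta <= ref / 2
    out[main] <- height[main] *
      (floor_frac + (1 - floor_frac) * cos(pi * delta[main] / ref)^2)
    tail <- !main & delta <= ref
    out[tail] <- height[tail] * floor_frac *
      cos((pi / 2) * (delta[tail] - ref / 2) / (ref / 2))^2
    out
  }
  function(s) {
    i <- findInterval(s, apparent)
    h <- numeric(length(s))
    for (dk in -2L:3L) {
      k <- pmin(pmax(i + dk, 1L), np)
      h <- pmax(h, bump(abs(s - apparent[k]), heights[k]))
    }
    if (isTRUE(severed[["start"]])) {
      d <- apparent[1L] - s
      h[d >= roll] <- 0
      part <- d > 0 & d < roll
      h[part] <- h[part] * cos((pi / 2) * d[part] / roll)^2
    }
    if (isTRUE(severed[["end"]])) {
      d <- s - apparent[np]
      h[d >= roll] <- 0
      part <- d > 0 & d < roll
      h[part] <- h[part] * cos((pi / 2) * d[part] / roll)^2
    }
    h
  }
}

# arc extension beyond terminal crossovers (bump tail + localization slack)
end_extension_nm <- function(config) {
  config$envelope_ref_pitch_nm + 3 * config$localization_jitter_nm + 2.5
}

# Straight filament along +x at row position y0: closed-form cylinder
# cross-section, vectorized over the raster band the filament can reach.
add_straight_filament <- function(grid, xv, yv, x_axis_origin, y0, env) {
  a <- env(xv - x_axis_origin)    # apex height per column
  r <- a / 2                      # cylinder radius per column
  rmax <- max(r)
  if (rmax <= 0) return(grid)
  rows <- which(abs(yv - y0) <= rmax)
  for (i in rows) {
    d2 <- (yv[i] - y0)^2
    w <- r * r - d2
    hit <- w > 0
    if (any(hit)) {
      row <- grid[i, ]
      cand <- r[hit] + sqrt(w[hit])
      row[hit] <- pmax(row[hit], cand)
      grid[i, ] <- row
    }
  }
  grid
}

# World coordinates of backbone points at arcs `s` for a (possibly curved)
# model. `origin` is the world position of arc coordinate 0.
backbone_xy <- function(model, s, origin) {
  th0 <- model$angle_deg * pi / 180
  kap <- model$curvature_per_nm
  if (kap == 0) {
    cbind(origin[1L] + s * cos(th0), origin[2L] + s * sin(th0))
  } else {
    cbind(origin[1L] + (sin(th0 + kap * s) - sin(th0)) / kap,
          origin[2L] + (cos(th0) - cos(th0 + kap * s)) / kap)
  }
}

# Curved/rotated filament: dense arc sampling, each sample stamps its local
# cylindrical cross-section (Euclidean disc) into the raster by max.
add_curved_filament <- function(grid, xv, yv, model, env, origin, px,
                                apparent, cap_nm) {
  ss <- seq(apparent[1L] - cap_nm, apparent[length(apparent)] + cap_nm,
            by = px * 0.4)
  pts <- backbone_xy(model, ss, origin)
  a <- env(ss)
  r <- a / 2
  ny <- nrow(grid); nx <- ncol(grid)
  for (q in seq_along(ss)) {
    if (r[q] <= 0) next
    i0 <- max(1L, floor((pts[q, 2L] - r[q]) / px) + 1L)
    i1 <- min(ny, ceiling((pts[q, 2L] + r[q]) / px) + 1L)
    j0 <- max(1L, floor((pts[q, 1L] - r[q]) / px) + 1L)
    j1 <- min(nx, ceiling((pts[q, 1L] + r[q]) / px) + 1L)
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    dx2 <- (xv[jj] - pts[q, 1L])^2
    dy2 <- (yv[ii] - pts[q, 2L])^2
    rho2 <- outer(dy2, dx2, "+")
    w <- r[q]^2 - rho2
    hit <- w > 0
    if (any(hit)) {
      sub <- grid[ii, jj, drop = FALSE]
      cand <- r[q] + sqrt(pmax(w, 0))
      sub[hit] <- pmax(sub[hit], cand[hit])
      grid[ii, jj] <- sub
    }
  }
  grid
}

#' Grayscale dilation by a spherical AFM tip
#'
#' Emulates tip convolution: the imaged surface is the grayscale dilation
#' of the true surface with the (reflected) tip shape, a sphere of radius
#' `tip_radius_nm` touching the surface. Summit heights are preserved;
#' lateral widths broaden. With `tip_radius_nm = 0` the surface is
#' returned unchanged.
#'
#' @param grid height matrix (nm).
#' @param pixel_size_nm pixel size (nm).
#' @param tip_radius_nm tip radius (nm).
#' @return dilated height matrix.
#' @export
dilate_tip <- function(grid, pixel_size_nm, tip_radius_nm) {
  if (tip_radius_nm <= 0) return(grid)
  rpx <- floor(tip_radius_nm / pixel_size_nm)
  if (rpx < 1L) return(grid)
  out <- grid
  nr <- nrow(grid); nc <- ncol(grid)
  for (di in -rpx:rpx) {
    for (dj in -rpx:rpx) {
      if (di == 0L && dj == 0L) next
      rho2 <- (di^2 + dj^2) * pixel_size_nm^2
      if (rho2 > tip_radius_nm^2) next
      zt <- tip_radius_nm - sqrt(tip_radius_nm^2 - rho2)
      # shift grid by (di, dj); outside stays background (0 nm)
      si <- max(1L, 1L - di):min(nr, nr - di)
      sj <- max(1L, 1L - dj):min(nc, nc - dj)
      ti <- si + di; tj <- sj + dj
      out[ti, tj] <- pmax(out[ti, tj], grid[si, sj] - zt)
    }
  }
  out
}
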