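#' Remove spike noise by conditional median replacement
#'
#' HS-AFM rasters occasionally carry single-pixel spikes (tip instabilities,
#' electronic transients). Each pixel is compared with the median of its
#' `window_px` x `window_px` neighborhood (the window shrinks at frame
#' borders); pixels deviating from that median by more than
#' `spike_threshold_nm` are replaced by it, all others pass through
#' untouched, so an already-clean frame is returned bit-identically.
#' Replacement passes repeat until no pixel is flagged (clusters of
#' adjacent spikes can expose new deviations once their neighbors are
#' cleaned), which makes the filter a fixed point: applying it twice
#' equals applying it once.
#'
#' @param frame an `afm_frame`.
#' @param window_px odd window edge length in pixels (>= 3).
#' @param spike_threshold_nm replacement threshold (nm).
#' @return filtered `afm_frame`.
#' @export
remove_spike_noise <- function(frame, window_px = 3L,
                               spike_threshold_nm = 2.0) {
  stopifnot(inherits(frame, "afm_frame"))
  w <- as.integer(window_px)
  if (w < 3L || w %% 2L == 0L)
    stop("`window_px` must be an odd integer >= 3")
  g <- frame$grid
  for (pass in 1:10) {
    med <- if (w == 3L) local_median3(g) else local_median_generic(g, w)
    spike <- abs(g - med) > spike_threshold_nm
    if (!any(spike)) break
    g[spike] <- med[spike]
  }
  out <- frame
  out$grid <- g
  out
}

# Exact 3x3 shrinking-window median: interior via a median-of-9 sorting
# network on shifted copies (fast, vectorized), border ring exactly via the
# clipped neighborhood.
local_median3 <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  if (nr < 3L || nc < 3L) return(local_median_generic(g, 3L))
  core <- g[2:(nr - 1L), 2:(nc - 1L), drop = FALSE]
  sh <- vector("list", 9L)
  k <- 1L
  for (di in -1:1) for (dj in -1:1) {
    sh[[k]] <- g[(2:(nr - 1L)) + di, (2:(nc - 1L)) + dj, drop = FALSE]
    k <- k + 1L
  }
  med <- g
  med[2:(nr - 1L), 2:(nc - 1L)] <- median9(sh)
  # border ring: clipped windows
  ring <- c(which(row(g) == 1L | row(g) == nr | col(g) == 1L | col(g) == nc))
  ri <- ((ring - 1L) %% nr) + 1L
  rj <- ((ring - 1L) %/% nr) + 1L
  for (t in seq_along(ring)) {
    i <- ri[t]; j <- rj[t]
    med[i, j] <- stats::median(g[max(1L, i - 1L):min(nr, i + 1L),
                                 max(1L, j - 1L):min(nc, j + 1L)])
  }
  med
}

# Paeth's 19-comparison median-of-9 network over parallel matrices.
median9 <- function(p) {
  sw <- function(a, b) {
    lo <- pmin(p[[a]], p[[b]]); hi <- pmax(p[[a]], p[[b]])
    p[[a]] <<- lo; p[[b]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  p[[5]]
}

local_median_generic <- function(g, w) {
  nr <- nrow(g); nc <- ncol(g)
  h <- (w - 1L) %/% 2L
  med <- g
  for (j in seq_len(nc)) {
    jr <- max(1L, j - h):min(nc, j + h)
    for (i in seq_len(nr)) {
      med[i, j] <- stats::median(g[max(1L, i - h):min(nr, i + h), jr])
    }
  }
  med
}

#' Flatten the xy plane of a frame
#'
#' Fits a first-order plane `a + b x + c y` by least squares to the
#' background pixels (those not in `mask`) and subtracts it from the whole
#' frame, so the background mean becomes 0 and tilt/offset of the support
#' is removed. Height differences between any two pixels are preserved up
#' to the fitted plane.
#'
#' @param frame an `afm_frame`.
#' @param mask optional logical matrix marking foreground pixels to exclude
#'   from the fit (e.g. filaments); `NULL` fits all pixels.
#' @return flattened `afm_frame`.
#' @export
flatten_plane <- function(frame, mask = NULL) {
  stopifnot(inherits(frame, "afm_frame"))
  g <- frame$grid
  if (is.null(mask)) {
    bg <- rep(TRUE, length(g))
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dim(g)))
      stop("`mask` must be a logical matrix matching the frame")
    bg <- !as.vector(mask)
  }
  if (sum(bg) < 3L)
    stop("degenerate background: need >= 3 non-masked pixels")
  px <- frame$pixel_size_nm
  x <- as.vector(col(g) - 1L) * px
  y <- as.vector(row(g) - 1L) * px
  X <- cbind(1, x[bg], y[bg])
  if (qr(X)$rank < 3L)
    stop("degenerate background: non-masked pixels are collinear")
  beta <- qr.coef(qr(X), as.vector(g)[bg])
  plane <- beta[1L] + beta[2L] * x + beta[3L] * y
  out <- frame
  out$grid <- g - matrix(plane, nrow(g), ncol(g))
  out
}

#' Apply the standard preprocessing chain to a frame
#'
#' Spike-noise removal followed by plane flattening. The flattening mask is
#' taken as all pixels above `foreground_threshold_nm` after spike removal,
#' so filaments do not bias the background plane fit.
#'
#' @param frame an `afm_frame`.
#' @param spike_window_px,spike_threshold_nm see [remove_spike_noise()].
#' @param flatten logical; skip plane flattening when `FALSE`.
#' @param foreground_threshold_nm mask threshold for the plane fit (nm).
#' @return preprocessed `afm_frame`.
#' @export
preprocess_frame <- function(frame, spike_window_px = 3L,
                             spike_threshold_nm = 2.0,
                             flatten = TRUE,
                             foreground_threshold_nm = 2.0) {
  fr <- remove_spike_noise(frame, spike_window_px, spike_threshold_nm)
  if (flatten) {
    mask <- fr$grid > foreground_threshold_nm
    if (sum(!mask) >= 3L) fr <- flatten_plane(fr, mask)
  }
  fr
}
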