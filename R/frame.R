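#' Calibrated AFM height frame
#'
#' A single topographic image: a rectangular grid of heights in nanometres
#' with a physical pixel size. Row `i`, column `j` of `grid` sits at
#' physical coordinates `x = (j - 1) * pixel_size_nm`,
#' `y = (i - 1) * pixel_size_nm` (pixel centres, 0-based physical origin).
#'
#' @param grid numeric matrix of heights (nm); must be finite.
#' @param pixel_size_nm edge length of one (square) pixel in nm.
#' @param t_s acquisition timestamp in seconds.
#' @return An object of class `afm_frame`.
#' @export
height_frame <- function(grid, pixel_size_nm, t_s = 0) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("`grid` must be a numeric matrix")
  if (!all(is.finite(grid)))
    stop("heights must be finite")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number")
  structure(
    list(grid = grid, pixel_size_nm = as.numeric(pixel_size_nm),
         t_s = as.numeric(t_s)),
    class = "afm_frame"
  )
}

#' @export
print.afm_frame <- function(x, ...) {
  cat(sprintf("<afm_frame> %d x %d px (%.2f nm/px), t = %.3f s, z in [%.2f, %.2f] nm\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size_nm, x$t_s,
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Time-lapse AFM movie
#'
#' An ordered list of [height_frame()] objects sharing one pixel size, with
#' strictly increasing timestamps.
#'
#' @param frames list of `afm_frame` objects.
#' @param frame_interval_s nominal time between frames, seconds.
#' @return An object of class `afm_movie`.
#' @export
afm_movie <- function(frames, frame_interval_s = NA_real_) {
  if (!length(frames))
    stop("a movie needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "afm_frame")))
    stop("all frames must be `afm_frame` objects")
  px <- vapply(frames, function(f) f$pixel_size_nm, numeric(1))
  if (diff(range(px)) > 1e-12)
    stop("all frames must share one pixel size")
  ts <- vapply(frames, function(f) f$t_s, numeric(1))
  if (length(ts) > 1L && any(diff(ts) <= 0))
    stop("frame timestamps must be strictly increasing")
  structure(
    list(frames = frames, pixel_size_nm = px[1L],
         frame_interval_s = as.numeric(frame_interval_s)),
    class = "afm_movie"
  )
}

#' @export
print.afm_movie <- function(x, ...) {
  cat(sprintf("<afm_movie> %d frame(s), %d x %d px, %.2f nm/px, dt = %s s\n",
              length(x$frames), nrow(x$frames[[1L]]$grid),
              ncol(x$frames[[1L]]$grid), x$pixel_size_nm,
              format(x$frame_interval_s)))
  invisible(x)
}

#' @export
length.afm_movie <- function(x) length(x$frames)

#' Bilinear height interpolation
#'
#' Heights at arbitrary physical positions, by bilinear interpolation of the
#' pixel-centre grid; positions are clamped to the grid hull.
#'
#' @param frame an `afm_frame`.
#' @param x_nm,y_nm numeric vectors of physical coordinates (nm).
#' @return numeric vector of interpolated heights (nm).
#' @export
frame_height_at <- function(frame, x_nm, y_nm) {
  g <- frame$grid
  px <- frame$pixel_size_nm
  nr <- nrow(g); nc <- ncol(g)
  cx <- pmin(pmax(x_nm / px, 0), nc - 1L)  # 0-based fractional col
  cy <- pmin(pmax(y_nm / px, 0), nr - 1L)
  j0 <- pmin(floor(cx), nc - 2L); i0 <- pmin(floor(cy), nr - 2L)
  if (nc == 1L) j0 <- rep(0, length(cx))
  if (nr == 1L) i0 <- rep(0, length(cy))
  fx <- cx - j0; fy <- cy - i0
  i0 <- i0 + 1L; j0 <- j0 + 1L  # back to 1-based
  i1 <- pmin(i0 + 1L, nr); j1 <- pmin(j0 + 1L, nc)
  g[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    g[cbind(i0, j1)] * fx * (1 - fy) +
    g[cbind(i1, j0)] * (1 - fx) * fy +
    g[cbind(i1, j1)] * fx * fy
}
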