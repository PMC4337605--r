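# Shared fixture builders. Everything is generated in code; no files.

# deterministic rendering conditions (no noise, no localization error)
quiet_config <- function(...) {
  args <- utils::modifyList(list(noise_sd_nm = 0, localization_jitter_nm = 0),
                            list(...))
  do.call(afm_config, args)
}

# frame with one isolated Gaussian bump at physical position (x0, y0)
gaussian_bump_frame <- function(x0_nm, y0_nm, sigma_nm = 3, height_nm = 8,
                                nx = 41L, ny = 31L, px = 1.5) {
  xs <- (seq_len(nx) - 1L) * px
  ys <- (seq_len(ny) - 1L) * px
  g <- height_nm * exp(-(outer((ys - y0_nm)^2, (xs - x0_nm)^2, "+")) /
                         (2 * sigma_nm^2))
  height_frame(g, px)
}

# brute-force grayscale dilation by a spherical tip (independent oracle for
# dilate_tip): direct double loop over all in-range displacements
dilate_oracle <- function(grid, px, tip_r) {
  nr <- nrow(grid); nc <- ncol(grid)
  rpx <- floor(tip_r / px)
  out <- grid
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      best <- grid[i, j]
      for (di in -rpx:rpx) {
        for (dj in -rpx:rpx) {
          rho2 <- (di^2 + dj^2) * px^2
          if (rho2 > tip_r^2) next
          ii <- i + di; jj <- j + dj
          if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
          zt <- tip_r - sqrt(tip_r^2 - rho2)
          best <- max(best, grid[ii, jj] - zt)
        }
      }
      out[i, j] <- best
    }
  }
  out
}

# brute-force severing rule table (independent restatement of the four
# category definitions, written against the verbal rules)
sever_oracle <- function(states, i) {
  n <- length(states)
  dec <- states == "decorated"
  if (dec[i]) {
    left_bare <- i == 1L || !dec[i - 1L]
    right_bare <- i == n || !dec[i + 1L]
    if (left_bare || right_bare) "end_cluster" else "inner_cluster"
  } else {
    touches <- (i > 1L && dec[i - 1L]) || (i < n && dec[i + 1L])
    if (touches) "neighbor_bare" else "far_bare"
  }
}

# brute-force run enumeration (independent oracle for find_clusters)
runs_oracle <- function(states) {
  out <- NULL
  j <- 1L
  while (j <= length(states)) {
    if (states[j] == "decorated") {
      k <- j
      while (k < length(states) && states[k + 1L] == "decorated") k <- k + 1L
      out <- rbind(out, data.frame(first = j, last = k))
      j <- k + 1L
    } else j <- j + 1L
  }
  if (is.null(out)) data.frame(first = integer(0), last = integer(0)) else out
}

# measured pitches pooled over a rendered simulation (thin wrapper used by
# several statistical tests)
pooled_pitches <- function(sim, params = afm_params()) {
  hh <- measure_simulation_pitches(sim, params)
  expect_false(is.null(hh))
  hh
}
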