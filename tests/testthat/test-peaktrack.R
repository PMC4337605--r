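# Backbone tracing, peak refinement, detection, linking.

test_that("straight filaments are traced along the generator backbone", {
  cfg <- quiet_config()
  set.seed(40)
  m <- build_filament_model(cfg, 8)
  fr <- render_frame(m, cfg, seed = 41)
  tru <- attr(fr, "truth")[[1]]
  trc <- trace_backbone(fr, tru$seed_xy)
  y0 <- tru$peak_xy_true[1, 2]
  # within 1 px of the true axis, over the span between terminal crossovers
  xr <- range(tru$peak_xy_true[, 1])
  on_fil <- trc$x_nm >= xr[1] & trc$x_nm <= xr[2]
  expect_true(all(abs(trc$y_nm[on_fil] - y0) <= cfg$pixel_size_nm))
  expect_true(all(diff(trc$arc_nm) > 0))
})

test_that("tracing a curved filament recovers its arc length within 2%", {
  cfg <- quiet_config()
  set.seed(42)
  m <- build_filament_model(cfg, 8)
  m$curvature_per_nm <- 1 / 400  # gentle arc, radius 400 nm
  fr <- render_frame(m, cfg, seed = 43)
  tru <- attr(fr, "truth")[[1]]
  trc <- trace_backbone(fr, tru$seed_xy)
  pk <- detect_peaks_along_trace(fr, trc)
  expect_equal(nrow(pk), length(tru$arcs_true_nm))
  measured_span <- max(pk$arc_nm) - min(pk$arc_nm)
  true_span <- max(tru$arcs_true_nm) - min(tru$arcs_true_nm)
  expect_lt(abs(measured_span - true_span) / true_span, 0.02)
})

test_that("tracing errors out on background seeds", {
  cfg <- quiet_config()
  set.seed(44)
  m <- build_filament_model(cfg, 6)
  fr <- render_frame(m, cfg, seed = 45)
  expect_error(trace_backbone(fr, c(1, 1)), "below the height floor")
})

test_that("center-of-mass refinement is exact on symmetric bumps and <0.2 px on sub-pixel offsets", {
  px <- 1.5
  # bump centered exactly on a pixel, approached from one pixel off
  fr <- gaussian_bump_frame(30, 22.5, px = px)
  pk <- refine_peak(fr, c(30 + px, 22.5))
  expect_equal(pk$x_nm, 30, tolerance = 1e-9)
  expect_equal(pk$y_nm, 22.5, tolerance = 1e-9)
  expect_false(pk$degenerate)

  # grid of sub-pixel offsets: refinement error < 0.2 px in both axes
  offs <- seq(-0.5, 0.5, by = 0.125) * px
  for (dx in offs) {
    for (dy in c(-0.25, 0, 0.25) * px) {
      f <- gaussian_bump_frame(30 + dx, 22.5 + dy, px = px)
      p <- refine_peak(f, c(30, 22.5))
      expect_lt(abs(p$x_nm - (30 + dx)), 0.2 * px)
      expect_lt(abs(p$y_nm - (22.5 + dy)), 0.2 * px)
    }
  }
})

test_that("refinement tie-breaks flat windows deterministically and flags them", {
  fr <- height_frame(matrix(5, 21, 21), 1.5)
  pk <- refine_peak(fr, c(15, 15))
  expect_true(pk$degenerate)
  # smallest row, then column, within the 5x5 search window
  expect_equal(pk$x_nm / 1.5 + 1, 9)  # column index of window corner
  expect_equal(pk$y_nm / 1.5 + 1, 9)
  expect_error(refine_peak(fr, c(0, 0)), "window")
})

test_that("refined peak stays inside its window and interpolated height matches the max mode", {
  set.seed(46)
  fr <- gaussian_bump_frame(30.9, 21.7, px = 1.5)
  p1 <- refine_peak(fr, c(30, 22.5), height_mode = "interpolated")
  p2 <- refine_peak(fr, c(30, 22.5), height_mode = "max_pixel")
  expect_equal(p1$x_nm, p2$x_nm)  # same position, different height rule
  # bilinear interpolation undershoots slightly on a curved summit; the
  # max pixel underestimates the off-grid peak: both within the bump scale
  expect_lt(abs(p1$height_nm - 8), 0.6)
  expect_lt(abs(p2$height_nm - 8), 0.6)
  expect_lt(abs(p1$x_nm - 30.9), 2 * 1.5)  # inside the 5x5 window
})

test_that("peak detection finds one crossover per half helix, ordered and separated", {
  cfg <- quiet_config()
  set.seed(47)
  m <- build_filament_model(cfg, 6)
  fr <- render_frame(m, cfg, seed = 48)
  tru <- attr(fr, "truth")[[1]]
  trc <- trace_backbone(fr, tru$seed_xy)
  pk <- detect_peaks_along_trace(fr, trc)
  expect_equal(nrow(pk), 7)
  expect_true(all(diff(pk$arc_nm) > 0))
  expect_true(all(diff(pk$arc_nm) >= 15))
  # detected arcs match truth within 1 px (no offset/jitter injected)
  hh <- half_pitches_with_truth(pk, tru)
  expect_false(is.null(hh))
  expect_lt(max(abs(hh$pitch_nm - hh$pitch_true_nm)), cfg$pixel_size_nm)
  # absurd separation: at most one peak survives
  pk1 <- detect_peaks_along_trace(fr, trc, min_separation_nm = 1e4)
  expect_lte(nrow(pk1), 1)
})

test_that("detected heights match generator truth within interpolation error", {
  cfg <- quiet_config()
  set.seed(49)
  m <- build_filament_model(cfg, 10, cluster_spec = list(c(4, 6)))
  fr <- render_frame(m, cfg, seed = 50)
  tru <- attr(fr, "truth")[[1]]
  trc <- trace_backbone(fr, tru$seed_xy)
  pk <- detect_peaks_along_trace(fr, trc)
  mm <- match_peaks_to_truth(pk, tru)
  expect_true(attr(mm, "aligned"))
  expect_lt(max(abs(mm$height_nm - tru$peak_heights_true_nm[mm$true_index])),
            0.05)
})

test_that("linking builds stable tracks and refuses teleporting assignments", {
  mk <- function(f, xs, ys) data.frame(frame = f, x_nm = xs, y_nm = ys,
                                       height_nm = 9, arc_nm = xs,
                                       degenerate = FALSE)
  # static peaks: one track per peak, each spanning all frames
  static <- do.call(rbind, lapply(1:5, function(f)
    mk(f, c(10, 50, 90), c(5, 5, 5))))
  lk <- link_peaks(static)
  expect_equal(length(unique(lk$track_id)), 3)
  expect_true(all(table(lk$track_id) == 5))

  # slow drift: a single unbroken track
  drift <- do.call(rbind, lapply(1:10, function(f) mk(f, 10 + f, 5)))
  expect_equal(length(unique(link_peaks(drift)$track_id)), 1)

  # both peaks jump 15 nm in one frame (beyond the 10 nm cutoff): both
  # tracks terminate and two new ones start — no teleporting assignment,
  # matching exhaustive enumeration of admissible (< cutoff) assignments,
  # of which there are none
  jump <- rbind(mk(1, c(10, 40), c(5, 5)), mk(2, c(25, 55), c(5, 5)))
  lks <- link_peaks(jump)
  expect_equal(length(unique(lks$track_id)), 4)
})
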