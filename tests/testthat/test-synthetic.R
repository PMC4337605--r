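# Generator: filament models, rendering, tip dilation, dynamics, fields.

test_that("model building draws state-correct pitches and assigns boundary states", {
  cfg <- afm_config()
  # zero structural variance: every pitch is exactly the state mean
  cfg0 <- cfg
  for (s in names(cfg0$states)) cfg0$states[[s]]$pitch_sd_struct_nm <- 0
  set.seed(1)
  m0 <- build_filament_model(cfg0, 10)
  expect_equal(m0$half_helices$pitch_true_nm, rep(36.8, 10))

  # decorated interval [5,8] of 12: pointed-side neighbor at 4, barbed at 9
  set.seed(2)
  m <- build_filament_model(cfg, 12, cluster_spec = list(c(5, 8)))
  st <- m$half_helices$state
  expect_equal(st[4], "p_neighbor")
  expect_equal(st[5:8], rep("decorated", 4))
  expect_equal(st[9], "b_neighbor")
  expect_equal(st[c(1:3, 10:12)], rep("bare", 6))

  # bare structural SD: sample SD of 2000 pitches ~ 3.1 within 3 SE of an SD
  set.seed(3)
  big <- build_filament_model(cfg, 2000)
  se_sd <- 3.1 / sqrt(2 * 2000)
  expect_lt(abs(sd(big$half_helices$pitch_true_nm) - 3.1), 3 * se_sd)

  # invalid cluster specs
  expect_error(build_filament_model(cfg, 12, list(c(5, 8), c(9, 10))),
               "separated")
  expect_error(build_filament_model(cfg, 12, list(c(5, 13))), "range")
  expect_error(build_filament_model(cfg, 0), "n_half_helices")
})

test_that("truncation guards pitches and peak heights average across half helices", {
  x <- afmhelix:::rnorm_trunc(5000, 12, 3, lower = 10)
  expect_true(all(x > 10))
  cfg <- afm_config()
  set.seed(4)
  m <- build_filament_model(cfg, 3)
  h <- m$half_helices$peak_height_true_nm
  expect_equal(model_peak_heights(m),
               c(h[1], (h[1] + h[2]) / 2, (h[2] + h[3]) / 2, h[3]))
  expect_equal(model_peak_arcs(m), c(0, cumsum(m$half_helices$pitch_true_nm)))
})

test_that("noiseless rendering places crossover maxima at the true spacing", {
  cfg <- quiet_config()
  cfg$states$bare$pitch_mean_nm <- 36
  cfg$states$bare$pitch_sd_struct_nm <- 0
  cfg$states$bare$peak_height_sd_nm <- 0
  set.seed(5)
  m <- build_filament_model(cfg, 6)
  fr <- render_frame(m, cfg, seed = 6)
  tru <- attr(fr, "truth")[[1]]
  y0 <- tru$peak_xy_true[1, 2]
  xs <- seq(5, (ncol(fr$grid) - 1) * fr$pixel_size_nm - 5, by = 0.25)
  prof <- frame_height_at(fr, xs, rep(y0, length(xs)))
  pk <- xs[which(diff(sign(diff(prof))) == -2) + 1]
  pk <- pk[prof[match(pk, xs)] > 4]
  expect_length(pk, 7)  # 6 half helices -> 7 crossovers
  expect_true(all(abs(diff(pk) - 36) <= cfg$pixel_size_nm))
})

test_that("rendering is deterministic given (model, config, seed)", {
  cfg <- afm_config()
  set.seed(7)
  m <- build_filament_model(cfg, 6)
  f1 <- render_frame(m, cfg, seed = 99)
  f2 <- render_frame(m, cfg, seed = 99)
  expect_identical(f1$grid, f2$grid)
  f3 <- render_frame(m, cfg, seed = 100)
  expect_false(identical(f1$grid, f3$grid))
})

test_that("tip dilation preserves summit heights and broadens widths", {
  cfg <- quiet_config(tip_radius_nm = 0)
  set.seed(8)
  m <- build_filament_model(cfg, 4)
  fr0 <- render_frame(m, cfg, seed = 9)
  cfg3 <- quiet_config(tip_radius_nm = 3)
  fr3 <- render_frame(m, cfg3, seed = 9)
  tru <- attr(fr0, "truth")[[1]]
  # summit heights unchanged (compare at apparent peak positions)
  h0 <- frame_height_at(fr0, tru$peak_xy_apparent[, 1], tru$peak_xy_apparent[, 2])
  h3 <- frame_height_at(fr3, tru$peak_xy_apparent[, 1], tru$peak_xy_apparent[, 2])
  expect_equal(h0, h3, tolerance = 1e-6)
  # apparent width strictly larger with the tip: count above-floor pixels in
  # a cross-section at a peak
  j <- round(tru$peak_xy_apparent[2, 1] / fr0$pixel_size_nm) + 1
  expect_gt(sum(fr3$grid[, j] > 2), sum(fr0$grid[, j] > 2))
  # fast dilation equals the brute-force oracle
  set.seed(10)
  g <- matrix(runif(30 * 25, 0, 10), 30, 25)
  expect_equal(dilate_tip(g, 1.5, 3), dilate_oracle(g, 1.5, 3))
  expect_identical(dilate_tip(g, 1.5, 0), g)
})

test_that("decorated crossovers render ~2 nm taller than bare ones", {
  cfg <- quiet_config()
  for (s in names(cfg$states)) {
    cfg$states[[s]]$peak_height_sd_nm <- 0
    cfg$states[[s]]$pitch_sd_struct_nm <- 0
  }
  set.seed(11)
  m <- build_filament_model(cfg, 12, cluster_spec = list(c(5, 8)))
  fr <- render_frame(m, cfg, seed = 12)
  tru <- attr(fr, "truth")[[1]]
  h <- frame_height_at(fr, tru$peak_xy_apparent[, 1], tru$peak_xy_apparent[, 2])
  # crossovers 6..8 are interior to the decorated run; 1..4 fully bare
  expect_equal(mean(h[6:8]) - mean(h[1:4]), 2.0, tolerance = 0.1)
})

test_that("dynamics: degenerate settings give identical frames and empty logs", {
  cfg <- afm_config(growth_rate_per_s = 0,
                    severing_rates = c(far_bare = 0, neighbor_bare = 0,
                                       end_cluster = 0, inner_cluster = 0),
                    n_frames = 4L)
  set.seed(13)
  m <- build_filament_model(cfg, 8, cluster_spec = list(c(4, 5)))
  sim <- simulate_dynamics(m, cfg, seed = 14, render = FALSE)
  expect_equal(nrow(sim$log$growth), 0)
  expect_equal(nrow(sim$log$severing), 0)
  for (f in 2:4)
    expect_identical(sim$states_history[[f]], sim$states_history[[1]])
})

test_that("dynamics: full pointed bias yields only pointed growth events", {
  cfg <- afm_config(growth_rate_per_s = 1.0, growth_bias_pointed = 1,
                    frame_interval_s = 0.5,
                    severing_rates = c(far_bare = 0, neighbor_bare = 0,
                                       end_cluster = 0, inner_cluster = 0))
  set.seed(15)
  m <- build_filament_model(cfg, 30, cluster_spec = list(c(25, 27)))
  sim <- simulate_dynamics(m, cfg, n_frames = 30, seed = 16, render = FALSE)
  expect_gt(nrow(sim$log$growth), 5)
  expect_true(all(sim$log$growth$direction == "pointed"))
})

test_that("dynamics: growth direction follows the configured bias", {
  cfg <- afm_config(growth_rate_per_s = 0.25, growth_bias_pointed = 0.8,
                    severing_rates = c(far_bare = 0, neighbor_bare = 0,
                                       end_cluster = 0, inner_cluster = 0))
  dirs <- character(0)
  for (i in 1:20) {
    set.seed(400 + i)
    m <- build_filament_model(cfg, 60, cluster_spec = list(c(29, 31)))
    sim <- simulate_dynamics(m, cfg, n_frames = 120, seed = 500 + i,
                             render = FALSE)
    dirs <- c(dirs, sim$log$growth$direction)
  }
  n <- length(dirs)
  expect_gte(n, 250)
  phat <- mean(dirs == "pointed")
  expect_lt(abs(phat - 0.8), 2.58 * sqrt(0.8 * 0.2 / n))  # 99% band
})

test_that("a newly decorated half helix adopts the supertwisted pitch", {
  cfg <- afm_config(growth_rate_per_s = 1.0, growth_bias_pointed = 1,
                    severing_rates = c(far_bare = 0, neighbor_bare = 0,
                                       end_cluster = 0, inner_cluster = 0))
  set.seed(17)
  m <- build_filament_model(cfg, 20, cluster_spec = list(c(15, 17)))
  sim <- simulate_dynamics(m, cfg, n_frames = 20, seed = 18, render = FALSE)
  g <- sim$log$growth
  expect_gt(nrow(g), 3)
  last <- sim$states_history[[20]][[1]]
  grown <- match(g$global_index, last$global_index)
  expect_true(all(last$states[grown] == "decorated"))
  # pooled grown pitches center on the decorated mean, far from bare
  expect_lt(abs(mean(last$pitch_true_nm[grown]) - 26.9), 2.5)
})

test_that("paracrystal field: pitch variance comes only from the measurement chain", {
  cfg <- quiet_config()
  sim <- make_paracrystal_field(cfg, n_filaments = 4, n_half_helices = 15,
                                n_frames = 1, seed = 19)
  hh <- pooled_pitches(sim)
  # no jitter, no noise: residual scatter is pixel quantization of the
  # center-of-mass refinement (well under 1 px)
  expect_equal(mean(hh$pitch_nm), 36.5, tolerance = 0.1)
  expect_lt(sd(hh$pitch_nm), cfg$pixel_size_nm / 2)
  expect_true(all(hh$pitch_true_nm == 36.5))

  # jitter sigma_p = 3/sqrt(2) per peak: apparent-vs-true pitch error SD
  # is sigma_p * sqrt(2) = 3.0 (difference of two i.i.d. jitters)
  cfgj <- quiet_config(localization_jitter_nm = 3.0 / sqrt(2))
  simj <- make_paracrystal_field(cfgj, n_filaments = 8, n_half_helices = 25,
                                 n_frames = 5, seed = 20)
  err <- unlist(lapply(simj$movie$frames, function(fr)
    lapply(attr(fr, "truth"), function(tru)
      diff(tru$arcs_apparent_nm) - diff(tru$arcs_true_nm))))
  expect_gt(length(err), 900)
  se_sd <- 3.0 / sqrt(2 * length(err))
  expect_lt(abs(sd(err) - 3.0), 4 * se_sd)
})

test_that("severed fragments render collinearly with a clear gap and are logged once", {
  cfg <- afm_config(growth_rate_per_s = 0, n_frames = 6,
                    severing_rates = c(far_bare = 0, neighbor_bare = 0.2,
                                       end_cluster = 0, inner_cluster = 0))
  set.seed(21)
  m <- build_filament_model(cfg, 14, cluster_spec = list(c(7, 9)))
  sim <- simulate_dynamics(m, cfg, seed = 22, render = TRUE)
  expect_gte(nrow(sim$log$severing), 1)
  ev <- sim$log$severing[1, ]
  fr_pre <- sim$movie$frames[[ev$frame]]
  fr_post <- sim$movie$frames[[ev$frame + 1]]
  tru <- attr(sim$movie$frames[[1]], "truth")[[1]]
  y0 <- tru$peak_xy_true[1, 2]
  xs <- seq(10, (ncol(fr_post$grid) - 1) * fr_post$pixel_size_nm - 10, by = 0.75)
  pre <- frame_height_at(fr_pre, xs, rep(y0, length(xs)))
  post <- frame_height_at(fr_post, xs, rep(y0, length(xs)))
  gap_run <- function(v) max(0, with(rle(v < 2), max(c(0, lengths[values]))))
  expect_lt(gap_run(pre[pre > -Inf][20:(length(pre) - 20)]), 10 / 0.75)
  expect_gt(gap_run(post), 10 / 0.75)  # >= 10 nm of substrate appears
})
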