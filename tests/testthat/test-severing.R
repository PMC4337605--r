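# Break detection, site classification, tallies.

test_that("constructed gaps are detected at the midpoint; transients are rejected", {
  px <- 1.5
  mk_frame <- function(gap = NULL, t = 0) {
    g <- matrix(0, 21, 161)
    g[9:13, ] <- 8  # crude continuous ridge along row 11
    if (!is.null(gap)) {
      j0 <- round(gap[1] / px) + 1; j1 <- round(gap[2] / px) + 1
      g[, j0:j1] <- 0
    }
    height_frame(g, px, t_s = t)
  }
  cont <- mk_frame()
  trc <- trace_backbone(cont, c(120, 15))
  # break appears at frame 3, 20 nm gap centered at 120 nm, lasts to the end
  frames <- list(mk_frame(t = 0), mk_frame(t = 1),
                 mk_frame(c(110, 130), 2), mk_frame(c(110, 130), 3),
                 mk_frame(c(110, 130), 4))
  mv <- afm_movie(frames, 1)
  br <- detect_breaks(mv, trc)
  expect_equal(nrow(br), 1)
  expect_equal(br$frame_detected, 3)
  expect_equal(br$frame, 2)  # last pre-break frame
  # arc midpoint within 1 px of 120 nm (trace arc == x here up to origin)
  mid_x <- trc$x_nm[which.min(abs(trc$arc_nm - br$arc_nm))]
  expect_lt(abs(mid_x - 120), 2 * px)

  # 1-frame transient gap: no event
  frames2 <- list(mk_frame(t = 0), mk_frame(c(110, 130), 1), mk_frame(t = 2),
                  mk_frame(t = 3))
  expect_equal(nrow(detect_breaks(afm_movie(frames2, 1), trc)), 0)
})

test_that("break arcs map to half helices with the pointed-side peak convention", {
  arcs <- c(0, 36, 72, 108)
  expect_equal(assign_break_half_helix(18, arcs), 1)
  expect_equal(assign_break_half_helix(70, arcs), 2)
  # exactly on a peak: pointed-side interval
  expect_equal(assign_break_half_helix(72, arcs, "pointed_at_start"), 2)
  expect_equal(assign_break_half_helix(72, arcs, "pointed_at_end"), 3)
  expect_error(assign_break_half_helix(200, arcs), "outside")
})

test_that("severing categories match the verbal rules and partition all cases", {
  # spec-level examples
  expect_equal(classify_severing(2, c("bare", "bare", "bare", "decorated",
                                      "bare"))$category, "far_bare")
  expect_equal(classify_severing(3, c("bare", "bare", "bare", "decorated",
                                      "bare"))$category, "neighbor_bare")
  expect_equal(classify_severing(4, c("bare", "bare", "bare", "decorated",
                                      "bare"))$category, "end_cluster")
  expect_equal(classify_severing(3, rep("decorated", 5))$category,
               "inner_cluster")
  # cluster-free filament: always far_bare
  expect_true(all(vapply(1:6, function(i)
    classify_severing(i, rep("bare", 6))$category, character(1)) ==
      "far_bare"))
  # decorated half helix at the physical filament end: end_cluster, flagged
  r <- classify_severing(1, c("decorated", "decorated", "bare"))
  expect_equal(r$category, "end_cluster")
  expect_true(r$end_of_filament)
  expect_error(classify_severing(2, c("bare", NA)), "unknown")
})

test_that("classifier equals the brute-force rule table on all strings up to length 12", {
  ok <- TRUE
  for (len in 1:12) {
    for (code in 0:(2^len - 1)) {
      states <- ifelse(bitwAnd(code, 2^(0:(len - 1))) > 0,
                       "decorated", "bare")
      got <- vapply(seq_len(len), function(i)
        classify_severing(i, states)$category, character(1))
      want <- vapply(seq_len(len), function(i)
        sever_oracle(states, i), character(1))
      if (!identical(got, want)) { ok <- FALSE; break }
    }
    if (!ok) break
  }
  expect_true(ok)
})

test_that("tallies report counts, fractions and the boundary-proximal pool", {
  # the published 40 nM fixture: 22 events, 18 boundary-proximal, 3 far, 1 inner
  cats <- c(rep("neighbor_bare", 8), rep("end_cluster", 10),
            rep("far_bare", 3), "inner_cluster")
  t1 <- tally_severing(cats)
  expect_equal(t1$n, 22)
  expect_equal(t1$boundary_proximal_n, 18)
  expect_equal(unname(t1$counts), c(3L, 8L, 10L, 1L))
  expect_equal(sum(t1$counts), t1$n)
  expect_equal(sum(t1$fractions), 1)
  expect_equal(t1$boundary_proximal_fraction, 18 / 22, tolerance = 1e-12)

  t2 <- tally_severing(rep("far_bare", 5))
  expect_equal(t2$boundary_proximal_fraction, 0)
  t3 <- tally_severing("end_cluster")
  expect_true(all(t3$fractions %in% c(0, 1)))
  expect_error(tally_severing(character(0)), "no severing")
})

test_that("recovered category frequencies track the configured rate ratios", {
  rates <- c(far_bare = 0.001, neighbor_bare = 0.02, end_cluster = 0.02,
             inner_cluster = 0.002)
  cfg <- afm_config(growth_rate_per_s = 0, severing_rates = rates)
  cats <- character(0)
  for (i in 1:40) {
    set.seed(700 + i)
    m <- build_filament_model(cfg, 20, cluster_spec = list(c(8, 13)))
    sim <- simulate_dynamics(m, cfg, n_frames = 40, seed = 800 + i,
                             render = FALSE)
    cats <- c(cats, sim$log$severing$category)
  }
  expect_gt(length(cats), 40)
  tl <- tally_severing(cats)
  # per-half-helix exposure: 12 far, 2 neighbor, 2 end, 4 inner at frame 1
  expo <- c(far_bare = 12, neighbor_bare = 2, end_cluster = 2,
            inner_cluster = 4)
  expect_prob <- rates[severing_categories] * expo[severing_categories]
  expect_prob <- expect_prob / sum(expect_prob)
  for (cat in c("neighbor_bare", "end_cluster")) {
    p <- expect_prob[[cat]]
    expect_lt(abs(tl$fractions[[cat]] - p),
              4 * sqrt(p * (1 - p) / length(cats)) + 0.02)
  }
})

test_that("simulated severing is detected 1:1 within one half helix", {
  cfg <- afm_config(growth_rate_per_s = 0, n_frames = 10,
                    severing_rates = c(far_bare = 0, neighbor_bare = 0.05,
                                       end_cluster = 0.05,
                                       inner_cluster = 0))
  matched <- 0L; events <- 0L
  for (i in 1:10) {
    set.seed(i)
    m <- build_filament_model(cfg, 16, cluster_spec = list(c(7, 10)))
    sim <- simulate_dynamics(m, cfg, seed = 300 + i, render = TRUE)
    if (nrow(sim$log$severing) != 1) next
    ev <- sim$log$severing[1, ]
    if (ev$frame > 8) next  # too late to satisfy the persistence window
    events <- events + 1L
    fr1 <- preprocess_frame(sim$movie$frames[[1]])
    tru <- attr(sim$movie$frames[[1]], "truth")[[1]]
    trc <- trace_backbone(fr1, tru$seed_xy)
    br <- detect_breaks(sim$movie, trc)
    if (nrow(br) != 1) next
    pk <- detect_peaks_along_trace(fr1, trc)
    mm <- match_peaks_to_truth(pk, tru)
    tarc <- approx(mm$arc_nm, mm$true_arc_nm, xout = br$arc_nm[1],
                   rule = 2)$y
    idx <- assign_break_half_helix(tarc, tru$arcs_true_nm,
                                   "pointed_at_start")
    if (br$frame[1] == ev$frame && abs(idx - ev$global_index) <= 1)
      matched <- matched + 1L
    # classification at the event frame matches the logged category
    st <- sim$states_history[[ev$frame]][[1]]$states
    st <- ifelse(st == "decorated", "decorated", "bare")
    expect_equal(classify_severing(ev$global_index, st)$category,
                 ev$category)
  }
  expect_gte(events, 3)
  expect_equal(matched, events)
})
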