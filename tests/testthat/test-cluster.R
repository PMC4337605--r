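# Decoration classification, cluster delimitation, neighbor tables,
# growth events, direction preference.

test_that("decoration threshold rule matches the printed modes and the tie convention", {
  expect_equal(classify_decoration(c(10.6, 8.6, 9.6)),
               c("decorated", "bare", "decorated"))
  hh <- data.frame(mean_peak_height_nm = c(8.0, 9.59, 9.61))
  expect_equal(classify_decoration(hh), c("bare", "bare", "decorated"))
})

test_that("classification error rate equals the Gaussian tail overlap at 9.6 nm", {
  set.seed(70)
  n <- 40000
  bare <- rnorm(n, 8.6, 0.8)
  dec <- rnorm(n, 10.6, 1.0)
  err_bare <- mean(classify_decoration(bare) == "decorated")
  err_dec <- mean(classify_decoration(dec) == "bare")
  p_bare <- pnorm(9.6, 8.6, 0.8, lower.tail = FALSE)
  p_dec <- pnorm(9.6, 10.6, 1.0)
  expect_lt(abs(err_bare - p_bare), 3 * sqrt(p_bare * (1 - p_bare) / n))
  expect_lt(abs(err_dec - p_dec), 3 * sqrt(p_dec * (1 - p_dec) / n))
})

test_that("find_clusters returns maximal decorated runs (exhaustive check)", {
  expect_equal(nrow(find_clusters(rep("bare", 6))), 0)
  cl <- find_clusters(c("bare", "decorated", "decorated", "bare", "decorated"))
  expect_equal(cl$first, c(2, 5))
  expect_equal(cl$last, c(3, 5))
  # all 2^12 state strings against brute-force run enumeration
  ok <- vapply(0:(2^12 - 1), function(code) {
    states <- ifelse(bitwAnd(code, 2^(0:11)) > 0, "decorated", "bare")
    identical(find_clusters(states), runs_oracle(states))
  }, logical(1))
  expect_true(all(ok))
})

test_that("neighbor positions respect polarity, ends and double claims", {
  # cluster [5,8] of 12, pointed at start: P1=4, P2=3, B1=9, B2=10
  idx <- afmhelix:::neighbor_positions(data.frame(first = 5L, last = 8L),
                                       12L, "pointed_at_start")
  expect_equal(idx$index[match(c("P1", "P2", "B1", "B2"), idx$position)],
               c(4L, 3L, 9L, 10L))
  # flipped polarity swaps sides
  idx2 <- afmhelix:::neighbor_positions(data.frame(first = 5L, last = 8L),
                                        12L, "pointed_at_end")
  expect_equal(idx2$index[match(c("P1", "P2", "B1", "B2"), idx2$position)],
               c(9L, 10L, 4L, 3L))
  # cluster at the filament start: pointed-side entries fall off and are
  # excluded
  idx3 <- afmhelix:::neighbor_positions(data.frame(first = 1L, last = 3L),
                                        12L, "pointed_at_start")
  expect_false(any(idx3$position %in% c("P1", "P2")))
  # two clusters sharing a bare gap of 3: the middle half helix (B2 of the
  # left cluster and P2 of the right) is claimed twice and dropped
  idx4 <- afmhelix:::neighbor_positions(
    data.frame(first = c(3L, 8L), last = c(4L, 9L)), 12L, "pointed_at_start")
  expect_false(6L %in% idx4$index)
  expect_true(all(c(5L, 7L) %in% idx4$index))  # B1/P1 keep their claims
})

test_that("neighbor_pitch_table pools clusters and excludes decorated entries", {
  hh <- data.frame(
    pitch_nm = c(36, 37, 35, 28.8, 26.9, 26.9, 37.3, 36.5, 36, 37),
    mean_peak_height_nm = c(8.6, 8.6, 8.6, 9.2, 10.6, 10.6, 9.0, 8.8, 8.6, 8.6),
    state = c("bare", "bare", "bare", "bare", "decorated", "decorated",
              "bare", "bare", "bare", "bare"))
  tab <- neighbor_pitch_table(hh, "pointed_at_start")
  expect_equal(tab$n, rep(1L, 4))
  expect_equal(tab$pitch_mean_nm[tab$position == "P1"], 28.8)
  expect_equal(tab$pitch_mean_nm[tab$position == "B1"], 37.3)
  # all-bare filament: empty table
  hh2 <- hh; hh2$state <- "bare"
  expect_equal(nrow(neighbor_pitch_table(hh2, "pointed_at_start")), 0)
})

test_that("growth events count gained half helices per side", {
  # [5,8] -> [4,8]: one pointed event
  ev <- detect_growth_events(list(data.frame(first = 5L, last = 8L),
                                  data.frame(first = 4L, last = 8L)),
                             "pointed_at_start")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "pointed")
  # [5,8] -> [3,9]: two pointed + one barbed
  ev2 <- detect_growth_events(list(data.frame(first = 5L, last = 8L),
                                   data.frame(first = 3L, last = 9L)),
                              "pointed_at_start")
  expect_equal(sum(ev2$direction == "pointed"), 2)
  expect_equal(sum(ev2$direction == "barbed"), 1)
  # losses ignored; nucleations are not growth
  ev3 <- detect_growth_events(list(data.frame(first = 5L, last = 8L),
                                   data.frame(first = c(6L, 11L),
                                              last = c(7L, 12L))),
                              "pointed_at_start")
  expect_equal(nrow(ev3), 0)
  # polarity flip inverts directions
  ev4 <- detect_growth_events(list(data.frame(first = 5L, last = 8L),
                                   data.frame(first = 4L, last = 8L)),
                              "pointed_at_end")
  expect_equal(ev4$direction, "barbed")
})

test_that("simulated growth is recovered one-for-one from cluster spans", {
  cfg <- afm_config(growth_rate_per_s = 0.3, growth_bias_pointed = 0.8,
                    severing_rates = c(far_bare = 0, neighbor_bare = 0,
                                       end_cluster = 0, inner_cluster = 0))
  set.seed(71)
  m <- build_filament_model(cfg, 50, cluster_spec = list(c(24, 26)))
  sim <- simulate_dynamics(m, cfg, n_frames = 80, seed = 72, render = FALSE)
  det <- detect_growth_events(true_clusters_by_frame(sim), sim$polarity)
  expect_equal(nrow(det), nrow(sim$log$growth))
  expect_equal(sum(det$direction == "pointed"),
               sum(sim$log$growth$direction == "pointed"))
})

test_that("direction preference reports exact binomial intervals", {
  expect_error(direction_preference(character(0)), "no growth")
  d1 <- direction_preference(rep("pointed", 10))
  expect_equal(d1$fraction_pointed, 1)
  d2 <- direction_preference(c(rep("pointed", 5), rep("barbed", 5)))
  expect_equal(d2$fraction_pointed, 0.5)
  expect_lt(d2$ci_low, 0.5); expect_gt(d2$ci_high, 0.5)
  # equals Clopper-Pearson from binom.test
  bt <- binom.test(5, 10)$conf.int
  expect_equal(c(d2$ci_low, d2$ci_high), as.numeric(bt))
})

test_that("interval coverage at beta = 0.7 is approximately 95%", {
  set.seed(73)
  cover <- vapply(1:400, function(i) {
    n <- 150
    k <- rbinom(1, n, 0.7)
    d <- direction_preference(c(rep("pointed", k), rep("barbed", n - k)))
    d$ci_low <= 0.7 && 0.7 <= d$ci_high
  }, logical(1))
  expect_gt(mean(cover), 0.92)
  expect_lte(mean(cover), 1.0)
})
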