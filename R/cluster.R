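#' Classify half helices as cofilin-decorated or bare
#'
#' Threshold rule on the mean bounding-peak height: decorated segments
#' image ~2 nm taller (10.6 +/- 1.0 nm) than bare filament (8.6 +/- 0.8
#' nm), so the default threshold is the midpoint of the two modes,
#' 9.6 nm; heights exactly at the threshold count as decorated (>= rule).
#' With the printed modes the rule's intrinsic error rate is the Gaussian
#' tail overlap at 9.6 nm (~11% of bare above, ~16% of decorated below),
#' which bounds what any per-half-helix threshold can do.
#'
#' @param half_helices data frame with `mean_peak_height_nm` (from
#'   [half_pitches()]) or a numeric vector of heights.
#' @param threshold_nm decision threshold (nm).
#' @return character vector of states, `"decorated"` or `"bare"`.
#' @export
classify_decoration <- function(half_helices, threshold_nm = 9.6) {
  h <- if (is.data.frame(half_helices)) {
    stopifnot("mean_peak_height_nm" %in% names(half_helices))
    half_helices$mean_peak_height_nm
  } else as.numeric(half_helices)
  ifelse(h >= threshold_nm, "decorated", "bare")
}

#' Find cofilin clusters as maximal decorated runs
#'
#' @param states character vector of per-half-helix states ordered along
#'   the filament (`"decorated"` vs anything else).
#' @return data frame with one row per cluster: `first`, `last` (1-based
#'   inclusive half-helix indices). Clusters are disjoint and maximal by
#'   construction.
#' @export
find_clusters <- function(states) {
  dec <- states == "decorated"
  if (!any(dec))
    return(data.frame(first = integer(0), last = integer(0)))
  r <- rle(dec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(first = starts[r$values], last = ends[r$values])
}

#' Pitches and heights of bare half helices flanking clusters
#'
#' Reproduces the neighbor-asymmetry table: for every cluster, the first
#' and second bare half helices on the pointed-end side (P1, P2) and on
#' the barbed-end side (B1, B2) are pooled over clusters (and over frames
#' when a pooled data frame is supplied) and summarized. Entries falling
#' off the filament end, onto another cluster, or claimed by two clusters
#' at once (bare gaps of < 2 between clusters) are excluded, and `n`
#' reflects the exclusions.
#'
#' @param half_helices data frame with `pitch_nm`, `mean_peak_height_nm`
#'   and a `state` column (`"decorated"`/`"bare"`), ordered along the
#'   filament; or a list of such data frames (one per filament/frame) to
#'   pool.
#' @param polarity `"pointed_at_start"` (index 1 is the pointed end) or
#'   `"pointed_at_end"`.
#' @return data frame with rows P1, P2, B1, B2: `position`, `n`,
#'   `pitch_mean_nm`, `pitch_sd_nm`, `height_mean_nm`, `height_sd_nm`.
#' @export
neighbor_pitch_table <- function(half_helices,
                                 polarity = c("pointed_at_start",
                                              "pointed_at_end")) {
  polarity <- match.arg(polarity)
  hh_list <- if (is.data.frame(half_helices)) list(half_helices)
  else half_helices
  pooled <- do.call(rbind, lapply(hh_list, function(hh) {
    idx <- neighbor_positions(find_clusters(hh$state), nrow(hh), polarity)
    if (!nrow(idx)) return(NULL)
    ok <- hh$state[idx$index] != "decorated" &
      !is.na(hh$pitch_nm[idx$index])  # unmeasured entries are excluded
    idx <- idx[ok, , drop = FALSE]
    data.frame(position = idx$position,
               pitch_nm = hh$pitch_nm[idx$index],
               height_nm = hh$mean_peak_height_nm[idx$index])
  }))
  positions <- c("P1", "P2", "B1", "B2")
  if (is.null(pooled) || !nrow(pooled)) {
    return(data.frame(position = character(0), n = integer(0),
                      pitch_mean_nm = numeric(0), pitch_sd_nm = numeric(0),
                      height_mean_nm = numeric(0), height_sd_nm = numeric(0)))
  }
  out <- do.call(rbind, lapply(positions, function(p) {
    v <- pooled[pooled$position == p, , drop = FALSE]
    if (!nrow(v)) return(NULL)
    data.frame(position = p, n = nrow(v),
               pitch_mean_nm = mean(v$pitch_nm),
               pitch_sd_nm = stats::sd(v$pitch_nm),
               height_mean_nm = mean(v$height_nm),
               height_sd_nm = stats::sd(v$height_nm))
  }))
  rownames(out) <- NULL
  out
}

# Per-cluster neighbor indices; drops off-filament entries and indices
# claimed by two clusters for the same depth (ambiguous bare gaps).
neighbor_positions <- function(clusters, n, polarity) {
  if (!nrow(clusters))
    return(data.frame(cluster = integer(0), position = character(0),
                      index = integer(0)))
  toward_pointed <- if (polarity == "pointed_at_start") -1L else 1L
  rows <- list()
  for (k in seq_len(nrow(clusters))) {
    p_edge <- if (toward_pointed == -1L) clusters$first[k] else clusters$last[k]
    b_edge <- if (toward_pointed == -1L) clusters$last[k] else clusters$first[k]
    cand <- data.frame(
      cluster = k,
      position = c("P1", "P2", "B1", "B2"),
      index = c(p_edge + toward_pointed, p_edge + 2L * toward_pointed,
                b_edge - toward_pointed, b_edge - 2L * toward_pointed)
    )
    rows[[k]] <- cand[cand$index >= 1L & cand$index <= n, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  dup <- out$index %in% out$index[duplicated(out$index)]
  out[!dup, , drop = FALSE]
}

#' Detect cluster growth events between consecutive frames
#'
#' Clusters in consecutive frames are matched by maximal half-helix span
#' overlap (ties resolved toward the lower span start and flagged;
#' clusters with no overlap in the earlier frame are nucleations, not
#' growth). For each matched pair, every half helix gained on the
#' pointed-end side yields one pointed growth event and every half helix
#' gained on the barbed side one barbed event — growth by one half helix
#' is one event. Losses (shrinkage) are ignored.
#'
#' @param clusters_by_frame list over frames of cluster data frames
#'   (`first`, `last`), as from [find_clusters()] per frame.
#' @param polarity `"pointed_at_start"` or `"pointed_at_end"`.
#' @return data frame of growth events: `frame` (the later frame of the
#'   pair), `cluster_id` (row in that frame's cluster table), `direction`
#'   (`"pointed"`/`"barbed"`), `n_half_helices` (always 1),
#'   `ambiguous_match` flag.
#' @export
detect_growth_events <- function(clusters_by_frame,
                                 polarity = c("pointed_at_start",
                                              "pointed_at_end")) {
  polarity <- match.arg(polarity)
  events <- list()
  for (f in seq_along(clusters_by_frame)[-1L]) {
    prev <- clusters_by_frame[[f - 1L]]
    cur <- clusters_by_frame[[f]]
    if (!nrow(prev) || !nrow(cur)) next
    for (j in seq_len(nrow(cur))) {
      ov <- pmin(cur$last[j], prev$last) - pmax(cur$first[j], prev$first) + 1L
      ov[ov < 0L] <- 0L
      if (max(ov) == 0L) next  # nucleation
      best <- which(ov == max(ov))
      flagged <- length(best) > 1L
      i <- best[which.min(prev$first[best])]
      start_gain <- max(0L, prev$first[i] - cur$first[j])
      end_gain <- max(0L, cur$last[j] - prev$last[i])
      low_dir <- if (polarity == "pointed_at_start") "pointed" else "barbed"
      high_dir <- if (polarity == "pointed_at_start") "barbed" else "pointed"
      add <- function(dir, times) {
        if (times > 0L)
          events[[length(events) + 1L]] <<- data.frame(
            frame = f, cluster_id = j, direction = rep(dir, times),
            n_half_helices = 1L, ambiguous_match = flagged)
      }
      add(low_dir, start_gain)
      add(high_dir, end_gain)
    }
  }
  if (!length(events))
    return(data.frame(frame = integer(0), cluster_id = integer(0),
                      direction = character(0), n_half_helices = integer(0),
                      ambiguous_match = logical(0)))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Directional preference of cluster growth
#'
#' Point estimate of the pointed-end fraction of growth events with its
#' exact (Clopper-Pearson) 95% binomial confidence interval.
#'
#' @param events growth-event data frame with a `direction` column, or a
#'   character vector of directions.
#' @return list: `n_total`, `n_pointed`, `fraction_pointed`, `ci_low`,
#'   `ci_high`.
#' @export
direction_preference <- function(events) {
  dirs <- if (is.data.frame(events)) events$direction else events
  if (!length(dirs)) stop("no growth events")
  if (!all(dirs %in% c("pointed", "barbed")))
    stop("directions must be 'pointed' or 'barbed'")
  n <- length(dirs)
  np <- sum(dirs == "pointed")
  ci <- stats::binom.test(np, n)$conf.int
  list(n_total = n, n_pointed = np, fraction_pointed = np / n,
       ci_low = ci[1L], ci_high = ci[2L])
}
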