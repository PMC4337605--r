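#' Detect filament breaks in a movie
#'
#' A severing event appears as a new gap along a previously continuous
#' filament. The height profile is sampled along a reference trace in
#' every frame; interior runs of below-floor samples at least
#' `gap_threshold_nm` long are gaps. A break is reported at the first
#' frame where a new gap (no overlapping gap in the previous frame)
#' appears and persists for at least `persistence_frames` consecutive
#' frames, which rejects one-frame imaging dropouts. The event is stamped
#' with the last pre-break frame (decoration states should be read there:
#' post-break retraction corrupts them) and the arc midpoint of the gap
#' when it first appears.
#'
#' @param movie an `afm_movie`.
#' @param trace reference `afm_trace` along the intact filament (from a
#'   pre-break frame).
#' @param gap_threshold_nm minimum gap length counted as a break.
#' @param persistence_frames frames a gap must persist.
#' @param height_floor_nm height below which a sample counts as substrate.
#' @return data frame of breaks: `frame` (last frame before the gap),
#'   `frame_detected` (first frame with the gap), `arc_nm` (gap
#'   midpoint in the reference trace's arc coordinates).
#' @export
detect_breaks <- function(movie, trace, gap_threshold_nm = 10,
                          persistence_frames = 2L,
                          height_floor_nm = 4.0) {
  stopifnot(inherits(movie, "afm_movie"), inherits(trace, "afm_trace"))
  nf <- length(movie$frames)
  gaps <- lapply(movie$frames, function(fr) {
    prof <- frame_height_at(fr, trace$x_nm, trace$y_nm)
    below <- prof < height_floor_nm
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & starts > 1L & ends < length(below)
    out <- data.frame(start_nm = trace$arc_nm[starts[keep]],
                      end_nm = trace$arc_nm[ends[keep]])
    out[out$end_nm - out$start_nm >= gap_threshold_nm, , drop = FALSE]
  })

  overlaps <- function(g, tbl) {
    if (!nrow(tbl)) return(FALSE)
    any(pmin(g$end_nm, tbl$end_nm) - pmax(g$start_nm, tbl$start_nm) > 0)
  }

  events <- list()
  for (f in seq_len(nf)) {
    gf <- gaps[[f]]
    if (!nrow(gf)) next
    for (k in seq_len(nrow(gf))) {
      g <- gf[k, , drop = FALSE]
      if (f > 1L && overlaps(g, gaps[[f - 1L]])) next  # not new
      persists <- TRUE
      if (persistence_frames > 1L) {
        need <- f + seq_len(persistence_frames - 1L)
        if (max(need) > nf) { persists <- FALSE }
        else persists <- all(vapply(need, function(ff)
          overlaps(g, gaps[[ff]]), logical(1)))
      }
      if (persists)
        events[[length(events) + 1L]] <- data.frame(
          frame = f - 1L, frame_detected = f,
          arc_nm = (g$start_nm + g$end_nm) / 2)
    }
  }
  if (!length(events))
    return(data.frame(frame = integer(0), frame_detected = integer(0),
                      arc_nm = numeric(0)))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Map a break arc onto a half-helix index
#'
#' The break belongs to the half helix whose interval contains the gap
#' midpoint; a midpoint landing exactly on a crossover peak goes to the
#' pointed-side interval.
#'
#' @param arc_nm gap midpoint (nm).
#' @param peak_arcs strictly increasing crossover arc coordinates of the
#'   pre-break filament.
#' @param polarity `"pointed_at_start"` or `"pointed_at_end"`.
#' @return half-helix index in `1 .. length(peak_arcs) - 1`.
#' @export
assign_break_half_helix <- function(arc_nm, peak_arcs,
                                    polarity = c("pointed_at_start",
                                                 "pointed_at_end")) {
  polarity <- match.arg(polarity)
  if (any(diff(peak_arcs) <= 0))
    stop("`peak_arcs` must be strictly increasing")
  n <- length(peak_arcs) - 1L
  if (arc_nm < peak_arcs[1L] || arc_nm > peak_arcs[n + 1L])
    stop("break arc lies outside the filament")
  on_peak <- which(peak_arcs == arc_nm)
  if (length(on_peak)) {
    k <- on_peak[1L]
    idx <- if (polarity == "pointed_at_start") k - 1L else k
    return(min(max(idx, 1L), n))
  }
  findInterval(arc_nm, peak_arcs)
}

#' Classify a severing site into the four boundary categories
#'
#' Categories at half-helix resolution, from the decoration states in the
#' last pre-break frame:
#' \describe{
#'   \item{`end_cluster`}{decorated half helix at a cluster end (adjacent
#'     to a bare half helix or to the physical filament end — the latter
#'     is flagged in `end_of_filament`).}
#'   \item{`inner_cluster`}{decorated half helix with decorated half
#'     helices on both sides.}
#'   \item{`neighbor_bare`}{bare half helix immediately adjacent to a
#'     cluster.}
#'   \item{`far_bare`}{bare half helix more than one half helix away from
#'     any cluster (always the case on cluster-free filaments).}
#' }
#'
#' @param half_helix_index index of the severed half helix.
#' @param states per-half-helix states in the pre-break frame
#'   (`"decorated"` vs bare; generator neighbor states count as bare).
#' @return list: `category`, `end_of_filament` flag.
#' @export
classify_severing <- function(half_helix_index, states) {
  i <- as.integer(half_helix_index)
  n <- length(states)
  if (i < 1L || i > n) stop("half-helix index out of range")
  if (any(is.na(states))) stop("unknown decoration state")
  dec <- states == "decorated"
  at_start <- i == 1L
  at_end <- i == n
  if (dec[i]) {
    edge <- at_start || at_end || !dec[i - 1L] || !dec[i + 1L]
    list(category = if (edge) "end_cluster" else "inner_cluster",
         end_of_filament = at_start || at_end)
  } else {
    near <- (!at_start && dec[i - 1L]) || (!at_end && dec[i + 1L])
    list(category = if (near) "neighbor_bare" else "far_bare",
         end_of_filament = FALSE)
  }
}

severing_categories <- c("far_bare", "neighbor_bare", "end_cluster",
                         "inner_cluster")

#' Tally severing events by category
#'
#' Counts and fractions per category, plus the boundary-proximal pool:
#' events within one half helix of a bare-zone/cluster boundary
#' (`neighbor_bare` + `end_cluster`), the pooled count behind the
#' "severing occurs near, but not necessarily at, the boundary"
#' observation. Fractions are reported raw and rounded to 1%.
#'
#' @param events data frame with a `category` column, or a character
#'   vector of categories.
#' @return list: `n`, `counts` (named, all four categories),
#'   `fractions`, `fractions_pct` (rounded to 1%),
#'   `boundary_proximal_n`, `boundary_proximal_fraction`.
#' @export
tally_severing <- function(events) {
  cats <- if (is.data.frame(events)) events$category else events
  if (!length(cats)) stop("no severing events to tally")
  if (!all(cats %in% severing_categories))
    stop("unknown severing category")
  counts <- table(factor(cats, levels = severing_categories))
  counts <- stats::setNames(as.integer(counts), severing_categories)
  n <- sum(counts)
  fr <- counts / n
  bp <- counts[["neighbor_bare"]] + counts[["end_cluster"]]
  list(n = n, counts = counts, fractions = fr,
       fractions_pct = round(100 * fr),
       boundary_proximal_n = bp,
       boundary_proximal_fraction = bp / n)
}
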