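#' Simulate cofilin cluster growth and severing on a filament
#'
#' Time evolution of a ground-truth filament model at half-helix
#' resolution, optionally rendered into an AFM movie. Per frame interval:
#'
#' * every cofilin cluster (maximal decorated run) extends by one half
#'   helix with probability `growth_rate_per_s * frame_interval_s`,
#'   toward the pointed end with probability `growth_bias_pointed`, else
#'   toward the barbed end. A newly decorated half helix redraws its
#'   pitch and height from the decorated distributions (the supertwist
#'   transition), and the bare half helices flanking the moved boundary
#'   are re-assigned their asymmetric neighbor states;
#' * every half helix severs with probability
#'   `severing_rates[category] * frame_interval_s`, its category taken
#'   from the current decoration states via the same rules as
#'   [classify_severing()]. A severed half helix is removed and the
#'   filament splits into two fragments separated by the resulting gap;
#'   fragments keep their global half-helix indices and arc coordinates.
#'
#' Events are logged with the frame in which the pre-event configuration
#' was last visible. The log is the ground truth against which detection
#' stages are validated: every logged severing corresponds to exactly one
#' new gap in the rendered movie, every logged growth event to one half
#' helix joining a cluster.
#'
#' @param model an `afm_filament_model` (frame-1 configuration).
#' @param config an [afm_config()].
#' @param n_frames number of frames (defaults to `config$n_frames`).
#' @param seed integer seed; `config$seed` when `NULL`.
#' @param render render frames into an `afm_movie` (`TRUE`) or simulate
#'   the lattice only (`FALSE`, much faster).
#' @return object of class `afm_simulation`: list with `movie` (or
#'   `NULL`), `log` (`$growth`, `$severing` data frames), `states_history`
#'   (per frame, a list of fragments each carrying `global_index`,
#'   `states`, `pitch_true_nm`, `arcs_true_nm`), `polarity`, `config`,
#'   `seed`.
#' @export
simulate_dynamics <- function(model, config, n_frames = NULL, seed = NULL,
                              render = TRUE) {
  config <- validate_afm_config(config)
  stopifnot(inherits(model, "afm_filament_model"))
  if (is.null(n_frames)) n_frames <- config$n_frames
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("`n_frames` must be >= 1")
  if (is.null(seed)) seed <- config$seed
  set.seed(as.integer(seed))
  dt <- config$frame_interval_s

  fragments <- list(model)
  frames <- vector("list", n_frames)
  history <- vector("list", n_frames)
  growth <- list()
  severing <- list()

  for (f in seq_len(n_frames)) {
    if (render) {
      # independent, reproducible render stream per frame
      frames[[f]] <- render_frame(fragments, config,
                                  seed = derive_seed(seed, 7919 * f),
                                  t_s = (f - 1L) * dt)
    }
    # dynamics stream is per frame and independent of rendering, so the
    # lattice evolution is identical for render = TRUE and FALSE
    set.seed(derive_seed(seed, 104729 + f))
    history[[f]] <- lapply(fragments, function(m)
      list(global_index = m$global_index,
           states = m$half_helices$state,
           pitch_true_nm = m$half_helices$pitch_true_nm,
           arcs_true_nm = model_peak_arcs(m)))
    if (f == n_frames) break

    # --- growth ---
    for (g in seq_along(fragments)) {
      frag <- fragments[[g]]
      cl <- find_clusters(frag$half_helices$state)
      if (!nrow(cl)) next
      for (k in seq_len(nrow(cl))) {
        if (stats::runif(1L) >= config$growth_rate_per_s * dt) next
        pointed <- stats::runif(1L) < config$growth_bias_pointed
        target <- if (pointed) cl$first[k] - 1L else cl$last[k] + 1L
        if (target < 1L || target > nrow(frag$half_helices)) next
        if (frag$half_helices$state[target] == "decorated") next
        frag <- decorate_half_helix(frag, target, config)
        fragments[[g]] <- frag
        growth[[length(growth) + 1L]] <- data.frame(
          frame = f,
          direction = if (pointed) "pointed" else "barbed",
          global_index = frag$global_index[target])
      }
    }

    # --- severing (at most one split per fragment per interval) ---
    g <- 1L
    while (g <= length(fragments)) {
      frag <- fragments[[g]]
      st <- frag$half_helices$state
      st_eff <- ifelse(st == "decorated", "decorated", "bare")
      cats <- vapply(seq_along(st_eff), function(i)
        classify_severing(i, st_eff)$category, character(1))
      p <- config$severing_rates[cats] * dt
      hit <- which(stats::runif(length(p)) < p)
      if (length(hit)) {
        j <- hit[1L]
        arcs <- model_peak_arcs(frag)
        severing[[length(severing) + 1L]] <- data.frame(
          frame = f,
          global_index = frag$global_index[j],
          category = cats[j],
          arc_nm = (arcs[j] + arcs[j + 1L]) / 2)
        pieces <- split_fragment(frag, j)
        fragments <- append(fragments[-g], pieces, after = g - 1L)
        g <- g + length(pieces)
      } else {
        g <- g + 1L
      }
    }
  }

  movie <- if (render)
    afm_movie(frames, frame_interval_s = dt) else NULL
  structure(
    list(movie = movie,
         log = list(
           growth = bind_event_rows(growth,
                                    c("frame", "direction", "global_index")),
           severing = bind_event_rows(severing,
                                      c("frame", "global_index", "category",
                                        "arc_nm"))),
         states_history = history,
         polarity = model$polarity,
         config = config,
         seed = as.integer(seed)),
    class = "afm_simulation"
  )
}

# Independent sub-stream seeds: multiplicative mixing (Lehmer-style
# constants) keeps (seed, offset) pairs from colliding additively — e.g.
# replicate i at frame f must not share a stream with replicate i+1 at
# frame f-1 — and stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 16807 +
                (as.numeric(seed) * as.numeric(offset)) %% 65213) %%
               2147483629)
}

bind_event_rows <- function(rows, cols) {
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                       cols))
  out
}

# Convert one half helix to the decorated state and refresh the asymmetric
# neighbor states around every cluster boundary it touches.
decorate_half_helix <- function(frag, target, config) {
  hh <- frag$half_helices
  st <- config$states$decorated
  hh$state[target] <- "decorated"
  hh$pitch_true_nm[target] <- rnorm_trunc(1L, st$pitch_mean_nm,
                                          st$pitch_sd_struct_nm, lower = 10)
  hh$peak_height_true_nm[target] <- rnorm_trunc(1L, st$peak_height_mean_nm,
                                                st$peak_height_sd_nm,
                                                lower = 1)
  n <- nrow(hh)
  for (idx in c(target - 1L, target + 1L)) {
    if (idx < 1L || idx > n || hh$state[idx] == "decorated") next
    wanted <- if (idx < target) "p_neighbor" else "b_neighbor"
    if (hh$state[idx] != wanted) {
      stn <- config$states[[wanted]]
      hh$state[idx] <- wanted
      hh$pitch_true_nm[idx] <- rnorm_trunc(1L, stn$pitch_mean_nm,
                                           stn$pitch_sd_struct_nm,
                                           lower = 10)
      hh$peak_height_true_nm[idx] <- rnorm_trunc(1L,
                                                 stn$peak_height_mean_nm,
                                                 stn$peak_height_sd_nm,
                                                 lower = 1)
    }
  }
  frag$half_helices <- hh
  frag
}

# Remove half helix j: the fragment splits into the pieces before and
# after it; each piece keeps global indices and its global arc offset.
split_fragment <- function(frag, j) {
  n <- nrow(frag$half_helices)
  pieces <- list()
  if (j > 1L) {
    left <- frag
    left$half_helices <- frag$half_helices[seq_len(j - 1L), , drop = FALSE]
    left$global_index <- frag$global_index[seq_len(j - 1L)]
    left$severed_ends["end"] <- TRUE  # abrupt, newly created end
    pieces[[length(pieces) + 1L]] <- left
  }
  if (j < n) {
    right <- frag
    right$half_helices <- frag$half_helices[(j + 1L):n, , drop = FALSE]
    right$global_index <- frag$global_index[(j + 1L):n]
    right$arc_offset_nm <- frag$arc_offset_nm +
      sum(frag$half_helices$pitch_true_nm[seq_len(j)])
    right$severed_ends["start"] <- TRUE
    pieces[[length(pieces) + 1L]] <- right
  }
  pieces
}

#' @export
print.afm_simulation <- function(x, ...) {
  cat(sprintf("<afm_simulation> %d frame(s), %d growth / %d severing events%s\n",
              length(x$states_history), nrow(x$log$growth),
              nrow(x$log$severing),
              if (is.null(x$movie)) " (lattice only)" else ""))
  invisible(x)
}

#' Per-frame cluster tables from a simulation's ground truth
#'
#' Maximal decorated runs in each frame of [simulate_dynamics()] output,
#' in global half-helix indices — the lattice-resolution cluster movie
#' used to validate growth-event detection against the ground-truth log.
#'
#' @param sim an `afm_simulation`.
#' @return list over frames of cluster data frames (`first`, `last`).
#' @export
true_clusters_by_frame <- function(sim) {
  stopifnot(inherits(sim, "afm_simulation"))
  lapply(sim$states_history, function(frs) {
    rows <- lapply(frs, function(fr) {
      cl <- find_clusters(fr$states)
      if (!nrow(cl)) return(NULL)
      data.frame(first = fr$global_index[cl$first],
                 last = fr$global_index[cl$last])
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) data.frame(first = integer(0), last = integer(0))
    else out[order(out$first), , drop = FALSE]
  })
}
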