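#' Link two consecutive frames by greedy nearest-neighbor assignment
#'
#' Greedy globally-shortest-first matching on 3D Euclidean distance: among
#' all unmatched (observation at t, observation at t+1) pairs, repeatedly
#' link the pair with the smallest distance, as long as it does not exceed
#' `max_disp_um`. Unmatched observations at t end their tracks; unmatched
#' observations at t+1 start new tracks. Nearest-neighbor linking is valid
#' when the inter-frame displacement is small against the inter-cell
#' spacing; greedy shortest-first strictly dominates naive per-cell nearest
#' neighbor (it cannot assign one target twice) and recovers the true
#' matching whenever each true pair is mutually nearest. Ties are broken by
#' (observation index at t, observation index at t+1), so the assignment is
#' deterministic.
#'
#' @param obs_t,obs_t1 data.frames with columns `x_um`, `y_um`, `z_um`
#'   (rows = observations of the two consecutive frames).
#' @param max_disp_um maximum link distance (um, > 0; default 30, i.e. a
#'   3 um/min gate at 10-min frames, several times the typical macrophage
#'   speed).
#' @return data.frame with columns `from` (row in `obs_t`), `to` (row in
#'   `obs_t1`), `dist_um`; zero rows if either input is empty.
#' @export
link_frames <- function(obs_t, obs_t1, max_disp_um = 30) {
  if (max_disp_um <= 0) stop("'max_disp_um' must be positive")
  n <- nrow(obs_t); m <- nrow(obs_t1)
  empty <- data.frame(from = integer(), to = integer(), dist_um = numeric())
  if (is.null(n) || is.null(m) || n == 0L || m == 0L) return(empty)
  D <- sqrt(outer(obs_t$x_um, obs_t1$x_um, `-`)^2 +
              outer(obs_t$y_um, obs_t1$y_um, `-`)^2 +
              outer(obs_t$z_um, obs_t1$z_um, `-`)^2)
  ri <- as.vector(row(D)); ci <- as.vector(col(D)); dv <- as.vector(D)
  ord <- order(dv, ri, ci)
  used_t <- logical(n); used_t1 <- logical(m)
  from <- integer(); to <- integer(); dd <- numeric()
  for (k in ord) {
    if (dv[k] > max_disp_um) break
    i <- ri[k]; j <- ci[k]
    if (used_t[i] || used_t1[j]) next
    used_t[i] <- TRUE; used_t1[j] <- TRUE
    from <- c(from, i); to <- c(to, j); dd <- c(dd, dv[k])
    if (all(used_t) || all(used_t1)) break
  }
  data.frame(from = from, to = to, dist_um = dd)
}

#' Build trajectories from per-frame observations
#'
#' Chains [link_frames()] over the time series. Track ids are stable for a
#' run: tracks are numbered in order of appearance (frame, then observation
#' order within the frame). A track's `complete` flag records whether it
#' spans every frame of the series with no internal gaps (a span-based
#' operational definition).
#'
#' @param observations data.frame with one row per detection; required
#'   columns `frame` (integer), `t_min`, `x_um`, `y_um`, `z_um`; any further
#'   columns (shape parameters, CI bounds, flags, ...) are carried through.
#' @param max_disp_um link distance gate, see [link_frames()].
#' @param max_gap maximum number of missed frames a track may bridge
#'   (default 0: a cell missing in one frame ends its track).
#' @return An object of class `cell_tracks`: list with `observations` (the
#'   input plus `track_id` and `obs_id` columns), `frames` (sorted frame
#'   indices of the series), `edit_log` (list, empty).
#' @export
build_trajectories <- function(observations, max_disp_um = 30, max_gap = 0L) {
  obs <- as.data.frame(observations)
  req <- c("frame", "t_min", "x_um", "y_um", "z_um")
  if (!all(req %in% names(obs)))
    stop("observations need columns ", paste(req, collapse = ", "))
  obs <- obs[order(obs$frame), , drop = FALSE]
  rownames(obs) <- NULL
  obs$obs_id <- seq_len(nrow(obs))
  obs$track_id <- NA_integer_
  frames <- sort(unique(obs$frame))
  next_id <- 1L
  # active track bookkeeping: id -> row index of its last observation
  active_rows <- integer()
  for (f in frames) {
    rows_f <- which(obs$frame == f)
    if (length(active_rows)) {
      last_frames <- obs$frame[active_rows]
      eligible <- which(f - last_frames <= max_gap + 1L)
    } else eligible <- integer()
    if (length(eligible) && length(rows_f)) {
      lnk <- link_frames(obs[active_rows[eligible], , drop = FALSE],
                         obs[rows_f, , drop = FALSE], max_disp_um)
      if (nrow(lnk)) {
        obs$track_id[rows_f[lnk$to]] <-
          obs$track_id[active_rows[eligible][lnk$from]]
        # extended tracks: update last observation
        active_rows[eligible[lnk$from]] <- rows_f[lnk$to]
      }
    }
    new_rows <- rows_f[is.na(obs$track_id[rows_f])]
    if (length(new_rows)) {
      obs$track_id[new_rows] <- seq(next_id, length.out = length(new_rows))
      next_id <- next_id + length(new_rows)
      active_rows <- c(active_rows, new_rows)
    }
    # drop tracks whose gap exceeded the allowance
    keep <- f - obs$frame[active_rows] <= max_gap
    active_rows <- active_rows[keep | obs$frame[active_rows] == f]
  }
  structure(list(observations = obs, frames = frames, edit_log = list()),
            class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  nt <- length(unique(x$observations$track_id))
  cat(sprintf("<cell_tracks> %d observation(s) in %d track(s) over %d frame(s), %d edit(s)\n",
              nrow(x$observations), nt, length(x$frames), length(x$edit_log)))
  invisible(x)
}

#' @export
summary.cell_tracks <- function(object, ...) {
  obs <- object$observations
  lens <- table(obs$track_id)
  comp <- track_completeness(object)
  cat(sprintf("cell_tracks: %d tracks, %d observations, frames %d..%d\n",
              length(lens), nrow(obs), min(object$frames), max(object$frames)))
  cat(sprintf("  track length: median %g, range %d..%d\n",
              stats::median(as.integer(lens)), min(lens), max(lens)))
  cat(sprintf("  complete tracks (full span, no gaps): %d (%.0f%%)\n",
              sum(comp$complete), 100 * mean(comp$complete)))
  invisible(object)
}

#' Span-based completeness of each track
#'
#' @param tracks a `cell_tracks` object.
#' @return data.frame with `track_id`, `n_obs`, `first_frame`, `last_frame`,
#'   `complete` (spans all frames of the series with no internal gaps).
#' @export
track_completeness <- function(tracks) {
  obs <- tracks$observations
  ids <- sort(unique(obs$track_id))
  all_f <- tracks$frames
  out <- lapply(ids, function(id) {
    fr <- sort(obs$frame[obs$track_id == id])
    span <- all_f[all_f >= fr[1L] & all_f <= fr[length(fr)]]
    data.frame(track_id = id, n_obs = length(fr), first_frame = fr[1L],
               last_frame = fr[length(fr)],
               complete = identical(fr, all_f))
  })
  do.call(rbind, out)
}

.validate_tracks <- function(tracks) {
  obs <- tracks$observations
  if (anyDuplicated(obs$obs_id)) stop("duplicated observation")
  for (id in unique(obs$track_id)) {
    fr <- obs$frame[obs$track_id == id]
    if (anyDuplicated(fr))
      stop(sprintf("track %d has two observations in one frame", id))
  }
  invisible(tracks)
}

#' Manual track correction
#'
#' Automated nearest-neighbor linking can fail under fast migration, high
#' local cell density or optical artifacts; edits let the user repair such
#' tracks. Every edit is appended to the track set's `edit_log` (so a raw
#' track set plus its edit log reproduces the corrected set) and the track
#' invariants (strictly increasing frames, one track per observation) are
#' re-validated.
#'
#' Supported edits:
#' * `relink`: move the observations of `from_track` at `at_frame` and later
#'   onto `to_track`; rejected if the target track already has observations
#'   in those frames or later.
#' * `split`: cut `from_track` at `at_frame`; observations from that frame
#'   on form a new track.
#' * `merge`: append `from_track` onto `to_track`; rejected if the two
#'   tracks overlap in time.
#'
#' @param tracks a `cell_tracks` object.
#' @param type `"relink"`, `"split"` or `"merge"`.
#' @param from_track,to_track,at_frame edit arguments (see above).
#' @return the edited `cell_tracks`.
#' @export
apply_edit <- function(tracks, type = c("relink", "split", "merge"),
                       from_track = NULL, to_track = NULL, at_frame = NULL) {
  stopifnot(inherits(tracks, "cell_tracks"))
  type <- match.arg(type)
  obs <- tracks$observations
  has <- function(id) id %in% obs$track_id
  if (!is.null(from_track) && !has(from_track)) stop("unknown 'from_track'")
  if (type == "relink") {
    if (is.null(to_track) || !has(to_track)) stop("unknown 'to_track'")
    if (is.null(at_frame)) stop("'at_frame' required")
    mv <- obs$track_id == from_track & obs$frame >= at_frame
    if (!any(mv)) stop("no observations of 'from_track' at or after 'at_frame'")
    if (any(obs$track_id == to_track & obs$frame >= min(obs$frame[mv])))
      stop("edit rejected: target track already extends into those frames")
    obs$track_id[mv] <- to_track
  } else if (type == "split") {
    if (is.null(at_frame)) stop("'at_frame' required")
    mv <- obs$track_id == from_track & obs$frame >= at_frame
    if (!any(mv)) stop("nothing to split: no observations at or after 'at_frame'")
    new_id <- max(obs$track_id) + 1L
    obs$track_id[mv] <- new_id
  } else {  # merge
    if (is.null(to_track) || !has(to_track)) stop("unknown 'to_track'")
    fa <- obs$frame[obs$track_id == from_track]
    fb <- obs$frame[obs$track_id == to_track]
    if (length(intersect(fa, fb)))
      stop("edit rejected: tracks overlap in time")
    obs$track_id[obs$track_id == from_track] <- to_track
  }
  tracks$observations <- obs
  tracks$edit_log <- c(tracks$edit_log,
                       list(list(type = type, from_track = from_track,
                                 to_track = to_track, at_frame = at_frame,
                                 time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))))
  .validate_tracks(tracks)
}

#' Save / replay an edit log
#'
#' The edit log is stored as JSON so that a raw track set can be
#' re-corrected reproducibly.
#'
#' @param tracks a `cell_tracks` object.
#' @param path JSON file path.
#' @return `write_edit_log` returns `path` invisibly; `replay_edits`
#'   returns the edited `cell_tracks`.
#' @export
write_edit_log <- function(tracks, path) {
  jsonlite::write_json(tracks$edit_log, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_edit_log
#' @param raw_tracks a `cell_tracks` object without the edits.
#' @export
replay_edits <- function(raw_tracks, path) {
  edits <- jsonlite::read_json(path)
  for (e in edits)
    raw_tracks <- apply_edit(raw_tracks, e$type,
                             from_track = e$from_track,
                             to_track = e$to_track, at_frame = e$at_frame)
  raw_tracks
}

#' Per-track migration statistics
#'
#' Step speed is the 3D Euclidean displacement between consecutive
#' observations divided by the actual elapsed time (so a bridged gap uses
#' the full time across the gap). Mean speed is the average of step speeds;
#' path length is the sum of displacements.
#'
#' @param tracks a `cell_tracks` object.
#' @param track_id if given, return the detailed statistics of one track
#'   (list with `step_speeds_um_min`, `step_dt_min`, `mean_speed_um_min`,
#'   `path_length_um`, `duration_min`); a single-observation track yields an
#'   empty speed vector. Otherwise a per-track summary data.frame.
#' @return see `track_id`.
#' @export
migration_stats <- function(tracks, track_id = NULL) {
  stopifnot(inherits(tracks, "cell_tracks"))
  one <- function(id) {
    tr <- tracks$observations[tracks$observations$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2L)
      return(list(track_id = id, step_speeds_um_min = numeric(),
                  step_dt_min = numeric(), mean_speed_um_min = NA_real_,
                  path_length_um = 0, duration_min = 0))
    disp <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2 + diff(tr$z_um)^2)
    dt <- diff(tr$t_min)
    list(track_id = id, step_speeds_um_min = disp / dt, step_dt_min = dt,
         mean_speed_um_min = mean(disp / dt), path_length_um = sum(disp),
         duration_min = sum(dt))
  }
  if (!is.null(track_id)) {
    if (!track_id %in% tracks$observations$track_id) stop("unknown track id")
    return(one(track_id))
  }
  ids <- sort(unique(tracks$observations$track_id))
  do.call(rbind, lapply(ids, function(id) {
    s <- one(id)
    data.frame(track_id = id, n_steps = length(s$step_speeds_um_min),
               mean_speed_um_min = s$mean_speed_um_min,
               path_length_um = s$path_length_um,
               duration_min = s$duration_min)
  }))
}

#' Population-level speed distribution statistics
#'
#' For each time window, per-cell mean speeds (over the steps whose
#' mid-time falls in the window) are summarized as mean and SD, together
#' with the fraction of cells migrating slower than `slow_um_min` and faster
#' than `fast_um_min` (defaults 0.5 and 2 um/min, the conventional slow and
#' fast bins for macrophage migration).
#'
#' @param tracks a `cell_tracks` object.
#' @param windows_min numeric vector of window breakpoints in minutes
#'   (default: one window covering the whole series).
#' @param slow_um_min,fast_um_min speed bin edges (um/min).
#' @return data.frame with one row per window: `t_start_min`, `t_end_min`,
#'   `n_cells`, `mean_speed_um_min`, `sd_speed_um_min`, `fraction_slow`,
#'   `fraction_fast`. Windows with no steps give `n_cells = 0` and `NA`
#'   statistics.
#' @export
population_stats <- function(tracks, windows_min = NULL,
                             slow_um_min = 0.5, fast_um_min = 2) {
  stopifnot(inherits(tracks, "cell_tracks"))
  obs <- tracks$observations
  if (is.null(windows_min))
    windows_min <- range(obs$t_min)
  if (length(windows_min) < 2L) stop("'windows_min' needs at least 2 breakpoints")
  ids <- sort(unique(obs$track_id))
  steps <- do.call(rbind, lapply(ids, function(id) {
    tr <- obs[obs$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2L) return(NULL)
    disp <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2 + diff(tr$z_um)^2)
    dt <- diff(tr$t_min)
    data.frame(track_id = id, t_mid = (tr$t_min[-1L] + tr$t_min[-nrow(tr)]) / 2,
               speed = disp / dt)
  }))
  out <- lapply(seq_len(length(windows_min) - 1L), function(w) {
    t0 <- windows_min[w]; t1 <- windows_min[w + 1L]
    sel <- if (is.null(steps)) NULL else
      steps[steps$t_mid >= t0 & (steps$t_mid < t1 |
                                   (w == length(windows_min) - 1L & steps$t_mid <= t1)), ]
    if (is.null(sel) || nrow(sel) == 0L)
      return(data.frame(t_start_min = t0, t_end_min = t1, n_cells = 0L,
                        mean_speed_um_min = NA_real_, sd_speed_um_min = NA_real_,
                        fraction_slow = NA_real_, fraction_fast = NA_real_))
    per_cell <- tapply(sel$speed, sel$track_id, mean)
    data.frame(t_start_min = t0, t_end_min = t1, n_cells = length(per_cell),
               mean_speed_um_min = mean(per_cell),
               sd_speed_um_min = if (length(per_cell) > 1L) stats::sd(per_cell) else 0,
               fraction_slow = mean(per_cell < slow_um_min),
               fraction_fast = mean(per_cell > fast_um_min))
  })
  do.call(rbind, out)
}

#' Plot trajectories in the xy-plane
#'
#' @param x a `cell_tracks` object.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.cell_tracks <- function(x, ...) {
  obs <- x$observations
  graphics::plot(range(obs$x_um), range(obs$y_um), type = "n",
                 xlab = "x (um)", ylab = "y (um)", ...)
  ids <- sort(unique(obs$track_id))
  cols <- grDevices::hcl.colors(max(3L, length(ids)), "Dark 3")
  for (i in seq_along(ids)) {
    tr <- obs[obs$track_id == ids[i], , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    graphics::lines(tr$x_um, tr$y_um, col = cols[i])
    graphics::points(tr$x_um[1L], tr$y_um[1L], pch = 16, col = cols[i], cex = 0.6)
  }
  invisible(x)
}
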