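#' Run the full detection-to-tracking pipeline
#'
#' Executes, per frame: min-max normalization, template-correlation
#' classification of every pixel, density filtering, candidate extraction,
#' sub-voxel z-estimation, correlation-gated region growing with collision
#' resolution, and shape parameters; then links the per-frame observations
#' into trajectories. Templates are extracted once from `template_frame`
#' (default the first frame) at the configured coordinates and reused for
#' the whole series. Frames are processed one at a time, so the working set
#' stays bounded by a single stack regardless of series length.
#'
#' The run is fully deterministic: identical inputs and configuration give
#' byte-identical output CSVs.
#'
#' @param input a directory of `frame_%04d.tif` files, a single multi-frame
#'   TIFF (then set `nz`), or a list of [image_stack()]s.
#' @param config a [run_config()] with template coordinates set.
#' @param out_dir if given, `tracks.csv`, `resolved_config.yaml` and
#'   `run_log.txt` are written there (created if missing).
#' @param qc if `TRUE` (and `out_dir` given), per-frame filtered cell maps
#'   and label images are written for visual QC.
#' @param nz z-planes per frame, for the single-file input form.
#' @return a `cell_tracks` object (see [build_trajectories()]); the
#'   observation table carries positions, CI bounds, shape parameters and
#'   flags. The run log is attached as `attr(, "log")`.
#' @export
run_pipeline <- function(input, config, out_dir = NULL, qc = FALSE, nz = NULL) {
  stopifnot(inherits(config, "run_config"))
  use_csv <- !is.null(config$template_cell_csv) &&
    !is.null(config$template_background_csv)
  if (!use_csv &&
      (is.null(config$template_cell_xy) || is.null(config$template_background_xy)))
    stop("config must set template coordinates or template CSV paths")
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  if (is.character(input)) {
    stacks <- read_series(input, config$voxel_size_um,
                          config$frame_interval_min, nz = nz)
  } else stacks <- input
  nf <- length(stacks)
  if (nf == 0L) stop("no input frames")
  say("pipeline start: %d frame(s), voxel %g x %g x %g um", nf,
      config$voxel_size_um[1], config$voxel_size_um[2], config$voxel_size_um[3])

  prep <- function(st) if (config$normalize) normalize_stack(st) else st
  if (use_csv) {
    templates <- template_pair(read_template(config$template_cell_csv),
                               read_template(config$template_background_csv),
                               ref_z_um = config$template_ref_z_um)
    say("templates from CSV: %s, %s, ref z %.3f um",
        config$template_cell_csv, config$template_background_csv,
        templates$ref_z_um)
  } else {
    tf <- config$template_frame
    if (tf < 1L || tf > nf) stop("'template_frame' outside the series")
    templates <- templates_from_stack(prep(stacks[[tf]]),
                                      config$template_cell_xy,
                                      config$template_background_xy,
                                      ref_z_um = config$template_ref_z_um,
                                      patch_radius_px = config$template_patch_px)
    say("templates from frame %d: cell (%d, %d), background (%d, %d), ref z %.3f um",
        tf, config$template_cell_xy[1], config$template_cell_xy[2],
        config$template_background_xy[1], config$template_background_xy[2],
        templates$ref_z_um)
  }

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  obs_rows <- list()
  for (f in seq_len(nf)) {
    st <- prep(stacks[[f]])
    raw <- withCallingHandlers(
      classify_pixels(st, templates),
      warning = function(w) {
        say("frame %d: %s", f, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    filt <- density_filter(raw, config$density_radius_px,
                           config$density_min_fraction)
    cands <- label_candidates(filt, config$voxel_size_um,
                              config$min_area_px)
    say("frame %d: %d raw px, %d filtered px, %d candidate(s)",
        f, sum(raw$mask), sum(filt$mask), length(cands))
    if (qc && !is.null(out_dir))
      write_cell_map(filt, file.path(out_dir, sprintf("cellmap_%04d.tif", f - 1L)))
    if (!length(cands)) next
    gr <- grow_candidates(st, cands, config$corr_threshold)
    if (qc && !is.null(out_dir))
      write_label_image(gr$masks, dim(st$data)[1:2],
                        file.path(out_dir, sprintf("labels_%04d.tif", f - 1L)))
    for (i in seq_along(cands)) {
      ze <- cell_z(cands[[i]], st, templates$cell,
                   central_fraction = config$central_fraction,
                   background = templates$background,
                   ref_z_um = templates$ref_z_um,
                   offset_step_um = config$offset_step_um,
                   stretch_limits = config$stretch_limits,
                   stretch_step = config$stretch_step)
      sp <- if (nrow(gr$masks[[i]]$pixels) >= 4L)
        shape_params(gr$masks[[i]], config$voxel_size_um)
      else {
        say("frame %d candidate %d: grown mask below 4 px, shape from candidate", f, i)
        shape_params(cands[[i]]$pixels, config$voxel_size_um)
      }
      if (nzchar(gr$flags[i]))
        say("frame %d candidate %d: flagged %s", f, i, gr$flags[i])
      obs_rows[[length(obs_rows) + 1L]] <- data.frame(
        frame = f, t_min = st$t_min,
        x_um = cands[[i]]$centroid_xy_um[1L],
        y_um = cands[[i]]$centroid_xy_um[2L],
        z_um = ze$z_um, z_ci_low_um = ze$ci95_um[1L],
        z_ci_high_um = ze$ci95_um[2L],
        area_um2 = sp$area_um2, roundness = sp$roundness,
        aspect_ratio = sp$aspect_ratio,
        orientation_deg = sp$orientation_deg,
        flags = gr$flags[i])
    }
  }

  if (length(obs_rows)) {
    obs <- do.call(rbind, obs_rows)
    tracks <- build_trajectories(obs, config$max_disp_um, config$max_gap)
  } else {
    obs <- data.frame(frame = integer(), t_min = numeric(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(),
                      z_ci_low_um = numeric(), z_ci_high_um = numeric(),
                      area_um2 = numeric(), roundness = numeric(),
                      aspect_ratio = numeric(), orientation_deg = numeric(),
                      flags = character())
    obs$obs_id <- integer()
    obs$track_id <- integer()
    tracks <- structure(list(observations = obs, frames = seq_len(nf),
                             edit_log = list()),
                        class = "cell_tracks")
  }
  say("tracking: %d observation(s) in %d track(s)",
      nrow(tracks$observations),
      length(unique(tracks$observations$track_id)))

  if (!is.null(out_dir)) {
    write_tracks_csv(tracks, file.path(out_dir, "tracks.csv"))
    write_config(config, file.path(out_dir, "resolved_config.yaml"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  attr(tracks, "log") <- log
  tracks
}

#' Write the tracks table as CSV
#'
#' Columns: `frame`, `t_min`, `track_id`, `x_um`, `y_um`, `z_um`,
#' `z_ci_low_um`, `z_ci_high_um`, `area_um2`, `roundness`, `aspect_ratio`,
#' `orientation_deg`, `flags`. Deterministic ordering (frame, then
#' track id).
#'
#' @param tracks a `cell_tracks` object.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "cell_tracks"))
  obs <- tracks$observations
  cols <- c("frame", "t_min", "track_id", "x_um", "y_um", "z_um",
            "z_ci_low_um", "z_ci_high_um", "area_um2", "roundness",
            "aspect_ratio", "orientation_deg", "flags")
  cols <- intersect(cols, names(obs))
  obs <- obs[order(obs$frame, obs$track_id), cols, drop = FALSE]
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Read a tracks CSV back as a `cell_tracks` object
#'
#' @param path a CSV written by [write_tracks_csv()].
#' @return a `cell_tracks` object (without edit history).
#' @export
read_tracks_csv <- function(path) {
  obs <- utils::read.csv(path)
  obs$obs_id <- seq_len(nrow(obs))
  structure(list(observations = obs,
                 frames = sort(unique(obs$frame)),
                 edit_log = list()),
            class = "cell_tracks")
}
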