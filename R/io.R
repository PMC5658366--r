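#' Write a stack as a multi-page TIFF
#'
#' Pages are z-planes in ascending z; each page is stored `[row = y,
#' col = x]` as 32-bit samples. Writing quantizes intensities to the 32-bit
#' grid, so `read(write(x))` is a deterministic quantization of `x` (within
#' `2^-32`) and a second write/read round-trip is the identity.
#'
#' @param stack an [image_stack()] with intensities in `[0, 1]`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(dim(stack$data)[3L]),
                  function(k) t(stack$data[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page TIFF as a stack
#'
#' @param path `.tif` file (pages = z-planes, ascending z).
#' @param voxel_size_um physical voxel size `(dx, dy, dz)` in um; file
#'   metadata is not trusted for geometry.
#' @param frame_index,t_min frame index and acquisition time to record.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_size_um, frame_index = 0L, t_min = 0) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("inconsistent page sizes in '", path, "'")
  nz <- length(pages)
  nx <- dims[2L, 1L]; ny <- dims[1L, 1L]
  data <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) data[, , k] <- t(pages[[k]])
  image_stack(data, voxel_size_um, frame_index = frame_index, t_min = t_min)
}

#' Read a time series of stacks
#'
#' Accepts either a directory of per-frame multi-page TIFFs named
#' `frame_%04d.tif` (pages = z-planes) or a single multi-page TIFF holding
#' all frames in TZYX order, in which case `nz` must be given to split the
#' pages into frames. All frames must have the same number of z-planes.
#'
#' @param path directory or single file.
#' @param voxel_size_um `(dx, dy, dz)` in um (overrides any file metadata).
#' @param frame_interval_min time between frames (min).
#' @param nz z-planes per frame; required for the single-file form.
#' @return list of [image_stack()]s, ordered by time.
#' @export
read_series <- function(path, voxel_size_um, frame_interval_min = 10, nz = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^frame_[0-9]+\\.tiff?$",
                             full.names = TRUE))
    if (!length(files)) stop("no frame_%04d.tif files in '", path, "'")
    stacks <- vector("list", length(files))
    for (i in seq_along(files)) {
      st <- read_stack(files[i], voxel_size_um, frame_index = i - 1L,
                       t_min = (i - 1L) * frame_interval_min)
      if (i > 1L && dim(st$data)[3L] != dim(stacks[[1L]]$data)[3L])
        stop(sprintf("frame '%s' has %d z-plane(s), expected %d",
                     basename(files[i]), dim(st$data)[3L],
                     dim(stacks[[1L]]$data)[3L]))
      stacks[[i]] <- st
    }
    return(stacks)
  }
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (is.null(nz)) stop("'nz' is required to read a single multi-frame TIFF")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% nz != 0L)
    stop(sprintf("%d page(s) does not divide into frames of %d z-plane(s)",
                 length(pages), nz))
  nf <- length(pages) %/% nz
  lapply(seq_len(nf), function(f) {
    sub <- pages[((f - 1L) * nz + 1L):(f * nz)]
    nx <- ncol(sub[[1L]]); ny <- nrow(sub[[1L]])
    data <- array(0, c(nx, ny, nz))
    for (k in seq_len(nz)) data[, , k] <- t(sub[[k]])
    image_stack(data, voxel_size_um, frame_index = f - 1L,
                t_min = (f - 1L) * frame_interval_min)
  })
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with validated defaults. The
#' defaults reflect the reference acquisition geometry (0.87 um lateral,
#' 5 um axial voxels, 10-min frames) and the method's published rules
#' (density filter keeps pixels with at least 20% cell neighbors; the z-fit
#' uses the central 50% of cell voxels).
#'
#' @param voxel_size_um `(dx, dy, dz)` in um.
#' @param frame_interval_min frame interval (min).
#' @param template_cell_xy,template_background_xy `(x, y)` pixel coordinates
#'   of the cell and background template columns (selected per experiment).
#' @param template_frame frame (1-based) the templates are extracted from;
#'   frame-1 templates are reused for the whole series.
#' @param template_ref_z_um reference z of the template cell (um), if known.
#' @param template_patch_px averaging patch radius for template extraction
#'   (see [templates_from_stack()]).
#' @param template_cell_csv,template_background_csv paths to stored template
#'   profiles (two-column CSV, see [write_template()]); when both are set
#'   they take precedence over in-stack extraction and the `*_xy`
#'   coordinates may be omitted.
#' @param density_radius_px,density_min_fraction density filter parameters
#'   (see [density_filter()]).
#' @param min_area_px minimum candidate area (see [label_candidates()]).
#' @param offset_step_um,stretch_limits,stretch_step,central_fraction z-fit
#'   parameters (see [fit_profile()] and [cell_z()]).
#' @param corr_threshold region-growing threshold (see [grow_region()]).
#' @param max_disp_um,max_gap linking parameters (see [link_frames()] and
#'   [build_trajectories()]).
#' @param slow_um_min,fast_um_min population speed bin edges (um/min).
#' @param normalize min-max normalize each stack before processing.
#' @param rng_seed seed recorded with the run.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(voxel_size_um = c(0.87, 0.87, 5),
                       frame_interval_min = 10,
                       template_cell_xy = NULL,
                       template_background_xy = NULL,
                       template_frame = 1L,
                       template_ref_z_um = NULL,
                       template_patch_px = 2L,
                       template_cell_csv = NULL,
                       template_background_csv = NULL,
                       density_radius_px = 2L,
                       density_min_fraction = 0.20,
                       min_area_px = 9L,
                       offset_step_um = NULL,
                       stretch_limits = c(0.9, 1.1),
                       stretch_step = 0.05,
                       central_fraction = 0.5,
                       corr_threshold = 0.8,
                       max_disp_um = 30,
                       max_gap = 0L,
                       slow_um_min = 0.5,
                       fast_um_min = 2,
                       normalize = TRUE,
                       rng_seed = 1L) {
  cfg <- list(voxel_size_um = as.numeric(voxel_size_um),
              frame_interval_min = as.numeric(frame_interval_min),
              template_cell_xy = if (!is.null(template_cell_xy)) as.integer(template_cell_xy),
              template_background_xy = if (!is.null(template_background_xy)) as.integer(template_background_xy),
              template_frame = as.integer(template_frame),
              template_ref_z_um = if (!is.null(template_ref_z_um)) as.numeric(template_ref_z_um),
              template_patch_px = as.integer(template_patch_px),
              template_cell_csv = if (!is.null(template_cell_csv)) as.character(template_cell_csv),
              template_background_csv = if (!is.null(template_background_csv)) as.character(template_background_csv),
              density_radius_px = as.integer(density_radius_px),
              density_min_fraction = as.numeric(density_min_fraction),
              min_area_px = as.integer(min_area_px),
              offset_step_um = if (!is.null(offset_step_um)) as.numeric(offset_step_um),
              stretch_limits = as.numeric(stretch_limits),
              stretch_step = as.numeric(stretch_step),
              central_fraction = as.numeric(central_fraction),
              corr_threshold = as.numeric(corr_threshold),
              max_disp_um = as.numeric(max_disp_um),
              max_gap = as.integer(max_gap),
              slow_um_min = as.numeric(slow_um_min),
              fast_um_min = as.numeric(fast_um_min),
              normalize = isTRUE(normalize),
              rng_seed = as.integer(rng_seed))
  if (length(cfg$voxel_size_um) != 3L || any(cfg$voxel_size_um <= 0))
    stop("'voxel_size_um' must be three positive numbers")
  if (cfg$frame_interval_min <= 0) stop("'frame_interval_min' must be positive")
  if (cfg$density_radius_px < 1L) stop("'density_radius_px' must be >= 1")
  if (cfg$density_min_fraction <= 0 || cfg$density_min_fraction > 1)
    stop("'density_min_fraction' must be in (0, 1]")
  if (cfg$min_area_px < 1L) stop("'min_area_px' must be >= 1")
  if (cfg$central_fraction <= 0 || cfg$central_fraction > 1)
    stop("'central_fraction' must be in (0, 1]")
  if (cfg$corr_threshold <= 0 || cfg$corr_threshold >= 1)
    stop("'corr_threshold' must be in (0, 1)")
  if (cfg$max_disp_um <= 0) stop("'max_disp_um' must be positive")
  if (cfg$max_gap < 0L) stop("'max_gap' must be >= 0")
  if (!is.null(cfg$offset_step_um) &&
      cfg$offset_step_um > cfg$voxel_size_um[3L] / 10 + 1e-12)
    stop("'offset_step_um' must be at most dz / 10")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(v)) "<default>" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' Unknown keys in the file are rejected (they are almost always typos of a
#' tunable and silently ignoring them would change results).
#'
#' @param path YAML file path.
#' @param config a `run_config`.
#' @return `read_config` returns a validated `run_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(yaml::as.yaml(unclass(config), precision = 17L), path)
  invisible(path)
}
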