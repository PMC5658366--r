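#' Canonical bright-field defocus profile
#'
#' Idealized z-intensity offset a cell imprints on the columns it covers: a
#' derivative-of-Gaussian, `amplitude * (z/sigma) * exp(-z^2 / (2 sigma^2))`,
#' with `z` the signed distance to the cell's focal plane. The form is odd in
#' `z` (bright lobe on one side of focus, dark lobe on the other) and decays
#' to zero away from focus, mimicking the defocus signature of a weakly
#' scattering cell in transmitted light. Real signatures depend on the
#' optical setup; this is the simplest antisymmetric, parametric, bounded
#' stand-in.
#'
#' @param z_rel_um signed axial distance(s) from the cell's focal plane (um).
#' @param amplitude peak-scaling factor (intensity units of a `[0,1]` image);
#'   may be negative for inverted contrast.
#' @param sigma_um axial width of the signature (um, > 0).
#' @return intensity offset(s), same length as `z_rel_um`.
#' @examples
#' canonical_profile(0, 0.2, 12)          # 0 at focus
#' canonical_profile(12, 0.2, 12)         # 0.2 * exp(-1/2)
#' @export
canonical_profile <- function(z_rel_um, amplitude, sigma_um) {
  if (!is.finite(sigma_um) || sigma_um <= 0) stop("'sigma_um' must be positive")
  amplitude * (z_rel_um / sigma_um) * exp(-z_rel_um^2 / (2 * sigma_um^2))
}

#' Scripted cell for a synthetic scene
#'
#' @param id integer cell id (unique within a scene).
#' @param path numeric matrix with columns `(x, y, z)` in micrometers, one
#'   row per frame in which the cell is present (a contiguous frame range).
#' @param radius_um lateral radius of the cell's footprint (um, > 0).
#' @param profile_amplitude amplitude of the defocus signature (nonzero).
#' @param profile_sigma_um axial width of the signature (um, > 0).
#' @param first_frame first frame (1-based) in which the cell is present.
#' @return An object of class `cell_script`.
#' @export
cell_script <- function(id, path, radius_um = 8, profile_amplitude = 0.2,
                        profile_sigma_um = 12, first_frame = 1L) {
  path <- rbind(path)
  if (ncol(path) != 3L) stop("'path' must have columns (x, y, z) in um")
  if (!is.finite(radius_um) || radius_um <= 0) stop("'radius_um' must be positive")
  if (!is.finite(profile_amplitude) || profile_amplitude == 0)
    stop("'profile_amplitude' must be nonzero")
  if (!is.finite(profile_sigma_um) || profile_sigma_um <= 0)
    stop("'profile_sigma_um' must be positive")
  structure(list(id = as.integer(id), path = unname(path),
                 radius_um = as.numeric(radius_um),
                 profile_amplitude = as.numeric(profile_amplitude),
                 profile_sigma_um = as.numeric(profile_sigma_um),
                 first_frame = as.integer(first_frame)),
            class = "cell_script")
}

.cell_frames <- function(cs) cs$first_frame + seq_len(nrow(cs$path)) - 1L

#' Synthetic scene specification
#'
#' Full, exactly reproducible description of a synthetic bright-field
#' time-lapse: volume geometry, scripted cell paths with their defocus
#' signatures, fibrillar clutter density, a smooth axial illumination
#' gradient, camera noise, and the RNG seed. Rendering a scene (see
#' [render_stack()]) is deterministic given the seed.
#'
#' The axial illumination profile (a weak, smooth, symmetric intensity
#' modulation along z, shaped like the second Legendre polynomial with
#' amplitude `background_gradient` at the stack ends) emulates the
#' depth-dependent illumination of real transmitted-light stacks; it is what
#' gives the cell-free background template its structure. Being even around
#' the stack midpoint it is orthogonal to the odd defocus signature of a
#' cell, so it structures the background without imitating a cell.
#'
#' @param volume_px integer length-3 `(nx, ny, nz)` volume size in voxels.
#' @param voxel_size_um numeric length-3 `(dx, dy, dz)` in um.
#' @param n_frames number of time points (>= 1).
#' @param frame_interval_min time between frames (min, > 0).
#' @param cells list of [cell_script()]s.
#' @param fibril_density clutter line segments per 100x100 pixel tile (>= 0).
#' @param fibril_amplitude intensity amplitude of clutter (absolute value;
#'   segments alternate sign); kept at <= 25% of typical cell amplitude.
#' @param noise_sigma SD of additive Gaussian camera noise (intensity units
#'   of a `[0,1]` image, >= 0).
#' @param background_level mean background intensity, in `(0, 1)`.
#' @param background_gradient amplitude of the axial illumination profile
#'   (intensity offset at the first/last plane relative to
#'   `background_level`).
#' @param soft_edge logical; if `TRUE` the lateral cell window falls off
#'   smoothly over one pixel instead of a hard disk (default off so that
#'   ground-truth footprints are exact).
#' @param rng_seed integer seed; per-frame noise uses substreams derived
#'   from `(seed, frame)` so any frame renders identically in isolation.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(volume_px, voxel_size_um = c(0.87, 0.87, 5),
                       n_frames = 1L, frame_interval_min = 10,
                       cells = list(), fibril_density = 3,
                       fibril_amplitude = 0.05, noise_sigma = 0.02,
                       background_level = 0.5, background_gradient = 0.08,
                       soft_edge = FALSE, rng_seed = 1L) {
  volume_px <- as.integer(volume_px)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(volume_px) != 3L || any(volume_px < 1L))
    stop("'volume_px' must be three positive integers")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("'voxel_size_um' must be three positive numbers")
  if (n_frames < 1L) stop("'n_frames' must be >= 1")
  if (frame_interval_min <= 0) stop("'frame_interval_min' must be positive")
  if (fibril_density < 0) stop("'fibril_density' must be >= 0")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  if (background_level <= 0 || background_level >= 1)
    stop("'background_level' must be in (0, 1)")
  ext_um <- volume_px * voxel_size_um
  for (cs in cells) {
    if (!inherits(cs, "cell_script")) stop("'cells' must be a list of cell_script objects")
    fr <- .cell_frames(cs)
    if (fr[1L] < 1L || fr[length(fr)] > n_frames)
      stop(sprintf("cell %d present outside the frame range 1..%d", cs$id, n_frames))
    if (any(cs$path < 0) || any(cs$path[, 1L] > ext_um[1L]) ||
        any(cs$path[, 2L] > ext_um[2L]) || any(cs$path[, 3L] > ext_um[3L]))
      stop(sprintf("cell %d leaves the physical volume", cs$id))
  }
  if (length(cells) && anyDuplicated(vapply(cells, `[[`, 1L, "id")))
    stop("cell ids must be unique")
  structure(list(volume_px = volume_px, voxel_size_um = voxel_size_um,
                 n_frames = as.integer(n_frames),
                 frame_interval_min = as.numeric(frame_interval_min),
                 cells = cells, fibril_density = as.numeric(fibril_density),
                 fibril_amplitude = as.numeric(fibril_amplitude),
                 noise_sigma = as.numeric(noise_sigma),
                 background_level = as.numeric(background_level),
                 background_gradient = as.numeric(background_gradient),
                 soft_edge = isTRUE(soft_edge), rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d x %d voxels, %d frame(s), %d cell(s), fibril density %g, noise sigma %g, seed %d\n",
              x$volume_px[1], x$volume_px[2], x$volume_px[3], x$n_frames,
              length(x$cells), x$fibril_density, x$noise_sigma, x$rng_seed))
  invisible(x)
}

# Fibril clutter: thin line segments confined to 1-2 z-planes each, drawn
# once per scene (the matrix is static over a time-lapse). Returns a list of
# segments; rasterized into each rendered frame.
.scene_fibrils <- function(scene) {
  n_seg <- round(scene$fibril_density *
                   prod(scene$volume_px[1:2]) / 1e4)
  if (n_seg < 1L) return(list())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(.substream_seed(scene$rng_seed, -1L, salt = 7L))
  nx <- scene$volume_px[1L]; ny <- scene$volume_px[2L]; nz <- scene$volume_px[3L]
  lapply(seq_len(n_seg), function(i) {
    x0 <- stats::runif(1, 1, nx); y0 <- stats::runif(1, 1, ny)
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 10, 30)
    z0 <- sample.int(nz, 1L)
    nzp <- sample(1:2, 1L)
    amp <- scene$fibril_amplitude * sample(c(-1, 1), 1L)
    list(x0 = x0, y0 = y0, angle = ang, length_px = len,
         z_planes = z0:min(nz, z0 + nzp - 1L), amplitude = amp)
  })
}

.rasterize_segment <- function(seg, nx, ny) {
  n <- max(2L, ceiling(seg$length_px * 2))
  t <- seq(0, seg$length_px, length.out = n)
  xs <- round(seg$x0 + t * cos(seg$angle))
  ys <- round(seg$y0 + t * sin(seg$angle))
  ok <- xs >= 1L & xs <= nx & ys >= 1L & ys <= ny
  unique(cbind(xs[ok], ys[ok]))
}

#' Render one frame of a synthetic scene
#'
#' Deterministically renders the 3D volume of frame `frame`:
#' `background_level` plus the axial illumination ramp, plus each present
#' cell's defocus signature applied within its lateral disk, plus fibril
#' clutter, plus Gaussian camera noise, clipped to `[0, 1]`.
#'
#' @param scene a [scene_spec()].
#' @param frame frame index, 1-based, in `1..n_frames`.
#' @return an [image_stack()].
#' @export
render_stack <- function(scene, frame) {
  stopifnot(inherits(scene, "scene_spec"))
  frame <- as.integer(frame)
  if (frame < 1L || frame > scene$n_frames)
    stop(sprintf("frame %d out of range 1..%d", frame, scene$n_frames))
  nx <- scene$volume_px[1L]; ny <- scene$volume_px[2L]; nz <- scene$volume_px[3L]
  dx <- scene$voxel_size_um[1L]; dy <- scene$voxel_size_um[2L]
  dz <- scene$voxel_size_um[3L]
  zc <- (seq_len(nz) - 0.5) * dz

  # background + smooth axial illumination profile (even around the stack
  # midpoint, so it cannot mimic the odd defocus signature of a cell)
  illum <- if (nz > 1L) {
    u <- 2 * (seq_len(nz) - 1) / (nz - 1) - 1
    scene$background_gradient * (3 * u^2 - 1) / 2
  } else 0
  vol <- array(rep(scene$background_level + illum, each = nx * ny), c(nx, ny, nz))

  xc_px <- (seq_len(nx) - 0.5) * dx
  yc_px <- (seq_len(ny) - 0.5) * dy
  for (cs in scene$cells) {
    fr <- .cell_frames(cs)
    k <- match(frame, fr)
    if (is.na(k)) next
    pos <- cs$path[k, ]
    ddx <- xc_px - pos[1L]; ddy <- yc_px - pos[2L]
    r2 <- outer(ddx^2, ddy^2, `+`)
    if (scene$soft_edge) {
      w <- 1 / (1 + exp((sqrt(r2) - cs$radius_um) / (0.5 * dx)))
    } else {
      w <- (r2 <= cs$radius_um^2) * 1
    }
    if (!any(w > 0)) next
    prof <- canonical_profile(zc - pos[3L], cs$profile_amplitude, cs$profile_sigma_um)
    vol <- vol + outer(w, prof)
  }

  for (seg in .scene_fibrils(scene)) {
    px <- .rasterize_segment(seg, nx, ny)
    if (!nrow(px)) next
    for (zp in seg$z_planes)
      vol[cbind(px, zp)] <- vol[cbind(px, zp)] + seg$amplitude
  }

  if (scene$noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(.substream_seed(scene$rng_seed, frame))
    vol <- vol + array(stats::rnorm(length(vol), 0, scene$noise_sigma), dim(vol))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }

  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  image_stack(vol, scene$voxel_size_um, frame_index = frame - 1L,
              t_min = (frame - 1L) * scene$frame_interval_min)
}

#' Ground truth table of a scene
#'
#' @param scene a [scene_spec()].
#' @return data.frame with columns `frame` (1-based), `cell_id`, `x_um`,
#'   `y_um`, `z_um`, `radius_um`; one row per scripted (frame, cell) pair,
#'   ordered by frame then cell id.
#' @export
ground_truth <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  rows <- lapply(scene$cells, function(cs) {
    fr <- .cell_frames(cs)
    data.frame(frame = fr, cell_id = cs$id, x_um = cs$path[, 1L],
               y_um = cs$path[, 2L], z_um = cs$path[, 3L],
               radius_um = cs$radius_um)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), cell_id = integer(), x_um = numeric(),
               y_um = numeric(), z_um = numeric(), radius_um = numeric())
  out <- out[order(out$frame, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the ground truth CSV of a scene
#'
#' @param scene a [scene_spec()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(scene, path) {
  utils::write.csv(ground_truth(scene), path, row.names = FALSE)
  invisible(path)
}

#' Binary ground-truth footprint of one cell at one frame
#'
#' Pixel-center inclusion: a pixel belongs to the footprint iff its center
#' lies within `radius_um` of the cell axis.
#'
#' @param scene a [scene_spec()].
#' @param cell_id scripted cell id.
#' @param frame frame index (1-based).
#' @return logical `nx x ny` matrix.
#' @export
ground_truth_footprint <- function(scene, cell_id, frame) {
  stopifnot(inherits(scene, "scene_spec"))
  cs <- NULL
  for (c0 in scene$cells) if (c0$id == cell_id) cs <- c0
  if (is.null(cs)) stop(sprintf("no cell with id %d", cell_id))
  k <- match(frame, .cell_frames(cs))
  if (is.na(k)) stop(sprintf("cell %d not present at frame %d", cell_id, frame))
  nx <- scene$volume_px[1L]; ny <- scene$volume_px[2L]
  xc <- (seq_len(nx) - 0.5) * scene$voxel_size_um[1L]
  yc <- (seq_len(ny) - 0.5) * scene$voxel_size_um[2L]
  outer((xc - cs$path[k, 1L])^2, (yc - cs$path[k, 2L])^2, `+`) <= cs$radius_um^2
}

#' Serialize / parse a scene specification
#'
#' YAML or JSON, chosen by file extension (`.yaml`/`.yml` or `.json`).
#' Round-tripping reproduces the scene field-for-field (numeric values to
#' full double precision for JSON, 17 significant digits, i.e. exactly, for YAML).
#'
#' @param scene a [scene_spec()].
#' @param path file path.
#' @return `write_scene` returns `path` invisibly; `read_scene` returns a
#'   [scene_spec()].
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene_spec"))
  x <- unclass(scene)
  x$cells <- lapply(x$cells, function(cs) {
    y <- unclass(cs)
    y$path <- lapply(seq_len(nrow(y$path)), function(i) as.numeric(y$path[i, ]))
    y
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    writeLines(yaml::as.yaml(x, precision = 17L), path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else stop("scene file must end in .yaml, .yml or .json")
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
  else stop("scene file must end in .yaml, .yml or .json")
  num <- function(v) as.numeric(unlist(v))
  cells <- lapply(x$cells, function(y) {
    p <- y$path
    p <- if (is.list(p)) do.call(rbind, lapply(p, num)) else rbind(num(p))
    cell_script(num(y$id), p, radius_um = num(y$radius_um),
                profile_amplitude = num(y$profile_amplitude),
                profile_sigma_um = num(y$profile_sigma_um),
                first_frame = num(y$first_frame))
  })
  scene_spec(volume_px = num(x$volume_px), voxel_size_um = num(x$voxel_size_um),
             n_frames = num(x$n_frames),
             frame_interval_min = num(x$frame_interval_min),
             cells = cells, fibril_density = num(x$fibril_density),
             fibril_amplitude = num(x$fibril_amplitude),
             noise_sigma = num(x$noise_sigma),
             background_level = num(x$background_level),
             background_gradient = num(x$background_gradient),
             soft_edge = isTRUE(unlist(x$soft_edge)), rng_seed = num(x$rng_seed))
}

#' Render a whole scene to disk
#'
#' Writes one multi-page TIFF per frame (`frame_%04d.tif`, pages = z-planes
#' in ascending z), the ground truth CSV and a copy of the scene spec.
#'
#' @param scene a [scene_spec()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with the written file paths.
#' @export
simulate_series <- function(scene, dir) {
  stopifnot(inherits(scene, "scene_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frames <- character(scene$n_frames)
  for (f in seq_len(scene$n_frames)) {
    st <- render_stack(scene, f)
    frames[f] <- file.path(dir, sprintf("frame_%04d.tif", f - 1L))
    write_stack(st, frames[f])
  }
  gt <- file.path(dir, "ground_truth.csv")
  write_ground_truth(scene, gt)
  sc <- file.path(dir, "scene.yaml")
  write_scene(scene, sc)
  invisible(list(frames = frames, ground_truth = gt, scene = sc))
}
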