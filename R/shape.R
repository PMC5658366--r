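#' Correlation-gated region growing
#'
#' Recovers the full 2D cell footprint from a detected core. Detection keeps
#' only pixels whose profile resembles the global cell template; border
#' pixels, whose z-signal is weak, are missed. Plain intensity-based region
#' growing fails on low-contrast bright-field data, so the growing step
#' reuses z-profile correlation as its stopping criterion: starting from the
#' seed, 8-neighboring pixels join the region as long as the Pearson
#' correlation between their z-profile and the *seed pixel's own* profile
#' (not the global template) stays at or above `corr_threshold`.
#'
#' @param stack an [image_stack()].
#' @param seed_xy integer `(x, y)` seed pixel (normally the candidate pixel
#'   nearest the candidate centroid).
#' @param corr_threshold correlation threshold in `(0, 1)` (default 0.8).
#' @return An object of class `cell_mask`: list with `pixels` (n x 2 integer
#'   matrix), `seed_xy`, `frame_index`. Always contains the seed; always
#'   8-connected. Growth is monotone in the threshold: a higher threshold
#'   yields a subset mask.
#' @export
grow_region <- function(stack, seed_xy, corr_threshold = 0.8) {
  stopifnot(inherits(stack, "image_stack"))
  if (corr_threshold <= 0 || corr_threshold >= 1)
    stop("'corr_threshold' must be in (0, 1)")
  d <- dim(stack$data)
  sx <- as.integer(seed_xy[1L]); sy <- as.integer(seed_xy[2L])
  if (sx < 1L || sx > d[1L] || sy < 1L || sy > d[2L])
    stop("seed outside lateral bounds")
  seedv <- stack$data[sx, sy, ]
  if (stats::var(seedv) == 0) stop("invalid seed: zero-variance profile")
  cmap <- .column_corr(stack, seedv)
  ok <- !is.na(cmap) & cmap >= corr_threshold
  ok[sx, sy] <- TRUE
  # BFS restricted to the thresholded correlation map
  lab <- .label8(ok)
  sel <- which(lab == lab[sx, sy])
  nx <- d[1L]
  px <- cbind(x = (sel - 1L) %% nx + 1L, y = (sel - 1L) %/% nx + 1L)
  structure(list(pixels = px, seed_xy = c(sx, sy),
                 frame_index = stack$frame_index),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d px, seed (%d, %d), frame %d\n",
              nrow(x$pixels), x$seed_xy[1L], x$seed_xy[2L], x$frame_index))
  invisible(x)
}

#' Moment-based 2D shape descriptors of a cell footprint
#'
#' Computes the standard descriptors from the second central moments of the
#' mask's pixel centers (with the 1/12-pixel self-moment added, so a single
#' row of pixels has the moments of a solid bar rather than a line). The
#' equivalent ellipse has axis lengths `4 * sqrt(lambda)` for the two
#' eigenvalues of the covariance matrix, giving:
#' * `area_um2 = N * dx * dy`
#' * `aspect_ratio = major / minor` (>= 1)
#' * `orientation_deg` = major-axis angle to the x-axis, in `[-90, 90)`,
#'   measured toward +y (increasing row index)
#' * `roundness = 4 * area / (pi * major^2)` (the ImageJ convention, in
#'   `(0, 1]`), so a disk scores 1 and elongated shapes score low.
#'
#' @param mask a `cell_mask` (or any object with an n x 2 `pixels` matrix);
#'   at least 4 pixels.
#' @param voxel_size_um numeric `(dx, dy)` lateral voxel size in um (extra
#'   entries ignored).
#' @return list of class `shape_params` with `area_um2`, `roundness`,
#'   `aspect_ratio`, `orientation_deg`, `major_um`, `minor_um`.
#' @export
shape_params <- function(mask, voxel_size_um = c(0.87, 0.87)) {
  px <- if (is.matrix(mask)) mask else mask$pixels
  if (nrow(px) < 4L) stop("shape parameters need at least 4 pixels")
  dx <- voxel_size_um[1L]; dy <- voxel_size_um[2L]
  xs <- (px[, 1L] - 0.5) * dx
  ys <- (px[, 2L] - 0.5) * dy
  n <- length(xs)
  mxx <- sum((xs - mean(xs))^2) / n + dx^2 / 12
  myy <- sum((ys - mean(ys))^2) / n + dy^2 / 12
  mxy <- sum((xs - mean(xs)) * (ys - mean(ys))) / n
  tr <- mxx + myy
  det_ <- mxx * myy - mxy^2
  disc <- sqrt(max(0, tr^2 / 4 - det_))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)  # pixel self-moment keeps this positive in practice
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  if (theta >= 90) theta <- theta - 180
  if (theta < -90) theta <- theta + 180
  area <- n * dx * dy
  structure(list(area_um2 = area,
                 roundness = min(1, 4 * area / (pi * major^2)),
                 aspect_ratio = major / minor,
                 orientation_deg = theta,
                 major_um = major, minor_um = minor),
            class = "shape_params")
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf("<shape_params> area %.2f um^2, roundness %.3f, aspect %.3f, orientation %.1f deg\n",
              x$area_um2, x$roundness, x$aspect_ratio, x$orientation_deg))
  invisible(x)
}

#' Grow all candidates of a frame and resolve collisions
#'
#' Runs [grow_region()] from each candidate's seed (the candidate pixel
#' nearest its centroid). Where grown masks overlap, each contested pixel is
#' assigned to the cell whose seed-profile correlation there is higher (ties
#' to the earlier candidate), and both cells are flagged `contact`. Cells
#' closer than the axial interference range may still merge into a single
#' candidate upstream; such regions are not split here.
#'
#' @param stack an [image_stack()].
#' @param candidates list of `cell_candidate`s (see [label_candidates()]).
#' @param corr_threshold passed to [grow_region()].
#' @return list with `masks` (list of `cell_mask`, parallel to
#'   `candidates`), `seeds` (n x 2 matrix) and `flags` (character vector,
#'   `""` or `"contact"`).
#' @export
grow_candidates <- function(stack, candidates, corr_threshold = 0.8) {
  nc <- length(candidates)
  if (nc == 0L) return(list(masks = list(), seeds = NULL, flags = character()))
  d <- dim(stack$data)
  dx <- stack$voxel_size_um[1L]; dy <- stack$voxel_size_um[2L]
  seeds <- t(vapply(candidates, function(cd) {
    d2 <- ((cd$pixels[, 1L] - 0.5) * dx - cd$centroid_xy_um[1L])^2 +
      ((cd$pixels[, 2L] - 0.5) * dy - cd$centroid_xy_um[2L])^2
    as.integer(cd$pixels[which.min(d2), ])
  }, integer(2L)))
  masks <- vector("list", nc)
  cmaps <- vector("list", nc)
  for (i in seq_len(nc)) {
    masks[[i]] <- grow_region(stack, seeds[i, ], corr_threshold)
    cmaps[[i]] <- .column_corr(stack, stack$data[seeds[i, 1L], seeds[i, 2L], ])
  }
  owner <- matrix(0L, d[1L], d[2L])
  best <- matrix(-Inf, d[1L], d[2L])
  flags <- character(nc)
  for (i in seq_len(nc)) {
    idx <- (masks[[i]]$pixels[, 2L] - 1L) * d[1L] + masks[[i]]$pixels[, 1L]
    contested <- owner[idx] != 0L
    if (any(contested)) {
      flags[i] <- "contact"
      flags[unique(owner[idx][contested])] <- "contact"
    }
    take <- !contested | cmaps[[i]][idx] > best[idx]
    owner[idx[take]] <- i
    best[idx[take]] <- cmaps[[i]][idx[take]]
  }
  nx <- d[1L]
  for (i in seq_len(nc)) {
    sel <- which(owner == i)
    # the seed always stays with its own cell
    sidx <- (seeds[i, 2L] - 1L) * nx + seeds[i, 1L]
    sel <- union(sel, sidx)
    masks[[i]]$pixels <- cbind(x = (sel - 1L) %% nx + 1L,
                               y = (sel - 1L) %/% nx + 1L)
  }
  list(masks = masks, seeds = seeds, flags = flags)
}

#' Export per-frame candidate labels as a 16-bit TIFF
#'
#' QC overlay: background 0, pixels of candidate `k` get value `k`.
#'
#' @param masks list of `cell_mask`s for one frame.
#' @param dim_xy integer `(nx, ny)` image size.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(masks, dim_xy, path) {
  lab <- matrix(0, dim_xy[1L], dim_xy[2L])
  for (i in seq_along(masks))
    lab[masks[[i]]$pixels] <- i
  tiff::writeTIFF(t(lab) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
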