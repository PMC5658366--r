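#' Per-frame binary cell map
#'
#' @param mask logical matrix over (x, y), same lateral shape as the source
#'   stack.
#' @param frame_index frame the map belongs to.
#' @param provenance `"raw"` (straight from classification) or `"filtered"`
#'   (after the density filter).
#' @return An object of class `cell_map`.
#' @export
cell_map <- function(mask, frame_index = 0L, provenance = c("raw", "filtered")) {
  stopifnot(is.matrix(mask), is.logical(mask))
  provenance <- match.arg(provenance)
  structure(list(mask = mask, frame_index = as.integer(frame_index),
                 provenance = provenance),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %d x %d (%s), %d cell pixel(s), frame %d\n",
              nrow(x$mask), ncol(x$mask), x$provenance, sum(x$mask), x$frame_index))
  invisible(x)
}

#' Classify every pixel as cell or background by template correlation
#'
#' For each lateral pixel, the Pearson correlation of its z-intensity profile
#' with the cell template and with the background template is computed; the
#' pixel is assigned to a cell iff the cell-template correlation is strictly
#' greater (ties and zero-variance columns go to background, the conservative
#' choice; zero-variance columns additionally raise a warning).
#'
#' @param stack an [image_stack()].
#' @param templates a [template_pair()] extracted from a stack with the same
#'   number of z-planes and the same dz.
#' @return a `cell_map` with provenance `"raw"`.
#' @export
classify_pixels <- function(stack, templates) {
  stopifnot(inherits(stack, "image_stack"), inherits(templates, "template_pair"))
  nz <- dim(stack$data)[3L]
  if (length(templates$cell$values) != nz)
    stop(sprintf("template length %d does not match stack nz %d",
                 length(templates$cell$values), nz))
  if (abs(templates$cell$dz_um - stack$voxel_size_um[3L]) > 1e-9)
    stop("template dz does not match stack dz")
  rc <- .column_corr(stack, templates$cell$values)
  rb <- .column_corr(stack, templates$background$values)
  nzv <- sum(is.na(rc))
  if (nzv > 0)
    warning(sprintf("%d zero-variance pixel profile(s) classified as background", nzv))
  m <- rc > rb
  m[is.na(m)] <- FALSE
  cell_map(m, frame_index = stack$frame_index, provenance = "raw")
}

#' Density (erosion-like) noise filter
#'
#' Single-pass removal of cell-map pixels whose neighborhood holds too few
#' cell pixels: a pixel stays in the map iff the fraction of cell pixels
#' among its neighbors within Chebyshev radius `radius_px` (excluding the
#' pixel itself) is at least `min_fraction`. At image borders only in-bounds
#' neighbors enter the denominator, so border cells are not penalized. The
#' output is computed from the input map only (no cascading within the
#' pass), and never contains pixels absent from the input.
#'
#' @param map a `cell_map`.
#' @param radius_px Chebyshev neighborhood radius (>= 1; default 2, i.e. a
#'   5x5 window with 24 neighbors).
#' @param min_fraction minimum cell fraction among neighbors (default 0.20:
#'   a pixel is removed if less than 20% of its neighbors are cells).
#' @return a `cell_map` with provenance `"filtered"`.
#' @export
density_filter <- function(map, radius_px = 2L, min_fraction = 0.20) {
  stopifnot(inherits(map, "cell_map"))
  radius_px <- as.integer(radius_px)
  if (radius_px < 1L) stop("'radius_px' must be >= 1")
  if (min_fraction <= 0 || min_fraction > 1) stop("'min_fraction' must be in (0, 1]")
  M <- map$mask
  nx <- nrow(M); ny <- ncol(M)
  num <- matrix(as.numeric(M), nx, ny)
  # summed-area table, zero-padded on the low side
  S <- apply(num, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  P <- matrix(0, nx + 1L, ny + 1L)
  P[-1L, -1L] <- S
  xi <- row(M); yi <- col(M)
  x1 <- pmax(xi - radius_px, 1L); x2 <- pmin(xi + radius_px, nx)
  y1 <- pmax(yi - radius_px, 1L); y2 <- pmin(yi + radius_px, ny)
  nbsum <- P[cbind(as.vector(x2 + 1L), as.vector(y2 + 1L))] -
    P[cbind(as.vector(x1), as.vector(y2 + 1L))] -
    P[cbind(as.vector(x2 + 1L), as.vector(y1))] +
    P[cbind(as.vector(x1), as.vector(y1))]
  counts <- as.vector((x2 - x1 + 1L) * (y2 - y1 + 1L)) - 1L  # exclude center
  frac_ok <- (nbsum - as.vector(num)) >= min_fraction * counts - 1e-9
  out <- M & matrix(frac_ok, nx, ny)
  cell_map(out, frame_index = map$frame_index, provenance = "filtered")
}

# 8-connected component labeling (BFS), labels in first-visit order.
.label8 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  idx <- which(mask)
  q <- integer(length(idx))
  for (p0 in idx) {
    if (lab[p0] != 0L) next
    cur <- cur + 1L
    q[1L] <- p0
    lab[p0] <- cur
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- q[head]; head <- head + 1L
      x <- (p - 1L) %% nx + 1L
      y <- (p - 1L) %/% nx + 1L
      for (ddy in -1L:1L) {
        yy <- y + ddy
        if (yy < 1L || yy > ny) next
        base <- (yy - 1L) * nx
        for (ddx in -1L:1L) {
          xx <- x + ddx
          if (xx < 1L || xx > nx) next
          pp <- base + xx
          if (mask[pp] && lab[pp] == 0L) {
            lab[pp] <- cur
            tail <- tail + 1L
            if (tail > length(q)) q <- c(q, integer(length(q)))
            q[tail] <- pp
          }
        }
      }
    }
  }
  lab
}

#' Extract connected cell candidates from a filtered cell map
#'
#' 8-connected components of the map with at least `min_area_px` pixels.
#' Candidate ids are assigned by the component's topmost (smallest y), then
#' leftmost (smallest x) pixel. Centroids are arithmetic means of pixel
#' centers, converted to micrometers.
#'
#' @param map a `cell_map` (normally `"filtered"`).
#' @param voxel_size_um numeric `(dx, dy)` (a length-3 voxel size is
#'   accepted; the z entry is ignored).
#' @param min_area_px minimum component area in pixels (default 9, about
#'   7 um^2 at 0.87 um pixels, dropping sub-cellular fragments).
#' @return list of `cell_candidate` objects, each with fields `pixels`
#'   (n x 2 integer matrix of (x, y)), `centroid_xy_um`, `frame_index`,
#'   `id_within_frame`.
#' @export
label_candidates <- function(map, voxel_size_um = c(0.87, 0.87), min_area_px = 9L) {
  stopifnot(inherits(map, "cell_map"))
  lab <- .label8(map$mask)
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0L)
  nx <- nrow(map$mask)
  xs <- (idx - 1L) %% nx + 1L
  ys <- (idx - 1L) %/% nx + 1L
  lv <- lab[idx]
  keep <- which(tabulate(lv, k) >= min_area_px)
  if (!length(keep)) return(list())
  # order components by (topmost, then leftmost) pixel
  miny <- vapply(keep, function(l) min(ys[lv == l]), 0L)
  minx <- vapply(keep, function(l) min(xs[lv == l & ys == miny[match(l, keep)]]), 0L)
  ord <- keep[order(miny, minx)]
  dx <- voxel_size_um[1L]; dy <- voxel_size_um[2L]
  out <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    sel <- lv == ord[i]
    px <- cbind(x = xs[sel], y = ys[sel])
    out[[i]] <- structure(
      list(pixels = px,
           centroid_xy_um = c(mean((px[, 1L] - 0.5) * dx),
                              mean((px[, 2L] - 0.5) * dy)),
           frame_index = map$frame_index,
           id_within_frame = i),
      class = "cell_candidate")
  }
  out
}

#' @export
print.cell_candidate <- function(x, ...) {
  cat(sprintf("<cell_candidate> id %d, frame %d, %d px, centroid (%.2f, %.2f) um\n",
              x$id_within_frame, x$frame_index, nrow(x$pixels),
              x$centroid_xy_um[1L], x$centroid_xy_um[2L]))
  invisible(x)
}

#' Export a cell map as a single-page binary TIFF
#'
#' Visual QC output: cell pixels white, background black.
#'
#' @param map a `cell_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cell_map <- function(map, path) {
  stopifnot(inherits(map, "cell_map"))
  tiff::writeTIFF(t(matrix(as.numeric(map$mask), nrow(map$mask))), path,
                  bits.per.sample = 8L)
  invisible(path)
}
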