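# Shared scene builders for the test suite. All fixtures are generated in
# code; nothing is read from disk.

# one cell centered laterally, at axial position z0 (um)
one_cell_scene <- function(z0 = 62.5, seed = 1L, noise_sigma = 0.02,
                           fibril_density = 3, nxy = 48L, nz = 25L,
                           radius_um = 8, amplitude = 0.2, sigma_um = 12) {
  scene_spec(c(nxy, nxy, nz),
             cells = list(cell_script(1L, cbind(20, 20, z0),
                                      radius_um = radius_um,
                                      profile_amplitude = amplitude,
                                      profile_sigma_um = sigma_um)),
             noise_sigma = noise_sigma, fibril_density = fibril_density,
             rng_seed = seed)
}

# reference templates: extracted from a dedicated one-cell scene whose cell
# sits exactly at the center of plane 13 (z = 62.5 um at dz = 5)
reference_templates <- function(seed = 999L, noise_sigma = 0.02,
                                fibril_density = 3) {
  sc <- one_cell_scene(62.5, seed = seed, noise_sigma = noise_sigma,
                       fibril_density = fibril_density)
  st <- normalize_stack(render_stack(sc, 1))
  templates_from_stack(st, c(23L, 23L), c(4L, 44L), ref_z_um = 62.5)
}

# n cells on a jittered lateral grid, z uniform in 62.5 +- z_halfwidth
multi_cell_scene <- function(n = 10L, seed = 7L, n_frames = 1L,
                             step_um = 3, z_halfwidth = 10,
                             noise_sigma = 0.02, fibril_density = 3,
                             nxy = 200L) {
  set.seed(seed * 13L + 1L)
  grid <- expand.grid(x = seq(25, nxy * 0.87 - 25, length.out = ceiling(sqrt(n))),
                      y = seq(25, nxy * 0.87 - 25, length.out = ceiling(sqrt(n))))
  grid <- grid[seq_len(n), , drop = FALSE]
  cells <- lapply(seq_len(n), function(i) {
    x <- grid$x[i] + stats::runif(1, -4, 4)
    y <- grid$y[i] + stats::runif(1, -4, 4)
    z <- 62.5 + stats::runif(1, -z_halfwidth, z_halfwidth)
    if (n_frames == 1L) path <- cbind(x, y, z)
    else path <- cbind(x + cumsum(c(0, stats::runif(n_frames - 1, -step_um, step_um))),
                       y + cumsum(c(0, stats::runif(n_frames - 1, -step_um, step_um))),
                       z + cumsum(c(0, stats::runif(n_frames - 1, -1, 1))))
    cell_script(i, path)
  })
  scene_spec(c(nxy, nxy, 25L), n_frames = n_frames, cells = cells,
             noise_sigma = noise_sigma, fibril_density = fibril_density,
             rng_seed = seed)
}

# union of all ground-truth footprints of a frame
truth_mask <- function(scene, frame) {
  m <- matrix(FALSE, scene$volume_px[1L], scene$volume_px[2L])
  for (cs in scene$cells) {
    if (frame %in% (cs$first_frame + seq_len(nrow(cs$path)) - 1L))
      m <- m | ground_truth_footprint(scene, cs$id, frame)
  }
  m
}

# exhaustive minimum-total-distance matching oracle (equal-size point sets,
# n <= 6); returns the to-index for each from-index
brute_force_matching <- function(a, b) {
  n <- nrow(a)
  stopifnot(n == nrow(b), n <= 6L)
  D <- sqrt(outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2 +
              outer(a[, 3], b[, 3], `-`)^2)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum(D[cbind(seq_len(n), p)])
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

obs_df <- function(m) data.frame(x_um = m[, 1], y_um = m[, 2], z_um = m[, 3])
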