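test_that("simple links, terminations and empty inputs behave", {
  a <- obs_df(rbind(c(0, 0, 0)))
  b <- obs_df(rbind(c(3, 0, 0)))
  lnk <- link_frames(a, b, 50)
  expect_equal(lnk$from, 1L)
  expect_equal(lnk$to, 1L)
  expect_equal(lnk$dist_um, 3)
  # cell absent at t+1: no link
  expect_equal(nrow(link_frames(a, obs_df(matrix(numeric(0), 0, 3)), 50)), 0L)
  expect_equal(nrow(link_frames(obs_df(matrix(numeric(0), 0, 3)), b, 50)), 0L)
  # gate: beyond max_disp nothing links
  expect_equal(nrow(link_frames(a, obs_df(rbind(c(40, 0, 0))), 30)), 0L)
})

test_that("greedy shortest-first resolves conflicts that naive NN gets wrong", {
  # both cells' naive per-cell nearest neighbor is target 1 (a conflict a
  # naive assignment cannot resolve); greedy links the closest pair first
  # and the result equals the enumerated minimum-total-distance matching
  a <- rbind(c(0, 0, 0), c(6, 0, 0), c(30, 0, 0))
  b <- rbind(c(6, 3, 0), c(0, 10, 0), c(30, 1, 0))
  naive <- apply(outer(seq_len(3), seq_len(3),
                       Vectorize(function(i, j) sqrt(sum((a[i, ] - b[j, ])^2)))),
                 1, which.min)
  expect_equal(naive, c(1L, 1L, 3L))  # both cells 1 and 2 want target 1
  lnk <- link_frames(obs_df(a), obs_df(b), 50)
  got <- lnk$to[order(lnk$from)]
  oracle <- brute_force_matching(a, b)
  expect_equal(got, oracle$assignment)
  expect_equal(sum(lnk$dist_um), oracle$cost)
  expect_false(identical(got, naive))  # greedy resolved the conflict
})

test_that("greedy equals the exhaustive matching in the NN-validity regime", {
  # instances where each true pair is mutually nearest (displacement below
  # half the minimum inter-cell spacing): greedy recovers the identity
  # matching, which is also the enumerated optimum
  set.seed(55)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    repeat {
      pos <- cbind(runif(n, 0, 200), runif(n, 0, 200), runif(n, 0, 100))
      dmin <- min(dist(pos))
      if (dmin > 12) break
    }
    step <- matrix(runif(3 * n, -1, 1), n, 3)
    step <- step / sqrt(rowSums(step^2)) * runif(n, 0, dmin / 2 * 0.98)
    nxt <- pos + step
    lnk <- link_frames(obs_df(pos), obs_df(nxt), 1e6)
    expect_equal(lnk$to[order(lnk$from)], seq_len(n))
    oracle <- brute_force_matching(pos, nxt)
    expect_equal(oracle$assignment, seq_len(n))
  }
})

test_that("trajectories chain correctly over frames", {
  # 1 cell, small steps -> one complete track
  obs <- data.frame(frame = 1:6, t_min = (0:5) * 10,
                    x_um = seq(0, 10, length.out = 6), y_um = 0, z_um = 50)
  tr <- build_trajectories(obs)
  expect_equal(unique(tr$observations$track_id), 1L)
  expect_true(all(track_completeness(tr)$complete))
  # 2 stationary cells far apart: two tracks, never swapped
  obs2 <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, t_min = (f - 1) * 10,
               x_um = c(0, 100), y_um = 0, z_um = c(50, 50))))
  tr2 <- build_trajectories(obs2)
  expect_equal(length(unique(tr2$observations$track_id)), 2L)
  by_track <- split(tr2$observations$x_um, tr2$observations$track_id)
  for (v in by_track) expect_equal(length(unique(v)), 1L)
  # a cell disappearing mid-series ends its track; reappearance starts a new
  # one when max_gap = 0
  obs3 <- data.frame(frame = c(1, 2, 4, 5), t_min = c(0, 10, 30, 40),
                     x_um = 1, y_um = 1, z_um = 1)
  tr3 <- build_trajectories(obs3, max_gap = 0L)
  expect_equal(length(unique(tr3$observations$track_id)), 2L)
  # with max_gap = 1 the gap is bridged
  tr3b <- build_trajectories(obs3, max_gap = 1L)
  expect_equal(length(unique(tr3b$observations$track_id)), 1L)
})

test_that("linking on scripted scenes is perfect under the validity condition", {
  # 10 cells, steps <= 5 um/frame, pairwise spacing >= 30 um: every link
  # must match the ground-truth identity
  set.seed(61)
  nf <- 6
  base <- expand.grid(x = c(30, 70, 110, 150, 190), y = c(40, 110))
  cells <- lapply(1:10, function(i) {
    steps <- matrix(runif(3 * (nf - 1), -1, 1), nf - 1, 3)
    steps <- steps / sqrt(rowSums(steps^2)) * runif(nf - 1, 0, 5)
    start <- c(base$x[i], base$y[i], 60)
    path <- rbind(start, sweep(apply(steps, 2, cumsum), 2, start, `+`))
    cell_script(i, path)
  })
  sc <- scene_spec(c(256, 176, 25), n_frames = nf, cells = cells, rng_seed = 3)
  gt <- ground_truth(sc)
  obs <- data.frame(frame = gt$frame, t_min = (gt$frame - 1) * 10,
                    x_um = gt$x_um, y_um = gt$y_um, z_um = gt$z_um,
                    cell_id = gt$cell_id)
  tr <- build_trajectories(obs)
  # each track maps to exactly one ground-truth cell
  tab <- table(tr$observations$track_id, tr$observations$cell_id)
  expect_equal(length(unique(tr$observations$track_id)), 10L)
  expect_true(all(rowSums(tab > 0) == 1))
  # violating the condition (a jump onto a neighbor's position, larger than
  # the distance to that neighbor) produces cross-linked tracks
  obs_bad <- obs
  obs_bad$x_um[obs_bad$frame >= 4 & obs_bad$cell_id == 1] <-
    obs$x_um[obs$frame >= 4 & obs$cell_id == 2]
  obs_bad$x_um[obs_bad$frame >= 4 & obs_bad$cell_id == 2] <-
    obs$x_um[obs$frame >= 4 & obs$cell_id == 1]
  tr_bad <- build_trajectories(obs_bad, max_disp_um = 1000)
  tab_bad <- table(tr_bad$observations$track_id, tr_bad$observations$cell_id)
  expect_false(all(rowSums(tab_bad > 0) == 1))
})

test_that("observations are conserved through linking and edits", {
  set.seed(91)
  obs <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, t_min = (f - 1) * 10,
               x_um = c(0, 50, 120) + rnorm(3), y_um = c(0, 30, 60),
               z_um = 50)))
  tr <- build_trajectories(obs)
  n0 <- nrow(tr$observations)
  expect_equal(n0, 15L)
  expect_false(anyNA(tr$observations$track_id))
  tr <- apply_edit(tr, "split", from_track = 1L, at_frame = 3L)
  expect_equal(nrow(tr$observations), n0)
  new_id <- max(tr$observations$track_id)
  tr <- apply_edit(tr, "merge", from_track = new_id, to_track = 1L)
  expect_equal(nrow(tr$observations), n0)
  expect_equal(sort(unique(tr$observations$track_id)), 1:3)
})

test_that("edits enforce trajectory invariants", {
  obs <- data.frame(frame = rep(1:4, 2), t_min = rep((0:3) * 10, 2),
                    x_um = rep(c(0, 100), each = 4), y_um = 0, z_um = 0)
  tr <- build_trajectories(obs)
  # merging tracks that overlap in time is rejected
  expect_error(apply_edit(tr, "merge", from_track = 1L, to_track = 2L),
               "overlap in time")
  # relink into an overlapping track is rejected; after truncating the
  # target it succeeds and the source ends before the relink frame
  expect_error(apply_edit(tr, "relink", from_track = 1L, to_track = 2L,
                          at_frame = 3L), "rejected")
  tr2 <- apply_edit(tr, "split", from_track = 2L, at_frame = 3L)
  tr3 <- apply_edit(tr2, "relink", from_track = 1L, to_track = 2L,
                    at_frame = 3L)
  o3 <- tr3$observations
  expect_equal(sort(o3$frame[o3$track_id == 2L]), 1:4)
  expect_true(all(o3$frame[o3$track_id == 1L] < 3L))
  # split bookkeeping: both halves present, edit log grows
  tr4 <- apply_edit(tr, "split", from_track = 1L, at_frame = 3L)
  ids <- tr4$observations$track_id[tr4$observations$x_um == 0]
  expect_equal(sort(unique(ids)), c(1L, max(tr4$observations$track_id)))
  expect_length(tr4$edit_log, 1L)
})

test_that("edit logs replay onto raw tracks", {
  obs <- data.frame(frame = 1:6, t_min = (0:5) * 10,
                    x_um = cumsum(c(0, rep(2, 5))), y_um = 0, z_um = 10)
  tr <- build_trajectories(obs)
  tr_e <- apply_edit(tr, "split", from_track = 1L, at_frame = 4L)
  f <- tempfile(fileext = ".json")
  write_edit_log(tr_e, f)
  tr_replayed <- replay_edits(build_trajectories(obs), f)
  expect_equal(tr_replayed$observations$track_id,
               tr_e$observations$track_id)
})

test_that("migration statistics follow the per-step arithmetic", {
  # 6 um displacement every 10-min frame -> 0.6 um/min everywhere
  obs <- data.frame(frame = 1:5, t_min = (0:4) * 10,
                    x_um = (0:4) * 6, y_um = 0, z_um = 0)
  tr <- build_trajectories(obs)
  s <- migration_stats(tr, track_id = 1L)
  expect_equal(s$step_speeds_um_min, rep(0.6, 4))
  expect_equal(s$mean_speed_um_min, 0.6)
  expect_equal(s$path_length_um, 24)
  # stationary cell: all zero
  obs0 <- data.frame(frame = 1:4, t_min = (0:3) * 10, x_um = 1, y_um = 2,
                     z_um = 3)
  expect_equal(migration_stats(build_trajectories(obs0), 1L)$step_speeds_um_min,
               rep(0, 3))
  # 3-4-5 path: (0,0,0)->(3,4,0)->(3,4,12): speeds 0.5 and 1.2, mean 0.85
  obs2 <- data.frame(frame = 1:3, t_min = (0:2) * 10,
                     x_um = c(0, 3, 3), y_um = c(0, 4, 4), z_um = c(0, 0, 12))
  s2 <- migration_stats(build_trajectories(obs2), 1L)
  expect_equal(s2$step_speeds_um_min, c(0.5, 1.2))
  expect_equal(s2$mean_speed_um_min, 0.85)
  # speeds are non-negative; mean <= max step speed
  set.seed(3)
  obs3 <- data.frame(frame = 1:8, t_min = (0:7) * 10,
                     x_um = cumsum(rnorm(8, 0, 4)),
                     y_um = cumsum(rnorm(8, 0, 4)),
                     z_um = cumsum(rnorm(8, 0, 2)))
  s3 <- migration_stats(build_trajectories(obs3, max_disp_um = 1e5), 1L)
  expect_true(all(s3$step_speeds_um_min >= 0))
  expect_lte(s3$mean_speed_um_min, max(s3$step_speeds_um_min))
  # a bridged gap uses the actual elapsed time
  obs4 <- data.frame(frame = c(1, 2, 4), t_min = c(0, 10, 30),
                     x_um = c(0, 6, 18), y_um = 0, z_um = 0)
  s4 <- migration_stats(build_trajectories(obs4, max_gap = 1L), 1L)
  expect_equal(s4$step_speeds_um_min, c(0.6, 0.6))
  # single-observation track: empty speed list
  s5 <- migration_stats(build_trajectories(
    data.frame(frame = 1, t_min = 0, x_um = 0, y_um = 0, z_um = 0)), 1L)
  expect_length(s5$step_speeds_um_min, 0L)
})

test_that("population statistics summarize speed distributions per window", {
  # all cells at constant 0.6 um/min
  obs <- do.call(rbind, lapply(1:4, function(i)
    data.frame(frame = 1:5, t_min = (0:4) * 10,
               x_um = (0:4) * 6, y_um = i * 100, z_um = 0)))
  tr <- build_trajectories(obs)
  ps <- population_stats(tr)
  expect_equal(ps$n_cells, 4L)
  expect_equal(ps$mean_speed_um_min, 0.6)
  expect_equal(ps$sd_speed_um_min, 0)
  expect_equal(ps$fraction_slow, 0)
  expect_equal(ps$fraction_fast, 0)
  # empty window: row with n_cells 0, no crash
  ps2 <- population_stats(tr, windows_min = c(0, 40, 500, 600))
  expect_equal(nrow(ps2), 3L)
  expect_equal(ps2$n_cells[3], 0L)
  expect_true(is.na(ps2$mean_speed_um_min[3]))
})

test_that("population mean recovers a generative lognormal speed model", {
  # cells moving straight at iid lognormal speeds: the recovered population
  # mean must sit within 2 SE of the generative mean
  set.seed(101)
  n <- 60
  mu <- log(0.6); sdl <- 0.4
  speeds <- rlnorm(n, mu, sdl)
  obs <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(frame = 1:4, t_min = (0:3) * 10,
               x_um = (0:3) * 10 * speeds[i], y_um = i * 40, z_um = 0)))
  tr <- build_trajectories(obs, max_disp_um = 1e5)
  ps <- population_stats(tr)
  gen_mean <- exp(mu + sdl^2 / 2)
  se <- sqrt(exp(2 * mu + sdl^2) * (exp(sdl^2) - 1) / n)
  expect_lt(abs(ps$mean_speed_um_min - gen_mean), 2 * se + 1e-12)
})
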