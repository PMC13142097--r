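static_traj <- function(n_res = 10, n_frames = 5) {
  xyz <- make_scaffold(n_res, seed = 1)
  new_trajectory(replicate(n_frames, xyz, simplify = FALSE),
                 times = 100 * (seq_len(n_frames) - 1), resno = seq_len(n_res))
}

test_that("frame selection reproduces the window/stride arithmetic", {
  tr <- new_trajectory(
    replicate(2001, cbind(3.8 * (1:4), 0, 0), simplify = FALSE),
    times = seq(0, 200000, by = 100), resno = 1:4)
  win <- select_frames(tr, 40000, 200000, stride = 100)
  expect_equal(dim(win$coords)[3], 1601L)  # (200000 - 40000) / 100 + 1
  expect_equal(win$times[1], 40000)
  expect_equal(win$times[1601], 200000)
  # stride equal to native spacing: pure window cut
  win2 <- select_frames(tr, 0, 10000)
  expect_equal(dim(win2$coords)[3], 101L)
  # coarser stride
  win3 <- select_frames(tr, 0, 10000, stride = 1000)
  expect_equal(win3$times, seq(0, 10000, by = 1000))
  expect_error(select_frames(tr, 300000, 400000),
               class = "conflex_empty_selection")
  expect_error(select_frames(tr, 100, 100), class = "conflex_bad_input")
})

test_that("a static trajectory has zero RMSF everywhere", {
  prof <- rmsf(static_traj())
  expect_equal(prof$value, rep(0, 10), tolerance = 1e-12)
})

test_that("two-frame hand case: atom at +/- a about its mean has RMSF = a", {
  a <- 0.8
  base <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0),
                c(10, 10, 10))
  f1 <- base; f1[5, 1] <- 10 - a
  f2 <- base; f2[5, 1] <- 10 + a
  tr <- new_trajectory(list(f1, f2), times = c(0, 100), resno = 1:5)
  prof <- rmsf(tr, fit_selection = 1:4)
  expect_equal(prof$value[5], a, tolerance = 1e-8)  # sqrt((a^2 + a^2) / 2)
  expect_equal(prof$value[1:4], rep(0, 4), tolerance = 1e-8)
})

test_that("iid Gaussian noise recovers RMSF = sigma * sqrt(3)", {
  sigma <- 0.4
  n_frames <- 1600
  sm <- tibble::tibble(resno = 1:40,
                       sigma = c(rep(0, 20), rep(sigma, 20)))
  tr <- make_trajectory(n_frames, sm, seed = 101)
  prof <- rmsf(tr, fit_selection = 1:20)
  # SE of the RMSF estimator (delta method on mean |u|^2): sigma / sqrt(2 n)
  se <- sigma / sqrt(2 * n_frames)
  dev <- prof$value[21:40] - sigma * sqrt(3)
  expect_lt(abs(mean(dev)), 3 * se / sqrt(20))
  expect_lt(max(abs(dev)), 4 * se)  # 20 simultaneous per-residue checks
  expect_lt(max(prof$value[1:20]), 1e-8)
})

test_that("RMSF is invariant to rigid motions, global or per-frame", {
  set.seed(41)
  sm <- tibble::tibble(resno = 1:30, sigma = c(rep(0.02, 20), rep(0.3, 10)))
  tr <- make_trajectory(50, sm, seed = 7)
  prof <- rmsf(tr, fit_selection = 1:20)
  # one fixed rigid motion applied to every frame
  R <- random_proper_rotation(); tv <- rnorm(3, 0, 10)
  tr_fixed <- tr
  for (f in seq_len(dim(tr$coords)[3])) {
    tr_fixed$coords[, , f] <- apply_rigid(tr$coords[, , f], R, tv)
  }
  expect_equal(rmsf(tr_fixed, fit_selection = 1:20)$value, prof$value,
               tolerance = 1e-8)
  # independent random motions per frame are undone by fitting on the
  # near-rigid scaffold
  tr_rand <- tr
  for (f in seq_len(dim(tr$coords)[3])) {
    tr_rand$coords[, , f] <- apply_rigid(tr$coords[, , f],
                                         random_proper_rotation(),
                                         rnorm(3, 0, 5))
  }
  prof_rand <- rmsf(tr_rand, fit_selection = 1:20)
  expect_lt(max(abs(prof_rand$value - prof$value)), 0.05)
  expect_lt(max(prof_rand$value[1:20]), 0.1)  # scaffold at the noise floor
})

test_that("replicate aggregation computes residue-wise mean and population SD", {
  p1 <- new_residue_profile(1:5, c(1, 2, 3, 4, 5), "rmsf")
  p2 <- new_residue_profile(1:5, c(3, 2, 3, 4, 5), "rmsf")
  agg <- aggregate_replicates(list(p1, p2))
  expect_equal(agg$mean$value[1], 2)   # mean of {1, 3}
  expect_equal(agg$sd$value[1], 1)     # population SD of {v, v + 2}
  expect_equal(agg$sd$value[2:5], rep(0, 4))

  five <- aggregate_replicates(rep(list(p1), 5))
  expect_equal(five$sd$value, rep(0, 5))
  one <- aggregate_replicates(list(p1))
  expect_equal(one$mean$value, p1$value)
  expect_equal(one$sd$value, rep(0, 5))
  p3 <- new_residue_profile(2:6, rep(1, 5), "rmsf")
  expect_error(aggregate_replicates(list(p1, p3)), class = "conflex_bad_input")
})

test_that("high-RMSF flagging is strict at the 0.12 A default", {
  flat <- new_residue_profile(1:10, rep(0.05, 10), "rmsf")
  expect_equal(nrow(flag_high_rmsf(flat)), 0L)
  span <- new_residue_profile(1:10, c(rep(0.05, 3), rep(0.2, 4), rep(0.05, 3)),
                              "rmsf")
  regs <- flag_high_rmsf(span)
  expect_equal(c(regs$first, regs$last), c(4L, 7L))
  boundary <- new_residue_profile(1:10, rep(0.12, 10), "rmsf")
  expect_equal(nrow(flag_high_rmsf(boundary)), 0L)
})

test_that("cross-domain restraints lower interface-region RMSF", {
  sm <- tibble::tibble(resno = 1:40, sigma = rep(0.3, 40))
  iface <- tibble::tibble(first = 15L, last = 22L)
  lower <- logical(20)
  for (seed in 1:20) {
    single <- rmsf(make_trajectory(120, sm, seed = seed))
    tandem <- rmsf(make_trajectory(120, sm, restrained_regions = iface,
                                   seed = seed + 1000))
    sel <- single$resno >= 15 & single$resno <= 22
    lower[seed] <- mean(tandem$value[sel]) < mean(single$value[sel])
  }
  expect_true(all(lower))
})

test_that("trajectories round-trip through TSV and multi-model PDB", {
  sm <- tibble::tibble(resno = 101:110, sigma = rep(0.2, 10))
  tr <- make_trajectory(6, sm, seed = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, tsv)
  back <- read_trajectory(tsv)
  expect_equal(back$coords, tr$coords, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$times, tr$times)
  expect_equal(back$resno, tr$resno)

  # nm inputs convert by a factor of 10
  tr_nm <- tr; tr_nm$coords <- tr$coords / 10
  expect_equal(nm_to_angstrom(tr_nm)$coords, tr$coords)
})
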