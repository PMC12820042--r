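test_that("feature vectors are channel-major, head to tail", {
  # 2 channels x 3 freqs, constant over time -> vector equals the constants
  vals <- array(0, c(2, 3, 4))
  for (ch in 1:2) for (f in 1:3) vals[ch, f, ] <- 10 * ch + f
  cube <- fake_db_cube(vals)
  tpl <- full_template(2, 3, times = cube$times)
  fv <- extract_ab_features(list(cube), tpl, "AB01")
  expect_length(fv$values, 6)
  expect_equal(fv$values, c(11, 12, 13, 21, 22, 23))
  expect_equal(fv$cells$channel, c(1, 1, 1, 2, 2, 2))
})

test_that("the median over time is taken within the template's support", {
  vals <- array(rnorm(2 * 3 * 10), c(2, 3, 10))
  cube <- fake_db_cube(vals, times = (0:9) * 0.02)
  # template time support covers only the first half of the cube
  tpl <- full_template(2, 3, times = c(0, 0.02, 0.04, 0.06, 0.08))
  fv <- extract_ab_features(list(cube), tpl)
  expect_equal(fv$values[1], median(vals[1, 1, 1:5]))
  # repetition averaging happens before the median
  cube2 <- fake_db_cube(vals + 2, times = cube$times)
  fv2 <- extract_ab_features(list(cube, cube2), tpl)
  expect_equal(fv2$values[1], median(vals[1, 1, 1:5] + 1))
})

test_that("24 movies x 4 segments yield 96 feature vectors per participant", {
  segs <- c("sim_first", "sim_first_context", "sim_second", "joint_context")
  tpls <- lapply(segs, function(s)
    full_template(2, 3, times = (0:3) * 0.02, segment = s))
  names(tpls) <- segs
  set.seed(31)
  count <- 0
  for (m in sprintf("AB%02d", 1:24)) {
    cubes <- list(fake_db_cube(array(rnorm(24), c(2, 3, 4))))
    for (s in segs) {
      fv <- extract_ab_features(cubes, tpls[[s]], m)
      expect_s3_class(fv, "feature_vector")
      count <- count + 1
    }
  }
  expect_equal(count, 96)
})

test_that("empty templates are refused for feature extraction", {
  tpl <- full_template(2, 3, times = (0:3) * 0.02)
  tpl$mask[] <- FALSE
  cube <- fake_db_cube(array(rnorm(24), c(2, 3, 4)))
  expect_error(extract_ab_features(list(cube), tpl), "empty feature template")
  expect_error(extract_ab_features(list(), tpl), "no cubes")
})

test_that("similarity hits the Fisher-z ceiling on an identical pattern", {
  set.seed(32)
  tpl <- full_template(2, 4, times = (0:4) * 0.02)
  anchor_vals <- array(rnorm(2 * 4 * 5), c(2, 4, 5))
  anchor_vals[] <- rep(anchor_vals[, , 1], 5)      # constant over time
  cube <- fake_db_cube(anchor_vals)
  fv <- extract_ab_features(list(cube), tpl, "AB01")
  s <- similarity_timecourse(fv, cube, tpl)
  expect_equal(s$z, rep(atanh(1 - 1e-7), 5), tolerance = 1e-6)
})

test_that("null patterns give near-zero mean z; r is affine-invariant", {
  set.seed(33)
  tpl <- full_template(4, 6, times = (0:9) * 0.02)
  anchor <- extract_ab_features(
    list(fake_db_cube(array(rnorm(4 * 6 * 10), c(4, 6, 10)))), tpl)
  target <- fake_db_cube(array(rnorm(4 * 6 * 500), c(4, 6, 500)),
                         times = (0:499) * 0.02)
  s <- similarity_timecourse(anchor, target, tpl)
  expect_lt(abs(mean(s$z, na.rm = TRUE)), 0.1)
  # affine rescaling of the target leaves Pearson r untouched
  target2 <- target
  target2$power <- 3 * target$power - 7
  s2 <- similarity_timecourse(anchor, target2, tpl)
  expect_equal(s$z, s2$z, tolerance = 1e-10)
  # zero-variance slices are marked invalid, not zero
  target3 <- target
  target3$power[, , 5] <- 1
  s3 <- similarity_timecourse(anchor, target3, tpl)
  expect_true(is.na(s3$z[5]))
})

test_that("baseline contrasts subtract the z-space baseline mean", {
  set.seed(34)
  tpl <- full_template(2, 3, times = (0:3) * 0.02)
  anchor <- extract_ab_features(
    list(fake_db_cube(array(rnorm(24), c(2, 3, 4)))), tpl)
  mk <- function() fake_db_cube(array(rnorm(2 * 3 * 50), c(2, 3, 50)),
                                times = (0:49) * 0.02)
  s_corr <- similarity_timecourse(anchor, mk(), tpl)
  b1 <- similarity_timecourse(anchor, mk(), tpl)
  b2 <- similarity_timecourse(anchor, mk(), tpl)
  ct <- baseline_contrast(s_corr, list(b1, b2), "vs_xy")
  expect_equal(ct$z, s_corr$z - (b1$z + b2$z) / 2)
  expect_equal(ct$baseline_applied, "vs_xy")
  # identical baselines -> zero contrast; common shifts cancel
  expect_equal(baseline_contrast(s_corr, list(s_corr, s_corr))$z,
               rep(0, 50))
  sh <- function(s, c) { s$z <- s$z + c; s }
  ct2 <- baseline_contrast(sh(s_corr, 5), list(sh(b1, 5), sh(b2, 5)))
  expect_equal(ct2$z, ct$z)
  expect_error(baseline_contrast(s_corr, list()), "empty baseline")
})

test_that("window averages match brute-force enumeration", {
  s <- structure(list(z = rep(0.01, 20), times = (0:19) * 0.02,
                      anchor = list(movie_id = "AB01")),
                 class = "similarity_series")
  expect_equal(window_average(s, c(0, 0.4)), 0.01)
  expect_equal(window_average(s, c(0.1, 0.12)), s$z[6])  # single timepoint
  set.seed(35)
  s$z <- rnorm(20)
  s$z[c(3, 7)] <- NA
  win <- c(0.04, 0.3)
  inside <- which(s$times >= win[1] & s$times < win[2])
  expect_equal(window_average(s, win),
               mean(s$z[setdiff(inside, c(3, 7))]))
  s$z[] <- NA
  expect_error(window_average(s, win), "no valid timepoints")
})

test_that("neighbourhood topography localises channel-limited effects", {
  set.seed(36)
  n_ch <- 6
  tpl <- full_template(n_ch, 8, times = (0:4) * 0.02)
  pattern <- array(rnorm(n_ch * 8 * 5), c(n_ch, 8, 5))
  pattern[] <- rep(pattern[, , 1], 5)
  ab_cube <- fake_db_cube(pattern)
  # target: anchor pattern on channels 1-3 only, noise elsewhere
  target_vals <- array(rnorm(n_ch * 8 * 30, sd = 1), c(n_ch, 8, 30))
  target_vals[1:3, , ] <- array(rep(pattern[1:3, , 1], 30), c(3, 8, 30)) +
    array(rnorm(3 * 8 * 30, sd = 0.1), c(3, 8, 30))
  target <- fake_db_cube(target_vals, times = (0:29) * 0.02)
  graph <- waversa:::grid_neighbor_graph(tpl$channels)
  topo <- neighborhood_topography(list(ab_cube), target, tpl, graph)
  means <- rowMeans(topo, na.rm = TRUE)
  expect_true(all(order(means, decreasing = TRUE)[1:3] %in% 1:3))
  # identical anchor/target: ceiling everywhere
  topo2 <- neighborhood_topography(list(ab_cube), ab_cube, tpl, graph)
  expect_true(all(topo2 > 5, na.rm = TRUE))
  # no edges: each neighbourhood degenerates to the channel itself
  lone <- matrix(0, n_ch, n_ch, dimnames = list(tpl$channels, tpl$channels))
  topo3 <- neighborhood_topography(list(ab_cube), ab_cube, tpl, lone)
  expect_true(all(topo3 > 5, na.rm = TRUE))
})
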