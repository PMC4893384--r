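test_that("the voting radius scales the stored distance by the previous scale", {
  expect_equal(vote_radius(100, 1.0), c(95, 105))
  expect_equal(vote_radius(0, 1.0), c(0, 0))
  expect_equal(vote_radius(50, 2.0), c(95, 105))
  expect_equal(vote_radius(40, 1.5, c(0.9, 1.1)), c(54, 66))
})

test_that("point votes and the weight threshold behave as specified", {
  mdl <- fx_synthetic_model(u = 50, v = 40, center = c(50, 40))
  ms <- fx_matchset(1, 50, 40, weight = 0.8)
  acc <- cast_votes(ms, mdl, 0.5, extent = c(100, 80))
  expect_equal(sum(acc$grid), 0.8, tolerance = 1e-12)
  expect_equal(acc$grid[41, 51], 0.8, tolerance = 1e-12)
  # all weights at or below threshold: zero accumulator
  ms2 <- fx_matchset(1, 50, 40, weight = 0.5)
  expect_equal(sum(cast_votes(ms2, mdl, 0.5, extent = c(100, 80))$grid), 0)
})

test_that("annulus voting reproduces an exhaustive brute-force accumulator", {
  mdl <- fx_synthetic_model(u = c(40, 70, 55), v = c(30, 35, 60),
                            center = c(55, 42))
  ms <- fx_posed_matches(mdl, c(55, 42))
  acc <- cast_votes(ms, mdl, 0.5, extent = c(110, 90))
  want <- oracle_accumulator(ms, mdl, 0.5, c(110, 90))
  expect_equal(acc$grid, want, tolerance = 1e-12)
  # the global max lies within one annulus half-thickness of the center
  fc <- find_center(acc, smooth_sigma = 0)
  hw <- max(0.05 * max(mdl$center_distance), sqrt(2) / 2)
  expect_lte(sqrt(sum((fc$cell - c(55, 42))^2)), hw + 1)
  expect_identical(fc$cell, oracle_argmax(acc$grid))
})

test_that("total accumulator mass never exceeds the summed eligible weights", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    mdl <- fx_synthetic_model(u = runif(n, 10, 90), v = runif(n, 10, 70),
                              center = c(runif(1, 20, 80), runif(1, 20, 60)),
                              seed = i)
    w <- runif(n)
    ms <- fx_matchset(seq_len(n), mdl$keypoints$u, mdl$keypoints$v, w)
    acc <- cast_votes(ms, mdl, 0.5, extent = c(100, 80))
    expect_lte(sum(acc$grid), sum(w[w > 0.5]) + 1e-9)
    expect_true(all(acc$grid >= 0))
  }
})

test_that("the center argmax is deterministic with a lexicographic tie rule", {
  acc <- structure(list(grid = matrix(0, 40, 40), bin_size = 1),
                   class = "ght_accumulator")
  expect_null(find_center(acc))
  acc$grid[15, 22] <- 1
  fc <- find_center(acc, smooth_sigma = 0, refine = FALSE)
  expect_identical(fc$cell, c(u = 21, v = 14))
  # two equal maxima: smallest (v, u) wins
  acc$grid[, ] <- 0
  acc$grid[20, 30] <- 1; acc$grid[10, 35] <- 1
  expect_identical(find_center(acc, smooth_sigma = 0)$cell, c(u = 34, v = 9))
  acc$grid[, ] <- 0
  acc$grid[10, 35] <- 1; acc$grid[10, 5] <- 1
  expect_identical(find_center(acc, smooth_sigma = 0)$cell, c(u = 4, v = 9))
})

test_that("vote classification honours geometry and participation", {
  mdl <- fx_synthetic_model(u = c(30, 80, 55), v = c(30, 30, 70),
                            center = c(55, 40))
  center <- c(55, 40)
  # keypoint at exactly the ring mid-distance: positive
  ms <- fx_posed_matches(mdl, center)
  cl <- classify_votes(ms, mdl, center)
  expect_identical(cl$states, rep(1L, 3))
  expect_identical(cl$positive, 1:3)
  expect_identical(cl$model$negative_streak, rep(0L, 3))
  # below the weight threshold: negative regardless of geometry
  ms_w <- fx_posed_matches(mdl, center, weight = 0.3)
  cl_w <- classify_votes(ms_w, mdl, center)
  expect_identical(cl_w$states, rep(0L, 3))
  expect_identical(cl_w$model$negative_streak, rep(1L, 3))
  # 3x the expected distance: negative
  far <- fx_matchset(1:3, center[1] + 3 * (ms$u - center[1]),
                     center[2] + 3 * (ms$v - center[2]))
  cl_f <- classify_votes(far, mdl, center)
  expect_identical(cl_f$states, rep(0L, 3))
})

test_that("scale and rotation are recovered from rigid motion of the positives", {
  set.seed(31)
  mdl <- fx_synthetic_model(u = runif(12, 30, 90), v = runif(12, 30, 70),
                            center = c(60, 50))
  # identity pose
  ms <- fx_posed_matches(mdl, c(60, 50))
  sr <- estimate_scale_rotation(ms, 1:12, c(60, 50), mdl)
  expect_equal(sr$scale, 1, tolerance = 1e-9)
  expect_equal(sr$rotation, 0, tolerance = 1e-9)
  expect_false(sr$carried)
  # rigid 30-degree rotation about the center
  th <- 30 * pi / 180
  ms_r <- fx_posed_matches(mdl, c(60, 50), theta = th)
  sr_r <- estimate_scale_rotation(ms_r, 1:12, c(60, 50), mdl)
  expect_equal(sr_r$rotation, th, tolerance = 1e-9)
  expect_equal(sr_r$scale, 1, tolerance = 1e-9)
  # uniform scaling by 1.2
  ms_s <- fx_posed_matches(mdl, c(60, 50), scale = 1.2)
  sr_s <- estimate_scale_rotation(ms_s, 1:12, c(60, 50), mdl)
  expect_equal(sr_s$scale, 1.2, tolerance = 1e-9)
  # fewer than two usable positives: previous values carried and flagged
  mdl$current_scale <- 1.4; mdl$current_rotation <- 0.3
  sr_c <- estimate_scale_rotation(ms, integer(0), c(60, 50), mdl)
  expect_true(sr_c$carried)
  expect_equal(sr_c$scale, 1.4)
  expect_equal(sr_c$rotation, 0.3)
})

test_that("annulus voting is invariant to in-plane rotation", {
  set.seed(41)
  mdl <- fx_synthetic_model(u = runif(10, 60, 140), v = runif(10, 40, 110),
                            center = c(100, 75))
  hw <- max(0.05 * max(mdl$center_distance), sqrt(2) / 2)
  for (deg in seq(0, 350, by = 10)) {
    ms <- fx_posed_matches(mdl, c(100, 75), theta = deg * pi / 180)
    acc <- cast_votes(ms, mdl, 0.5, extent = c(200, 150))
    fc <- find_center(acc)
    err <- sqrt(sum((fc$cell - c(100, 75))^2))
    expect_lte(err, hw + 1)
  }
})

test_that("with a degenerate ring and no rotation, annulus and vector voting agree", {
  set.seed(51)
  mdl <- fx_synthetic_model(u = runif(8, 40, 120), v = runif(8, 30, 90),
                            center = c(80, 60))
  ms <- fx_posed_matches(mdl, c(80, 60))
  acc <- cast_votes(ms, mdl, 0.5, extent = c(160, 120),
                    thickness_ratio = c(1, 1))
  fc <- find_center(acc, smooth_sigma = 0)
  vec <- oracle_vector_votes(ms, mdl, 0.5, c(160, 120))
  vec_max <- oracle_argmax(vec)
  expect_lte(max(abs(fc$cell - vec_max)), 1)
})

test_that("the annulus covers the true center for within-ring scale changes", {
  set.seed(61)
  mdl <- fx_synthetic_model(u = runif(10, 60, 140), v = runif(10, 40, 110),
                            center = c(100, 75))
  for (s in c(0.96, 1.0, 1.04)) {
    ms <- fx_posed_matches(mdl, c(100, 75), scale = s)
    # every inlier's ring must pass within its rasterized half-width of truth
    for (k in 1:10) {
      d_i <- mdl$center_distance[k]
      r <- vote_radius(d_i, 1.0)
      hw <- max((r[2] - r[1]) / 2, 0.5)
      dist <- sqrt((ms$u[k] - 100)^2 + (ms$v[k] - 75)^2)
      expect_lte(abs(dist - mean(r)), hw + 1e-9)
    }
  }
})

test_that("removing matches never increases accumulator mass anywhere", {
  set.seed(71)
  mdl <- fx_synthetic_model(u = runif(9, 40, 120), v = runif(9, 30, 90),
                            center = c(80, 60))
  ms <- fx_posed_matches(mdl, c(80, 60))
  full <- cast_votes(ms, mdl, 0.5, extent = c(160, 120))$grid
  keep <- c(1, 3, 5, 7, 9)
  sub <- fx_matchset(keep, ms$u[keep], ms$v[keep],
                     orientation = ms$orientation[keep])
  part <- cast_votes(sub, mdl, 0.5, extent = c(160, 120))$grid
  expect_true(all(part <= full + 1e-12))
})

test_that("center detection tolerates up to 40% uniformly random outliers", {
  set.seed(81)
  mdl <- fx_synthetic_model(u = runif(20, 60, 140), v = runif(20, 40, 110),
                            center = c(100, 75))
  ms <- fx_posed_matches(mdl, c(100, 75))
  inlier_fc <- find_center(cast_votes(ms, mdl, 0.5, extent = c(200, 150)))
  inlier_err <- sqrt(sum((inlier_fc$cell - c(100, 75))^2))
  for (rep_i in 1:5) {
    bad <- sample(20, 8)
    mso <- ms
    mso$u[bad] <- runif(8, 0, 199)
    mso$v[bad] <- runif(8, 0, 149)
    fc <- find_center(cast_votes(mso, mdl, 0.5, extent = c(200, 150)))
    err <- sqrt(sum((fc$cell - c(100, 75))^2))
    expect_lte(err, inlier_err + 1)
  }
})

test_that("accumulators export as heat-map PNGs", {
  mdl <- fx_synthetic_model(u = c(40, 60), v = c(40, 50), center = c(50, 45))
  ms <- fx_posed_matches(mdl, c(50, 45))
  acc <- cast_votes(ms, mdl, 0.5, extent = c(100, 80))
  path <- withr::local_tempfile(fileext = ".png")
  write_accumulator_png(acc, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})
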