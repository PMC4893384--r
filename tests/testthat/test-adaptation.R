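test_that("candidate collection filters by box membership and weight", {
  kp <- ghtrack:::new_keypoints(c(20, 40, 60, 90), c(20, 40, 60, 90),
                                rep(0, 4), rep(1.3, 4), rep(1, 4),
                                matrix(1, 4, 128))
  bbox <- ght_rect(10, 10, 70, 70)   # keypoint 4 outside
  zero_map <- matrix(0, 100, 100)
  expect_length(collect_candidates(kp, bbox, zero_map), 0)
  ones_map <- matrix(1, 100, 100)
  expect_length(collect_candidates(kp, bbox, ones_map), 3)
  # per-region weights {0.2, 0.6, 0.9} with threshold 0.5: two survive
  mixed <- matrix(0, 100, 100)
  mixed[1:31, 1:31] <- 0.2
  mixed[31:51, 31:51] <- 0.6
  mixed[51:71, 51:71] <- 0.9
  cand <- collect_candidates(kp, bbox, mixed, 0.5)
  expect_length(cand, 2)
  expect_setequal(cand$keypoints$u, c(40, 60))
})

test_that("the update/hold/reset decision follows the candidate hull", {
  mk <- function(u, v) {
    n <- length(u)
    structure(list(keypoints = ghtrack:::new_keypoints(
      u, v, rep(0, n), rep(1.3, n), rep(1, n), matrix(1, n, 128)),
      weight = rep(0.9, n), index = seq_len(n)),
      class = "ght_candidates")
  }
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- mk(50 + 20 * cos(ang), 50 + 20 * sin(ang))
  expect_identical(adaptation_decision(c(50, 50), ring, 5L), "UPDATE")
  expect_identical(adaptation_decision(c(50, 50), ring, 10L), "HOLD")
  expect_identical(adaptation_decision(c(200, 200), ring, 5L), "RESET")
  expect_identical(adaptation_decision(c(50, 50), mk(c(10, 20), c(10, 20)),
                                       5L), "RESET")
})

test_that("updates enroll candidates in template units and prune stale features", {
  mdl <- fx_synthetic_model(u = c(40, 60, 50, 45, 55),
                            v = c(40, 40, 60, 50, 45), center = c(50, 48))
  # candidate at distance 60 px while s_t = 1.2: stored distance 50
  set.seed(7)
  cd <- matrix(rnorm(128), 1, 128); cd <- cd / sqrt(sum(cd^2))
  cand <- structure(list(
    keypoints = ghtrack:::new_keypoints(110, 48, 0, 1.3, 1, cd),
    weight = 0.9, index = 1L), class = "ght_candidates")
  up <- apply_update(mdl, cand, center = c(50, 48), scale = 1.2,
                     rotation = 0)
  expect_length(up$center_distance, 6)
  expect_equal(up$center_distance[6], 50, tolerance = 1e-9)
  expect_identical(up$voting_state[6], 1L)
  # duplicates (same position and descriptor as an existing keypoint) rejected
  dup <- structure(list(
    keypoints = subset_kp <- ghtrack:::subset_keypoints(mdl$keypoints, 2),
    weight = 0.9, index = 1L), class = "ght_candidates")
  up2 <- apply_update(mdl, dup, center = c(50, 48), scale = 1, rotation = 0)
  expect_length(up2$center_distance, 5)
  # stale features removed, but never below half the enrollment size
  mdl$negative_streak <- c(9L, 8L, 7L, 6L, 5L)
  empty_cand <- structure(list(keypoints = ghtrack:::empty_keypoints(),
                               weight = numeric(0), index = integer(0)),
                          class = "ght_candidates")
  up3 <- apply_update(mdl, empty_cand, c(50, 48), 1, 0,
                      removal_streak = 5L, min_frac = 0.5)
  expect_length(up3$center_distance, 3)   # ceil(0.5 * 5) = 3 survivors
  expect_true(all(up3$negative_streak <= 7))
})

test_that("re-detection ignores absent objects and recovers rotated ones", {
  sq <- fx_template_sequence()
  tpl <- sq$frame(1)
  mdl <- fx_template_model()
  seg <- init_segmentation(tpl, cbind(mdl$keypoints$u, mdl$keypoints$v),
                           ght_rect(115, 75, 90, 90))
  ms0 <- match_model(mdl, mdl$keypoints)
  peak0 <- find_center(cast_votes(ms0, mdl, 0.5, extent = c(320, 240)))$peak
  # fully absent: background only
  bg_only <- generate_sequence(sequence_config(
    tibble::tibble(frame = 1, u = 1000, v = 1000, theta = 0, scale = 1),
    noise_sd = 0, seed = 11))$frame(1)
  expect_null(redetect(mdl, bg_only, seg, peak0))
  # identical reappearance
  rd <- redetect(mdl, tpl, seg, peak0)
  expect_false(is.null(rd))
  expect_lt(sqrt(sum((rd$pose[c("u", "v")] - c(160, 120))^2)), 2)
  # reappearance at 180 degrees, displaced
  rot <- generate_sequence(sequence_config(
    tibble::tibble(frame = 1, u = 120, v = 100, theta = pi, scale = 1),
    noise_sd = 0, seed = 11))$frame(1)
  rd2 <- redetect(mdl, rot, seg, peak0)
  expect_false(is.null(rd2))
  expect_lt(sqrt(sum((rd2$pose[c("u", "v")] - c(120, 100))^2)), 2)
  expect_lt(abs(ghtrack:::wrap_angle(rd2$pose["theta"] - pi)), 5 * pi / 180)
})

test_that("reset mode freezes the model and the segmentation", {
  sq <- fx_template_sequence()
  state <- ght_tracker(sq$frame(1), ght_rect(115, 75, 90, 90))
  bg_only <- generate_sequence(sequence_config(
    tibble::tibble(frame = 1, u = 1000, v = 1000, theta = 0, scale = 1),
    noise_sd = 0, seed = 11))$frame(1)
  before_model <- state$model
  before_fg <- state$seg$fg_hist
  before_post <- state$seg$prev_posterior
  st1 <- track_frame(state, bg_only)
  expect_identical(st1$record$mode, "RESET")
  st2 <- track_frame(st1$state, bg_only)
  expect_identical(st2$record$mode, "RESET")
  expect_true(is.na(st2$record$u))
  expect_identical(length(st2$state$model$keypoints),
                   length(before_model$keypoints))
  expect_equal(st2$state$seg$fg_hist, before_fg, tolerance = 1e-12)
  expect_equal(st2$state$seg$prev_posterior, before_post, tolerance = 1e-12)
})
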