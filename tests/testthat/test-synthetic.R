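test_that("an identity motion program renders identical frames with constant truth", {
  cfg <- sequence_config(tibble::tibble(frame = 1:4, u = 160, v = 120,
                                        theta = 0, scale = 1),
                         noise_sd = 0, seed = 3)
  sq <- generate_sequence(cfg)
  f1 <- sq$frame(1)
  for (t in 2:4) expect_identical(sq$frame(t), f1)
  expect_identical(length(unique(sq$truth$u)), 1L)
  expect_true(all(sq$truth$visibility == 1))
})

test_that("sequences are deterministic for a fixed seed", {
  cfg <- preset("instrument_occlusion", seed = 9, n_frames = 20)
  s1 <- generate_sequence(cfg)
  s2 <- generate_sequence(cfg)
  expect_identical(s1$frame(5), s2$frame(5))
  expect_identical(s1$frame(5), s1$frame(5))   # random access is repeatable
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_sequence(preset("instrument_occlusion", seed = 10,
                                 n_frames = 20))
  expect_false(identical(s1$frame(5), s3$frame(5)))
})

test_that("a 90-degree rotation leaves the center fixed and rotates the pixels", {
  cfg <- sequence_config(tibble::tibble(frame = 1:2, u = 160, v = 120,
                                        theta = c(0, pi / 2), scale = 1),
                         noise_sd = 0, seed = 4)
  sq <- generate_sequence(cfg)
  expect_equal(sq$truth$u, c(160, 160))
  f1 <- sq$frame(1); f2 <- sq$frame(2)
  # sample the target interior at matched pre-/post-rotation positions:
  # the pixel at center + (du, dv) in frame 1 appears at center + (-dv, du)
  offs <- expand.grid(du = seq(-30, 30, by = 6), dv = seq(-30, 30, by = 6))
  for (c3 in 1:3) {
    a <- ghtrack:::bilinear_sample(f1[, , c3], 160 + offs$du, 120 + offs$dv)
    b <- ghtrack:::bilinear_sample(f2[, , c3], 160 - offs$dv, 120 + offs$du)
    expect_lt(mean(abs(a - b)), 0.02)   # interpolation tolerance
  }
})

test_that("ground truth visibility reflects occlusion and leaving the view", {
  sq <- generate_sequence(preset("out_of_view", seed = 1))
  away <- which(!sq$truth$in_view)
  expect_gte(length(away), 30)
  expect_identical(away, seq(min(away), max(away)))   # contiguous interval
  expect_true(all(sq$truth$visibility[away] <= 0.05))
  expect_true(all(sq$truth$visibility[1:20] == 1))
  occ <- generate_sequence(preset("instrument_occlusion", seed = 1))
  expect_lt(min(occ$truth$visibility), 0.5)
  expect_true(all(occ$truth$visibility[1:30] == 1))
})

test_that("presets encode the canonical regime designs", {
  expect_gte(nrow(preset("long_term")$poses), 2000)
  lt <- preset("long_term", n_frames = 100, rotate = FALSE, zoom = FALSE)
  expect_true(all(lt$poses$theta == 0))
  expect_true(all(lt$poses$scale == 1))
  expect_gt(diff(range(lt$poses$u)), 10)   # still translating
  io <- preset("instrument_occlusion")
  expect_identical(io$occluder$type, "patch")
  to <- preset("tissue_occlusion")
  expect_identical(to$occluder$type, "blob")
  expect_error(preset("nope"))
  expect_error(sequence_config(preset("long_term", n_frames = 5)$poses,
                               target_size = 500))
})

test_that("the enrolled target carries enough texture for keypoint tracking", {
  for (seed in 1:3) {
    sq <- generate_sequence(preset("long_term", seed = seed, n_frames = 1))
    bb <- ght_rect(sq$truth$u[1] - 45, sq$truth$v[1] - 45, 90, 90)
    kp <- detect_keypoints(sq$frame(1), region = bb)
    expect_gte(length(kp), 30)
  }
})

test_that("the camouflage palette overlaps the background hue mode", {
  sep <- generate_sequence(preset("long_term", n_frames = 1, seed = 2))
  cam <- generate_sequence(preset("long_term", n_frames = 1, seed = 2,
                                  palette = "camouflage"))
  hue_of <- function(img, u, v) {
    grDevices::rgb2hsv(matrix(img[v, u, ], 3))[1, ]
  }
  # target center hue vs background corner hue
  sep_t <- hue_of(sep$frame(1), 160, 120); sep_b <- hue_of(sep$frame(1), 10, 10)
  cam_t <- hue_of(cam$frame(1), 160, 120); cam_b <- hue_of(cam$frame(1), 10, 10)
  expect_gt(abs(sep_t - sep_b), 0.2)
  expect_lt(abs(cam_t - cam_b), 0.1)
})

test_that("sequences export frames and ground truth to disk", {
  dir <- withr::local_tempdir()
  sq <- generate_sequence(sequence_config(
    tibble::tibble(frame = 1:3, u = 160, v = 120, theta = 0, scale = 1),
    noise_sd = 0, seed = 6))
  write_sequence(sq, dir)
  files <- list.files(dir, pattern = "\\.png$")
  expect_length(files, 3)
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_identical(names(gt), c("frame", "u", "v", "theta", "scale",
                                "visibility", "in_view"))
  # frames written to disk read back within 8-bit quantization
  back <- read_frame(file.path(dir, files[1]))
  expect_lt(max(abs(back - sq$frame(1))), 1 / 255 + 1e-9)
})
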