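test_that("initialization builds histograms from hull and surround regions", {
  # one-colour image: whatever region is used, one bin carries all the mass
  img <- fx_flat_image(120, 160, c(0.2, 0.4, 0.8))
  pos <- cbind(c(60, 100, 80), c(40, 40, 80))
  seg <- init_segmentation(img, pos, ght_rect(50, 30, 60, 60))
  expect_identical(sum(seg$fg_hist > 0), 1L)
  expect_equal(sum(seg$fg_hist), 1, tolerance = 1e-9)
  expect_equal(sum(seg$bg_hist), 1, tolerance = 1e-9)
  expect_true(all(seg$prev_posterior == 0.5))
})

test_that("a degenerate hull falls back to the detected box", {
  img <- fx_flat_image(120, 160, c(0.9, 0.1, 0.1))
  collinear <- cbind(c(60, 70, 80), c(50, 50, 50))
  expect_no_error(seg <- init_segmentation(img, collinear,
                                           ght_rect(50, 30, 60, 60)))
  expect_identical(sum(seg$fg_hist > 0), 1L)
})

test_that("background histogram concentrates on the background colour", {
  # object colour inside the hull region, distinct background elsewhere
  img <- fx_flat_image(240, 320, c(0.8, 0.3, 0.2))
  obj_rgb <- c(0.2, 0.3, 0.9)
  img[81:160, 121:200, ] <- rep(obj_rgb, each = 80 * 80)
  pos <- cbind(c(130, 190, 190, 130), c(90, 90, 150, 150))
  seg <- init_segmentation(img, pos, ght_rect(120, 80, 80, 80))
  bg_bin <- ghtrack:::hsv_bin_index(matrix(c(0.8, 0.3, 0.2), 1))
  obj_bin <- ghtrack:::hsv_bin_index(matrix(obj_rgb, 1))
  expect_gt(seg$bg_hist[bg_bin], 0.95)
  expect_gt(seg$fg_hist[obj_bin], 0.95)
  expect_false(bg_bin == obj_bin)
})

test_that("the posterior matches a scalar two-class forward filter", {
  # limit cases first
  colA <- c(0.2, 0.4, 0.8)
  binA <- ghtrack:::hsv_bin_index(matrix(colA, 1))
  img <- fx_flat_image(3, 3, colA)
  mk_hist <- function(bin, mass = 1) { h <- rep(0, 152); h[bin] <- mass; h }
  # uninformative: equal likelihoods, symmetric transitions, prior 0.5
  seg <- fx_segmentation(mk_hist(binA), mk_hist(binA), matrix(0.5, 3, 3))
  expect_equal(posterior_map(seg, img)$map, matrix(0.5, 3, 3),
               tolerance = 1e-12)
  # likelihood excludes background
  seg <- fx_segmentation(mk_hist(binA), rep(0, 152), matrix(0.3, 3, 3))
  expect_equal(posterior_map(seg, img)$map, matrix(1, 3, 3),
               tolerance = 1e-12)
  # random small cases against the scalar oracle
  set.seed(123)
  for (i in 1:25) {
    rgbs <- matrix(runif(9), 3)
    img3 <- array(0, dim = c(1, 3, 3))
    for (px in 1:3) img3[1, px, ] <- rgbs[, px]
    fg <- runif(152); fg <- fg / sum(fg)
    bg <- runif(152); bg <- bg / sum(bg)
    prior <- matrix(runif(3), 1, 3)
    stay <- runif(1, 0.5, 0.95)
    seg <- fx_segmentation(fg, bg, prior, stay = stay)
    got <- posterior_map(seg, img3)$map
    for (px in 1:3) {
      bin <- ghtrack:::hsv_bin_index(matrix(rgbs[, px], 1))
      want <- oracle_bayes_step(fg[bin], bg[bin], prior[1, px], stay)
      expect_equal(got[1, px], want, tolerance = 1e-9)
    }
  }
})

test_that("foreground and background posteriors are complementary", {
  set.seed(5)
  img <- array(runif(40 * 60 * 3), dim = c(40, 60, 3))
  fg <- runif(152); fg <- fg / sum(fg)
  bg <- runif(152); bg <- bg / sum(bg)
  prior <- matrix(runif(40 * 60), 40, 60)
  m_fg <- fx_segmentation(fg, bg, prior)
  m_bg <- fx_segmentation(bg, fg, 1 - prior)   # the symmetric filter
  p_fg <- posterior_map(m_fg, img)$map
  p_bg <- posterior_map(m_bg, img)$map
  expect_equal(p_fg + p_bg, matrix(1, 40, 60), tolerance = 1e-9)
})

test_that("raising a colour's foreground likelihood never lowers its posterior", {
  colA <- c(0.7, 0.2, 0.2)
  binA <- ghtrack:::hsv_bin_index(matrix(colA, 1))
  img <- fx_flat_image(2, 2, colA)
  set.seed(8)
  bg <- runif(152); bg <- bg / sum(bg)
  prior <- matrix(0.4, 2, 2)
  last <- -Inf
  for (mass in seq(0.05, 1, by = 0.05)) {
    fg <- rep((1 - mass) / 151, 152); fg[binA] <- mass
    p <- posterior_map(fx_segmentation(fg, bg, prior), img)$map[1, 1]
    expect_gte(p, last)
    last <- p
  }
})

test_that("temporal smoothing damps single-frame colour flicker", {
  colA <- c(0.3, 0.6, 0.9)
  binA <- ghtrack:::hsv_bin_index(matrix(colA, 1))
  img <- fx_flat_image(2, 2, colA)
  fg <- rep(1e-3, 152); fg[binA] <- 0.1    # flicker: colour now looks bg-ish
  bg <- rep(1e-3, 152); bg[binA] <- 0.9
  pure_likelihood <- 0.1 / (0.1 + 0.9)
  confident_prior <- matrix(0.95, 2, 2)
  p <- posterior_map(fx_segmentation(fg, bg, confident_prior, stay = 0.6),
                     img)$map[1, 1]
  expect_gt(p, pure_likelihood)
})

test_that("histogram updates follow the exponential-forgetting rule", {
  colA <- c(0.2, 0.4, 0.8); colB <- c(0.8, 0.5, 0.1)
  binA <- ghtrack:::hsv_bin_index(matrix(colA, 1))
  binB <- ghtrack:::hsv_bin_index(matrix(colB, 1))
  hull <- cbind(c(40, 120, 80), c(30, 30, 90))
  bbox <- ght_rect(40, 20, 80, 80)
  # fixed point: new-frame hull histogram identical to the old one
  imgA <- fx_flat_image(160, 200, colA)
  segA <- init_segmentation(imgA, hull, bbox)
  upA <- update_histograms(segA, imgA, hull, bbox)
  expect_equal(upA$fg_hist, segA$fg_hist, tolerance = 1e-12)
  # delta = 0 freezes the model regardless of the frame
  imgB <- fx_flat_image(160, 200, colB)
  up0 <- update_histograms(segA, imgB, hull, bbox, delta = 0)
  expect_equal(up0$fg_hist, segA$fg_hist, tolerance = 1e-12)
  # two-bin substitution: old mass on A, new hull entirely on B
  upB <- update_histograms(segA, imgB, hull, bbox)
  expect_equal(upB$fg_hist[binA], 0.9, tolerance = 1e-12)
  expect_equal(upB$fg_hist[binB], 0.1, tolerance = 1e-12)
  expect_equal(sum(upB$fg_hist), 1, tolerance = 1e-9)
  expect_equal(sum(upB$bg_hist), 1, tolerance = 1e-9)
  # empty hull leaves the foreground untouched
  upE <- update_histograms(segA, imgB, NULL, bbox)
  expect_equal(upE$fg_hist, segA$fg_hist, tolerance = 1e-12)
})

test_that("keypoint weights average the posterior over a clipped patch", {
  map <- matrix(0.7, 20, 30)
  expect_equal(keypoint_weight(map, 10, 10, 4), 0.7, tolerance = 1e-12)
  # corner: the patch mean uses only the valid intersection
  map2 <- matrix(0, 20, 30)
  map2[1:3, 1:3] <- 1
  expect_equal(keypoint_weight(map2, 0, 0, 2),
               mean(map2[1:3, 1:3]), tolerance = 1e-12)
  # listed 3x3 fixture: arithmetic mean by hand
  vals <- matrix(seq(0, 1, length.out = 9), 3, 3)
  map3 <- matrix(0.5, 9, 9)
  map3[4:6, 4:6] <- vals
  expect_equal(keypoint_weight(map3, 4, 4, 1), mean(vals), tolerance = 1e-12)
})

test_that("probability maps export as 8-bit PNG", {
  map <- matrix(seq(0, 1, length.out = 12), 3, 4)
  path <- withr::local_tempfile(fileext = ".png")
  write_probability_png(map, path)
  back <- png::readPNG(path)
  expect_equal(round(back * 255), round(map * 255))
})
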