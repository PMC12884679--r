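# Preprocessing: green channel, histogram equalisation, CLAHE, denoising,
# joint augmentation.

test_that("normalised green channel follows the channel-ratio formula", {
  px <- array(0, dim = c(2, 2, 3))
  px[1, 1, ] <- c(0, 255, 0) / 255    # pure green
  px[1, 2, ] <- c(0, 0, 0)            # degenerate
  px[2, 1, ] <- c(60, 120, 60) / 255
  px[2, 2, ] <- c(30, 30, 30) / 255
  g <- extract_green_normalized(px)
  expect_equal(g[1, 1], 1)
  expect_equal(g[1, 2], 0)
  expect_equal(g[2, 1], 0.5)
  expect_equal(g[2, 2], 1 / 3, tolerance = 1e-12)
  raw <- extract_green_normalized(px, "raw")
  expect_equal(raw[2, 1], 120 / 255)
  expect_error(extract_green_normalized(matrix(0, 2, 2)), "3-channel")
})

test_that("histogram equalisation matches the cumulative-count mapping", {
  img <- matrix(c(0, 0, 1, 1), 2, 2)
  out <- histogram_equalize(img, levels = 256L, rescale = FALSE)
  expect_equal(out[img == 0][1], (255 / 4) * 2)
  expect_equal(out[img == 1][1], 255)
  # constant image maps to Gmax (all mass at/below every pixel)
  cst <- histogram_equalize(matrix(0.4, 5, 5))
  expect_true(all(abs(cst - 1) < 1e-12))
  # monotone non-decreasing in input level; output within range
  set.seed(1)
  x <- matrix(runif(400), 20, 20)
  y <- histogram_equalize(x)
  ord <- order(x)
  expect_true(all(diff(y[ord]) >= -1e-12))
  expect_true(min(y) >= 0 && max(y) <= 1)
  expect_error(histogram_equalize(x, levels = 1L), "levels")
})

test_that("CLAHE degenerates to global equalisation and handles constants", {
  set.seed(2)
  x <- matrix(runif(32 * 32), 32, 32)
  global <- histogram_equalize(x)
  tiled <- clahe(x, clip_limit = Inf, tile_grid = c(1L, 1L))
  expect_equal(as.vector(tiled), as.vector(global), tolerance = 1e-12)
  cst <- clahe(matrix(0.3, 32, 32))
  expect_true(max(cst) - min(cst) < 1e-12)
  expect_error(clahe(x, clip_limit = 0), "clip_limit")
  expect_error(clahe(x, tile_grid = c(0L, 4L)), "tile_grid")
})

test_that("CLAHE increases local contrast of a faint vessel patch", {
  wins <- vapply(1:10, function(sd) {
    set.seed(sd)
    img <- matrix(0.5, 48, 48)
    img[22:26, ] <- 0.55                       # faint vessel
    img <- img + matrix(rnorm(48 * 48, sd = 0.005), 48, 48)
    img <- pmin(pmax(img, 0), 1)
    sd(clahe(img, clip_limit = 4, tile_grid = c(4L, 4L))) > sd(img)
  }, logical(1))
  expect_true(all(wins))
})

test_that("denoising is a normalised smoother", {
  x <- matrix(runif(100), 10, 10)
  expect_equal(denoise(x, 0), x, ignore_attr = TRUE)
  cst <- matrix(0.7, 10, 10)
  expect_equal(denoise(cst, 2.5), cst, ignore_attr = TRUE, tolerance = 1e-12)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  expect_equal(sum(denoise(imp, 1.5)), 1, tolerance = 1e-10)
  expect_error(denoise(x, -1), "sigma")
})

test_that("joint augmentation keeps image, mask and labels aligned", {
  s <- render_sample(vessel_tree_spec(seed = 9L, image_size = c(96L, 96L),
                                      disc_center = c(48, 48),
                                      disc_radius = 10,
                                      root_width_artery = 5,
                                      root_width_vein = 8,
                                      branch_depth = 1L))
  img <- s$image$pixels[, , 2]
  plan <- augment_plan(angles = c(-20, 40, 90, 180, 270), flip = TRUE,
                       brightness_range = c(-0.05, 0.05),
                       scale_range = NULL, seed = 3L)
  out <- augment(img, s$vessel_mask, s$av_labels, plan)
  expect_length(out, 6L)
  for (tr in out) {
    # mask support and label support never separate
    expect_identical(as.vector(tr$mask == 1L),
                     as.vector(tr$labels %in% c(1L, 2L)))
    expect_identical(dim(tr$image), dim(img))
  }
  expect_error(augment(img[1:10, ], s$vessel_mask, s$av_labels, plan),
               "dimensions")
})

test_that("right-angle rotations are exact permutations", {
  s <- fixture_sample()
  img <- s$image$pixels[, , 2]
  plan <- augment_plan(angles = c(90, 180, 270), flip = FALSE,
                       brightness_range = NULL, scale_range = NULL)
  out <- augment(img, s$vessel_mask, s$av_labels, plan)
  for (tr in out) {
    expect_identical(sum(tr$mask), sum(s$vessel_mask))
    expect_identical(sort(table(tr$labels)), sort(table(s$av_labels)))
  }
  # 90 deg applied four times is the identity
  cur <- list(image = img, mask = s$vessel_mask, labels = s$av_labels)
  for (i in 1:4) {
    step <- augment(cur$image, cur$mask, cur$labels,
                    augment_plan(angles = 90, flip = FALSE,
                                 brightness_range = NULL,
                                 scale_range = NULL))[[1]]
    cur <- step[c("image", "mask", "labels")]
  }
  expect_equal(cur$image, img, ignore_attr = TRUE)
  expect_identical(cur$mask, s$vessel_mask)
  expect_identical(cur$labels, s$av_labels)
})

test_that("arbitrary-angle rotations approximately round-trip", {
  s <- fixture_sample()
  fwd <- retavr:::transform_triple(s$image$pixels[, , 2], s$vessel_mask,
                                   s$av_labels, theta = 20)
  back <- retavr:::transform_triple(fwd$image, fwd$mask, fwd$labels,
                                    theta = -20)
  # corners rotate out of frame and are filled with background, so the
  # resampling round-trip is judged inside the inscribed circle, whose
  # pixels stay in frame under any rotation about the centre
  h <- nrow(s$vessel_mask)
  rr <- matrix(seq_len(h), h, h); cc <- t(rr)
  keep <- (rr - (h + 1) / 2)^2 + (cc - (h + 1) / 2)^2 <= (h / 2)^2
  expect_gt(dice_coef(back$mask[keep], s$vessel_mask[keep]), 0.95)
  # a near-identity resampling round-trip is exact
  near <- retavr:::transform_triple(s$image$pixels[, , 2], s$vessel_mask,
                                    s$av_labels, theta = 1e-6)
  expect_equal(near$mask, s$vessel_mask, ignore_attr = TRUE)
})

test_that("the enhancement chain preserves shape and range", {
  s <- fixture_sample()
  enh <- enhance_fundus(s$image)
  expect_identical(dim(enh), dim(s$vessel_mask))
  expect_true(min(enh) >= 0 && max(enh) <= 1)
  expect_true(length(attr(enh, "provenance")) >= 2)
})
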