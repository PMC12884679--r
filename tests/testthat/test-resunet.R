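# Res-UNet building blocks and training behaviour.

test_that("relu matches its two branches and the boundary", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  expect_equal(relu(0), 0)
  expect_equal(relu(c(-1, 0.5)), c(0, 0.5))
})

test_that("dilated convolution implements the strided-tap formula", {
  expect_equal(dilated_conv(c(3, 1, 4), 1, r = 5, pad = "same"),
               c(3, 1, 4))
  expect_equal(dilated_conv(1:5, c(1, 1), r = 2, pad = "valid"),
               c(4, 6, 8))
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(20); w <- rnorm(3); r <- sample(1:3, 1)
    expect_equal(dilated_conv(x, w, r, pad = "valid"),
                 oracle_dilated_1d(x, w, r), tolerance = 1e-12)
  }
})

test_that("the network conv2d with r = 1 matches a brute-force oracle", {
  set.seed(5)
  for (i in 1:5) {
    p <- retavr:::conv_param(3L, 2L, 2L)
    x <- array(rnorm(7 * 6 * 2), c(7, 6, 2))
    got <- retavr:::conv2d_forward(x, p)$y
    want <- oracle_conv2d_same(x, conv_weight_array(p))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("residual blocks are identity at zero weights and keep shape", {
  p <- retavr:::res_block_param(3L, 3L)
  p$conv1$W[] <- 0; p$conv2$W[] <- 0
  x <- array(runif(6 * 8 * 3), c(6, 8, 3))
  out <- retavr:::res_block_forward(x, p)
  expect_equal(out$y, x)
  # with a projection shortcut the spatial dims are still preserved
  p2 <- retavr:::res_block_param(2L, 5L)
  x2 <- array(runif(6 * 8 * 2), c(6, 8, 2))
  expect_identical(dim(retavr:::res_block_forward(x2, p2)$y)[1:2],
                   c(6L, 8L))
})

test_that("gradients flow through the shortcut even with zeroed conv path", {
  set.seed(6)
  p <- retavr:::res_block_param(1L, 1L)
  p$conv1$W[] <- 0; p$conv2$W[] <- 0
  x <- array(runif(16), c(4, 4, 1))
  dy <- array(runif(16), c(4, 4, 1))
  fw <- retavr:::res_block_forward(x, p)
  bw <- retavr:::res_block_backward(dy, p, fw$cache)
  # analytic dx equals dy exactly (block is the identity)
  expect_equal(bw$dx, dy)
  # and matches a finite difference through the block
  eps <- 1e-6
  i <- 7
  x2 <- x; x2[i] <- x2[i] + eps
  num <- (sum(retavr:::res_block_forward(x2, p)$y * dy) -
            sum(fw$y * dy)) / eps
  expect_equal(bw$dx[i], num, tolerance = 1e-5)
})

test_that("model shapes, output range and parameter count are right", {
  cfg <- seg_config(depth = 2L, base_channels = 4L,
                    dilation_rates = c(1L, 2L))
  model <- build_resunet(cfg, seed = 2L)
  x <- array(runif(16 * 24), c(16, 24, 1))
  fw <- retavr:::resunet_forward(model, x)
  expect_identical(dim(fw$prob), c(16L, 24L))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  expect_error(retavr:::resunet_forward(model, array(0, c(6, 6, 1))),
               "divisible")

  # hand-enumerated parameter count for depth 1, base 1, rates {1,2,4}:
  #   encoder block: conv1 (3*3*1*1 + 1) + conv2 (3*3*1*1 + 1)      = 20
  #   bottleneck: 3 dilated convs 1 -> 2: 3 * (3*3*1*2 + 2)          = 60
  #   decoder: upconv 2 -> 1 (4*2*1 + 1) + block 1 -> 1 (20)         = 29
  #   head: 1x1 conv 1 -> 1 (1 + 1)                                  =  2
  count <- function(l) {
    if (is.null(l)) return(0L)
    if (is.list(l)) {
      nm <- names(l)
      tot <- 0L
      for (k in seq_along(l)) {
        if (!is.null(nm) && nm[k] %in% c("k", "r", "cin", "cout")) next
        tot <- tot + count(l[[k]])
      }
      return(tot)
    }
    length(l)
  }
  m1 <- build_resunet(seg_config(depth = 1L, base_channels = 1L), seed = 1L)
  expect_identical(count(m1$params), 111L)
})

test_that("binary cross-entropy matches its closed forms", {
  q <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lt(bce_loss(q, q), 1e-5)
  expect_equal(bce_loss(matrix(0.5), matrix(1)), log(2), tolerance = 1e-9)
  set.seed(7)
  p <- matrix(runif(16), 4, 4); t <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_equal(bce_loss(p, t), bce_loss(1 - p, 1 - t), tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "mismatch")
})

test_that("binarize thresholds correctly and monotonically", {
  p <- matrix(c(0.4, 0.6, 0.5, 0.2), 2, 2)
  expect_identical(binarize(p, 0.5), matrix(c(0L, 1L, 1L, 0L), 2, 2))
  set.seed(8)
  pr <- matrix(runif(100), 10, 10)
  m1 <- binarize(pr, 0.3); m2 <- binarize(pr, 0.7)
  expect_true(all(m2 <= m1))
  expect_identical(sum(binarize(pr, 0.45)), sum(pr >= 0.45))
  expect_error(binarize(pr, 1), "threshold")
})

test_that("training reduces the loss deterministically", {
  samples <- fixture_seg_samples(4L, seed = 21L)
  cfg <- seg_config(depth = 2L, base_channels = 4L,
                    dilation_rates = c(1L, 2L))
  tcfg <- train_config(epochs = 4L, seed = 3L, patch_size = 32L)
  m1 <- train_segmenter(samples, cfg, tcfg)
  m2 <- train_segmenter(samples, cfg, tcfg)
  expect_identical(m1$history, m2$history)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  pr <- predict_vessels(m1, samples[[1]]$x)
  expect_true(all(pr$prob > 0 & pr$prob < 1))
  expect_identical(dim(pr$prob), dim(samples[[1]]$x))
})

test_that("prediction pads and crops odd-sized inputs consistently", {
  cfg <- seg_config(depth = 2L, base_channels = 2L, dilation_rates = 1L)
  model <- build_resunet(cfg, seed = 4L)
  img <- matrix(runif(20 * 20), 20, 20)
  whole <- predict_vessels(model, img)$prob
  direct <- retavr:::resunet_forward(model,
                                     array(img, c(20, 20, 1)))$prob
  expect_equal(whole, direct, tolerance = 1e-12)
  odd <- matrix(runif(19 * 17), 19, 17)
  expect_identical(dim(predict_vessels(model, odd)$prob), c(19L, 17L))
})

test_that("checkpoints round-trip through disk", {
  model <- build_resunet(seg_config(depth = 1L, base_channels = 2L),
                         seed = 9L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  re <- load_checkpoint(path)
  x <- array(runif(16 * 16), c(16, 16, 1))
  expect_identical(retavr:::resunet_forward(model, x)$prob,
                   retavr:::resunet_forward(re, x)$prob)
})
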