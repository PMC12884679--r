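# GCN layers, losses, training and label-image rendering.

test_that("gcn_layer reproduces hand-computed propagations", {
  # isolated self-looped nodes, identity weights, non-negative features
  m <- matrix(0L, 1, 5); m[1, c(1, 3, 5)] <- 1L
  g <- build_graph(m)            # three isolated nodes
  W_hat <- normalize_adjacency(g)
  H <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(gcn_layer(H, W_hat, diag(1)), H, ignore_attr = TRUE)

  # K2 with self-loops: W_hat entries all 0.5; H = [2, 0], weight 1
  g2 <- build_graph(matrix(1L, 1, 2))
  out <- gcn_layer(matrix(c(2, 0), 2, 1), normalize_adjacency(g2),
                   matrix(1))
  expect_equal(out, matrix(c(1, 1), 2, 1), ignore_attr = TRUE)

  expect_error(gcn_layer(matrix(1, 2, 3), normalize_adjacency(g2),
                         matrix(1, 2, 1)), "dimension")
})

test_that("forward stacking, softmax rows and the composition oracle", {
  set.seed(20)
  m <- matrix(rbinom(36, 1, 0.6), 6, 6)
  g <- extract_node_features(build_graph(m),
                             array(rnorm(36 * 3), c(6, 6, 3)))
  cfg <- gcn_config(n_layers = 1L, hidden_dim = 8L, seed = 2L)
  params <- retavr:::gcn_init_params(3L, cfg)
  fw <- gcn_forward(g, params)
  expect_equal(rowSums(fw$scores), rep(1, g$n_nodes), tolerance = 1e-9)
  # n_layers = 1 is one linear gcn_layer followed by softmax
  W_hat <- normalize_adjacency(g)
  Z <- gcn_layer(g$features, W_hat, params[[1]]$W, params[[1]]$b,
                 activation = "identity")
  expect_equal(fw$scores, retavr:::row_softmax(Z), tolerance = 1e-12)
})

test_that("predictions are permutation-equivariant", {
  set.seed(21)
  n <- 6
  A <- Matrix::Matrix(matrix(c(1, 1, 0, 0, 0, 0,
                               1, 1, 1, 0, 0, 0,
                               0, 1, 1, 0, 0, 0,
                               0, 0, 0, 1, 1, 0,
                               0, 0, 0, 1, 1, 1,
                               0, 0, 0, 0, 1, 1), n, n), sparse = TRUE)
  d <- Matrix::rowSums(A)
  W_hat <- Matrix::Diagonal(x = 1 / sqrt(d)) %*% A %*%
    Matrix::Diagonal(x = 1 / sqrt(d))
  H <- matrix(rnorm(n * 2), n, 2)
  th <- matrix(rnorm(2 * 2), 2, 2)
  out <- gcn_layer(H, W_hat, th)
  perm <- sample(n)
  out_p <- gcn_layer(H[perm, ], W_hat[perm, perm], th)
  expect_equal(out_p, out[perm, ], tolerance = 1e-12)
  # two connected nodes with identical inputs get identical outputs
  expect_equal(out[1, ], gcn_layer(H, W_hat, th)[1, ])
})

test_that("dice loss matches its closed forms and eps placements", {
  expect_lt(dice_loss(c(1, 0, 1), c(1, 0, 1)), 1e-5)
  expect_gt(dice_loss(rep(1, 4), rep(0, 4)), 1 - 1e-5)
  expect_equal(dice_loss(c(1, 0), c(0.5, 0.5), eps = 1e-12), 1 / 3,
               tolerance = 1e-6)
  # printed placement: eps in the numerator only
  got <- dice_loss(c(1, 0), c(0.5, 0.5), eps = 0.1,
                   eps_placement = "printed")
  expect_equal(got, 1 - (2 * 0.5 + 0.1) / (1 + 0.5), tolerance = 1e-12)
  expect_error(dice_loss(c(1, 0), c(0.5, 0.5), eps = 0), "eps")
  expect_error(dice_loss(c(1, 0), 0.5), "mismatch")
})

test_that("masked cross-entropy matches ln 2 and rejects empty supervision", {
  expect_lt(ce_loss(c(1, 0), c(1, 0)), 1e-5)
  expect_equal(ce_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(ce_loss(c(1, NA, 0), c(0.5, 0.9, 0.5)), log(2),
               tolerance = 1e-9)
  expect_error(ce_loss(c(NA_real_, NA_real_), c(0.5, 0.5)), "masked")
})

test_that("training is deterministic and reduces the combined loss", {
  mk_graph <- function(seed) {
    set.seed(seed)
    m <- matrix(0L, 12, 12); m[3:4, ] <- 1L; m[9:10, ] <- 1L
    lab_img <- matrix(0L, 12, 12); lab_img[3:4, ] <- 1L; lab_img[9:10, ] <- 2L
    f <- matrix(0, 12, 12)
    f[3:4, ] <- 0.8 + rnorm(24, sd = 0.05)
    f[9:10, ] <- 0.4 + rnorm(24, sd = 0.05)
    g <- extract_node_features(build_graph(m), f)
    list(g = g, lb = lab_img[cbind(g$nodes$row + 1, g$nodes$col + 1)])
  }
  drops <- vapply(1:10, function(sd) {
    gx <- mk_graph(sd)
    mod <- train_gcn(list(gx$g), list(gx$lb),
                     gcn_config(epochs = 30L, seed = sd, hidden_dim = 8L))
    tail(mod$history$loss, 1) < mod$history$loss[1]
  }, logical(1))
  expect_gte(sum(drops), 9L)

  gx <- mk_graph(99)
  cfg <- gcn_config(epochs = 20L, seed = 5L, hidden_dim = 8L)
  h1 <- train_gcn(list(gx$g), list(gx$lb), cfg)$history
  h2 <- train_gcn(list(gx$g), list(gx$lb), cfg)$history
  expect_identical(h1, h2)
  expect_error(train_gcn(list(), list(), cfg), "no training graphs")
})

test_that("intensity-separable classes are recovered above 0.9 accuracy", {
  set.seed(30)
  m <- matrix(0L, 24, 24); m[5:8, ] <- 1L; m[17:20, ] <- 1L
  lab_img <- matrix(0L, 24, 24); lab_img[5:8, ] <- 1L; lab_img[17:20, ] <- 2L
  f <- matrix(0, 24, 24)
  f[5:8, ] <- 0.8 + rnorm(96, sd = 0.05)
  f[17:20, ] <- 0.4 + rnorm(96, sd = 0.05)
  g <- extract_node_features(build_graph(m), f)
  lb <- lab_img[cbind(g$nodes$row + 1, g$nodes$col + 1)]
  mod <- train_gcn(list(g), list(lb), gcn_config(epochs = 150L, seed = 2L))
  acc <- mean(predict_av(mod, g)$labels == lb)
  expect_gt(acc, 0.9)
})

test_that("label images follow the colour convention and round-trip", {
  m <- matrix(0L, 5, 5); m[2, 2:4] <- 1L; m[4, 1:3] <- 1L
  g <- build_graph(m)
  pred <- structure(list(scores = matrix(c(1, 0), g$n_nodes, 2,
                                         byrow = TRUE),
                         labels = rep(1L, g$n_nodes)),
                    class = "node_prediction")
  img <- labels_to_image(pred, g)
  expect_true(all(img[m == 1L] == 1L))
  expect_true(all(img[m == 0L] == 0L))
  # mixed prediction: pixel class counts equal node class counts
  pred$labels <- rep(c(1L, 2L), length.out = g$n_nodes)
  img2 <- labels_to_image(pred, g)
  expect_identical(sum(img2 == 1L), sum(pred$labels == 1L))
  expect_identical(sum(img2 == 2L), sum(pred$labels == 2L))
  # round-trip through the RGB encoding
  expect_identical(rgb_to_av_labels(av_labels_to_rgb(img2)), img2)
  expect_error(labels_to_image(pred, g, shape = c(2L, 2L)), "outside")
})
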