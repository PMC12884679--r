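# Residual U-Net vessel segmenter.
#
# Encoder: `depth` residual blocks (two 3x3 conv + ReLU stages with an
# additive shortcut; 1x1 projection when the channel count changes), each
# followed by 2x2 max pooling, channels doubling per level.  Bottleneck:
# parallel dilated 3x3 convolutions at the configured rates, fused by
# summation.  Decoder: 2x2 transposed convolutions halving channels, long
# skip connections merged by summation (not concatenation), then a
# residual block.  Head: 1x1 convolution + sigmoid.

#' Segmentation network configuration
#'
#' @param depth number of down/up-sampling levels (default 4).
#' @param base_channels feature channels at the first level (default 16).
#' @param dilation_rates dilation rates of the parallel bottleneck
#'   convolutions (distinct integers >= 1).
#' @param use_batch_norm normalise each conv stage per channel (batch-1
#'   instance statistics); off by default.
#' @param dropout_rate dropout probability on the bottleneck during
#'   training, in `[0, 1)`.
#' @return `seg_config` list.
#' @export
seg_config <- function(depth = 4L, base_channels = 16L,
                       dilation_rates = c(1L, 2L, 4L),
                       use_batch_norm = FALSE, dropout_rate = 0) {
  if (depth < 1 || base_channels < 1) stop("depth and base_channels must be >= 1")
  if (any(dilation_rates < 1) || anyDuplicated(dilation_rates))
    stop("dilation rates must be distinct integers >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate in [0, 1)")
  list(depth = as.integer(depth), base_channels = as.integer(base_channels),
       dilation_rates = as.integer(dilation_rates),
       use_batch_norm = isTRUE(use_batch_norm), dropout_rate = dropout_rate)
}

#' Training configuration
#'
#' @param epochs,batch_size,learning_rate,optimiser,seed,patch_size the
#'   usual knobs; optimiser is `"adam"` (default) or `"sgd"`.
#' @param patches_per_image random patches drawn per image per epoch.
#' @return `train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_size = 1L, learning_rate = 1e-3,
                         optimiser = c("adam", "sgd"), seed = 1L,
                         patch_size = 64L, patches_per_image = 1L) {
  optimiser <- match.arg(optimiser)
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       learning_rate = learning_rate, optimiser = optimiser,
       seed = as.integer(seed), patch_size = as.integer(patch_size),
       patches_per_image = as.integer(patches_per_image))
}

res_block_param <- function(cin, cout, use_norm = FALSE) {
  p <- list(conv1 = conv_param(3L, cin, cout),
            conv2 = conv_param(3L, cout, cout),
            proj = if (cin != cout) conv_param(1L, cin, cout) else NULL)
  if (use_norm) {
    p$norm1 <- list(gamma = rep(1, cout), beta = rep(0, cout))
    p$norm2 <- list(gamma = rep(1, cout), beta = rep(0, cout))
  }
  p
}

# per-channel normalisation over the spatial dims (batch-1 statistics)
chan_norm_forward <- function(x, np, eps = 1e-5) {
  n <- dim(x)[1] * dim(x)[2]
  xm <- matrix(x, n, dim(x)[3])
  mu <- colMeans(xm)
  va <- colMeans(sweep(xm, 2, mu)^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, np$gamma, `*`), 2, np$beta, `+`)
  list(y = array(y, dim = dim(x)),
       cache = list(xhat = xhat, istd = istd, dim = dim(x)))
}

chan_norm_backward <- function(dy, np, cache) {
  d <- cache$dim; n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, np$gamma, `*`)
  # dx = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat * xhat))
  t1 <- sweep(dxhat, 2, colSums(dxhat) / n)
  t2 <- sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / n, `*`)
  dx <- sweep(t1 - t2, 2, cache$istd, `*`)
  list(dx = array(dx, dim = d),
       grads = list(gamma = dgamma, beta = dbeta))
}

res_block_forward <- function(x, p) {
  c1 <- conv2d_forward(x, p$conv1)
  n1 <- if (!is.null(p$norm1)) chan_norm_forward(c1$y, p$norm1)
  else list(y = c1$y, cache = NULL)
  a1 <- relu(n1$y)
  c2 <- conv2d_forward(a1, p$conv2)
  n2 <- if (!is.null(p$norm2)) chan_norm_forward(c2$y, p$norm2)
  else list(y = c2$y, cache = NULL)
  a2 <- relu(n2$y)
  s <- if (is.null(p$proj)) list(y = x, col = NULL)
  else conv2d_forward(x, p$proj)
  list(y = a2 + s$y,
       cache = list(x_dim = dim(x), c1 = c1, n1 = n1, a1 = a1,
                    c2 = c2, n2 = n2, s = s))
}

res_block_backward <- function(dy, p, cache) {
  da2 <- dy * (cache$n2$y > 0)
  gn2 <- NULL
  if (!is.null(p$norm2)) {
    nb <- chan_norm_backward(da2, p$norm2, cache$n2$cache)
    da2 <- nb$dx; gn2 <- nb$grads
  }
  b2 <- conv2d_backward(da2, dim(cache$a1), p$conv2, cache$c2$col)
  da1 <- b2$dx * (cache$n1$y > 0)
  gn1 <- NULL
  if (!is.null(p$norm1)) {
    nb <- chan_norm_backward(da1, p$norm1, cache$n1$cache)
    da1 <- nb$dx; gn1 <- nb$grads
  }
  b1 <- conv2d_backward(da1, cache$x_dim, p$conv1, cache$c1$col)
  dx <- b1$dx
  gproj <- NULL
  if (is.null(p$proj)) {
    dx <- dx + dy
  } else {
    bp <- conv2d_backward(dy, cache$x_dim, p$proj, cache$s$col)
    dx <- dx + bp$dx
    gproj <- list(W = bp$dW, b = bp$db)
  }
  g <- list(conv1 = list(W = b1$dW, b = b1$db),
            conv2 = list(W = b2$dW, b = b2$db),
            proj = gproj)
  if (!is.null(gn1)) g$norm1 <- gn1
  if (!is.null(gn2)) g$norm2 <- gn2
  list(dx = dx, grads = g)
}

#' Initialise a Res-UNet model
#'
#' @param cfg a [seg_config()].
#' @param in_channels input channels (1 for enhanced fundus images).
#' @param seed RNG seed for the weight draw.
#' @return a `resunet_model` list with `params` and `cfg`.
#' @export
build_resunet <- function(cfg = seg_config(), in_channels = 1L, seed = 1L) {
  set.seed(seed)
  d <- cfg$depth
  ch <- cfg$base_channels * 2^(0:(d - 1))
  enc <- vector("list", d)
  cin <- in_channels
  for (l in seq_len(d)) {
    enc[[l]] <- res_block_param(cin, ch[l], cfg$use_batch_norm)
    cin <- ch[l]
  }
  cb <- ch[d] * 2L
  bott <- lapply(cfg$dilation_rates, function(r)
    conv_param(3L, ch[d], cb, r = r))
  dec <- vector("list", d)
  cur <- cb
  for (l in rev(seq_len(d))) {
    dec[[l]] <- list(up = upconv_param(cur, ch[l]),
                     block = res_block_param(ch[l], ch[l], cfg$use_batch_norm))
    cur <- ch[l]
  }
  head <- conv_param(1L, ch[1], 1L)
  structure(list(params = list(enc = enc, bott = bott, dec = dec,
                               head = head),
                 cfg = cfg, in_channels = as.integer(in_channels)),
            class = "resunet_model")
}

resunet_forward <- function(model, x, train = FALSE) {
  cfg <- model$cfg; p <- model$params
  d <- cfg$depth
  h <- dim(x)[1]; w <- dim(x)[2]
  if (h %% 2^d != 0 || w %% 2^d != 0)
    stop(sprintf("input dims must be divisible by 2^depth = %d", 2^d))
  skips <- vector("list", d); enc_cache <- vector("list", d)
  pool_cache <- vector("list", d)
  cur <- x
  for (l in seq_len(d)) {
    rb <- res_block_forward(cur, p$enc[[l]])
    skips[[l]] <- rb$y; enc_cache[[l]] <- rb$cache
    mp <- maxpool2_forward(rb$y)
    pool_cache[[l]] <- list(sel = mp$sel, x_dim = dim(rb$y))
    cur <- mp$y
  }
  bott_in <- cur
  bott_cache <- vector("list", length(p$bott))
  acc <- 0
  for (i in seq_along(p$bott)) {
    cf <- conv2d_forward(bott_in, p$bott[[i]])
    bott_cache[[i]] <- cf
    acc <- acc + cf$y
  }
  bott_pre <- acc
  cur <- relu(acc)
  drop_mask <- NULL
  if (train && cfg$dropout_rate > 0) {
    drop_mask <- array(runif(length(cur)) >= cfg$dropout_rate,
                       dim = dim(cur)) / (1 - cfg$dropout_rate)
    cur <- cur * drop_mask
  }
  dec_cache <- vector("list", d)
  for (l in rev(seq_len(d))) {
    up <- upconv2_forward(cur, p$dec[[l]]$up)
    merged <- up$y + skips[[l]]
    rb <- res_block_forward(merged, p$dec[[l]]$block)
    dec_cache[[l]] <- list(up_xf = up$xf, up_in_dim = dim(cur),
                           block = rb$cache)
    cur <- rb$y
  }
  features <- cur  # last decoder block output, pre-head
  hd <- conv2d_forward(cur, p$head)
  logits <- hd$y[, , 1]
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, logits = logits, features = features,
       cache = list(enc = enc_cache, pool = pool_cache,
                    bott_in_dim = dim(bott_in), bott = bott_cache,
                    bott_pre = bott_pre, drop_mask = drop_mask,
                    dec = dec_cache, head_col = hd$col,
                    feat_dim = dim(features)))
}

# dlogits: H x W matrix of dLoss/dlogit
resunet_backward <- function(model, dlogits, cache) {
  cfg <- model$cfg; p <- model$params
  d <- cfg$depth
  dl <- array(dlogits, dim = c(dim(dlogits), 1L))
  bh <- conv2d_backward(dl, cache$feat_dim, p$head, cache$head_col)
  grads <- list(enc = vector("list", d), bott = vector("list", length(p$bott)),
                dec = vector("list", d),
                head = list(W = bh$dW, b = bh$db))
  dcur <- bh$dx
  dskips <- vector("list", d)
  for (l in seq_len(d)) {
    bb <- res_block_backward(dcur, p$dec[[l]]$block, cache$dec[[l]]$block)
    dmerged <- bb$dx
    dskips[[l]] <- dmerged
    bu <- upconv2_backward(dmerged, p$dec[[l]]$up, cache$dec[[l]]$up_xf,
                           cache$dec[[l]]$up_in_dim)
    grads$dec[[l]] <- list(up = list(W = bu$dW, b = bu$db), block = bb$grads)
    dcur <- bu$dx
  }
  if (!is.null(cache$drop_mask)) dcur <- dcur * cache$drop_mask
  dacc <- dcur * (cache$bott_pre > 0)
  dbott_in <- 0
  for (i in seq_along(p$bott)) {
    bb <- conv2d_backward(dacc, cache$bott_in_dim, p$bott[[i]],
                          cache$bott[[i]]$col)
    grads$bott[[i]] <- list(W = bb$dW, b = bb$db)
    dbott_in <- dbott_in + bb$dx
  }
  dcur <- dbott_in
  for (l in rev(seq_len(d))) {
    dpool <- maxpool2_backward(dcur, cache$pool[[l]]$sel,
                               cache$pool[[l]]$x_dim)
    dpool <- dpool + dskips[[l]]
    be <- res_block_backward(dpool, p$enc[[l]], cache$enc[[l]])
    grads$enc[[l]] <- be$grads
    dcur <- be$dx
  }
  list(dx = dcur, grads = grads)
}

#' Binary cross-entropy loss
#'
#' `-(1/n) sum(q log p + (1 - q) log(1 - p))`, with `p` clipped to
#' `[eps, 1 - eps]`.
#'
#' @param p predicted probabilities.
#' @param q binary ground truth, same shape.
#' @param eps clipping epsilon.
#' @return non-negative scalar.
#' @export
bce_loss <- function(p, q, eps = 1e-7) {
  if (!identical(dim(p), dim(q)) || length(p) != length(q))
    stop("shape mismatch between prediction and truth")
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(q * log(pc) + (1 - q) * log(1 - pc))
}

extract_patch <- function(x, y, size) {
  h <- nrow(y); w <- ncol(y)
  if (h <= size && w <= size) return(list(x = x, y = y))
  r0 <- sample.int(h - size + 1L, 1L) - 1L
  c0 <- sample.int(w - size + 1L, 1L) - 1L
  list(x = x[r0 + seq_len(size), c0 + seq_len(size)],
       y = y[r0 + seq_len(size), c0 + seq_len(size)])
}

#' Train the Res-UNet segmenter
#'
#' Patch-based stochastic training minimising binary cross-entropy.
#' Deterministic for a fixed seed.
#'
#' @param samples list of `list(x = enhanced image matrix, y = 0/1 mask)`.
#' @param cfg a [seg_config()].
#' @param tcfg a [train_config()].
#' @param validation optional held-out list in the same format.
#' @return the trained `resunet_model`, with a `history` data.frame of
#'   per-epoch mean training (and optional validation) loss.
#' @export
train_segmenter <- function(samples, cfg = seg_config(),
                            tcfg = train_config(), validation = NULL) {
  if (!length(samples)) stop("no training samples")
  set.seed(tcfg$seed)
  model <- build_resunet(cfg, seed = tcfg$seed)
  state <- adam_init(model$params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (ep in seq_len(tcfg$epochs)) {
    losses <- c()
    for (si in sample(seq_along(samples))) {
      for (rep in seq_len(tcfg$patches_per_image)) {
        pt <- extract_patch(samples[[si]]$x, samples[[si]]$y, tcfg$patch_size)
        xin <- array(pt$x, dim = c(dim(pt$x), 1L))
        fw <- resunet_forward(model, xin, train = TRUE)
        losses <- c(losses, bce_loss(fw$prob, pt$y))
        dlogits <- (fw$prob - pt$y) / length(pt$y)
        bw <- resunet_backward(model, dlogits, fw$cache)
        if (tcfg$optimiser == "adam") {
          st <- adam_step(model$params, bw$grads, state,
                          lr = tcfg$learning_rate)
        } else {
          st <- sgd_step(model$params, bw$grads, state,
                         lr = tcfg$learning_rate)
        }
        model$params <- st$params; state <- st$state
      }
    }
    vl <- NA_real_
    if (!is.null(validation)) {
      vl <- mean(vapply(validation, function(s)
        bce_loss(predict_vessels(model, s$x)$prob, s$y), numeric(1)))
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = vl))
  }
  model$history <- hist
  model
}

#' Predict a vessel probability map
#'
#' Pads the input (reflection) to a multiple of `2^depth`, runs the
#' network, and crops back.
#'
#' @param model a trained `resunet_model`.
#' @param img enhanced single-channel image matrix.
#' @param return_features also return the pre-head decoder feature maps.
#' @return list with `prob` (H x W in (0,1)) and optionally `features`
#'   (H x W x C array).
#' @export
predict_vessels <- function(model, img, return_features = FALSE) {
  d <- model$cfg$depth
  h <- nrow(img); w <- ncol(img)
  mh <- ceiling(h / 2^d) * 2^d; mw <- ceiling(w / 2^d) * 2^d
  pad_idx <- function(n, m) {
    extra <- m - n
    if (extra == 0) seq_len(n) else c(seq_len(n), n - seq_len(extra) + 1L)
  }
  ri <- pad_idx(h, mh); ci <- pad_idx(w, mw)
  xin <- array(img[ri, ci], dim = c(mh, mw, 1L))
  fw <- resunet_forward(model, xin, train = FALSE)
  out <- list(prob = fw$prob[seq_len(h), seq_len(w)])
  if (return_features)
    out$features <- fw$features[seq_len(h), seq_len(w), , drop = FALSE]
  out
}

#' Binarise a probability map
#'
#' @param p probability matrix.
#' @param threshold in (0, 1); values `>= threshold` become vessel.
#' @return 0/1 integer matrix.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  (p >= threshold) * 1L
}

#' Save / load a model checkpoint
#'
#' Configuration and weights are bundled in one RDS container.
#'
#' @param model a `resunet_model` or `gcn_model`.
#' @param path checkpoint path.
#' @return `path` (save) or the model object (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
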