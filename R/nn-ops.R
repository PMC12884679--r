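# Minimal CNN building blocks on plain R arrays, with hand-written
# backward passes.  Feature maps are H x W x C arrays; convolutions are
# computed by im2col + one BLAS matrix product.
#
# Internal weight layout for k x k convolutions: a matrix of shape
# (Cin * k * k) x Cout whose rows are ordered channel-fastest within each
# kernel offset, offsets row-fastest.  `conv_weight_array()` converts to a
# (k, k, Cin, Cout) array for inspection and oracle tests.

#' Rectified linear unit
#'
#' `max(0, x)`, applied elementwise.
#'
#' @param x numeric scalar/vector/array.
#' @return same shape as `x`.
#' @export
relu <- function(x) pmax(x, 0)

#' Dilated convolution of a 1-D or 2-D signal
#'
#' Implements `y[i] = sum_k x[i + r (k - 1)] w[k]` along each spatial
#' dimension, with `r = 1` reducing to standard convolution.
#'
#' @param x numeric vector or matrix.
#' @param w kernel: vector for 1-D input, matrix for 2-D input.
#' @param r dilation rate (integer >= 1).
#' @param pad `"same"` (zero padding preserving length/shape) or
#'   `"valid"`.
#' @return convolved signal.
#' @export
dilated_conv <- function(x, w, r = 1L, pad = c("same", "valid")) {
  pad <- match.arg(pad)
  if (r < 1) stop("dilation rate r must be >= 1")
  if (is.matrix(x)) {
    if (!is.matrix(w)) stop("2-D input needs a matrix kernel")
    kh <- nrow(w); kw <- ncol(w)
    span_r <- r * (kh - 1L); span_c <- r * (kw - 1L)
    ph <- if (pad == "same") floor(span_r / 2) else 0L
    pw <- if (pad == "same") floor(span_c / 2) else 0L
    H <- nrow(x); W <- ncol(x)
    xp <- matrix(0, H + span_r, W + span_c)
    xp[ph + seq_len(H), pw + seq_len(W)] <- x
    oh <- if (pad == "same") H else H - span_r
    ow <- if (pad == "same") W else W - span_c
    y <- matrix(0, oh, ow)
    for (i in seq_len(kh)) for (j in seq_len(kw))
      y <- y + w[i, j] *
        xp[(1 + r * (i - 1)):(oh + r * (i - 1)),
           (1 + r * (j - 1)):(ow + r * (j - 1)), drop = FALSE]
    y
  } else {
    K <- length(w)
    span <- r * (K - 1L)
    p <- if (pad == "same") floor(span / 2) else 0L
    xp <- c(rep(0, p), x, rep(0, span - p))
    n_out <- if (pad == "same") length(x) else length(x) - span
    if (n_out < 1) stop("signal shorter than the dilated kernel")
    y <- numeric(n_out)
    for (k in seq_len(K)) y <- y + w[k] * xp[(1 + r * (k - 1)):(n_out + r * (k - 1))]
    y
  }
}

# ---- conv2d ----------------------------------------------------------------

he_init <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))

conv_param <- function(k, cin, cout, r = 1L, init = c("he", "zero")) {
  init <- match.arg(init)
  n <- cin * k * k * cout
  w <- if (init == "he") he_init(n, cin * k * k) else rep(0, n)
  list(W = matrix(w, cin * k * k, cout), b = rep(0, cout),
       k = as.integer(k), r = as.integer(r), cin = as.integer(cin),
       cout = as.integer(cout))
}

#' View a conv parameter's weights as a (k, k, Cin, Cout) array
#' @param p a conv parameter list.
#' @return 4-D array indexed `[ki, kj, cin, cout]`.
#' @export
conv_weight_array <- function(p) {
  a <- array(p$W, dim = c(p$cin, p$k, p$k, p$cout))
  aperm(a, c(2, 3, 1, 4))
}

set_conv_weights <- function(p, arr4) {
  stopifnot(identical(dim(arr4), c(p$k, p$k, p$cin, p$cout)))
  p$W <- matrix(aperm(arr4, c(3, 1, 2, 4)), p$cin * p$k * p$k, p$cout)
  p
}

im2col <- function(x, k, r) {
  d <- dim(x)
  cpp_im2col(x, d[1], d[2], d[3], k, r)
}

# NOTE: im2col block order is (i fastest, then j), channels fastest within
# a block -- matching the (Cin, k, k, Cout) weight flattening where rows
# run cin fastest, then ki, then kj.
conv2d_forward <- function(x, p) {
  h <- dim(x)[1]; w <- dim(x)[2]
  col <- im2col(x, p$k, p$r)
  y <- col %*% p$W
  if (any(p$b != 0)) y <- y + rep(p$b, each = h * w)
  dim(y) <- c(h, w, p$cout)
  list(y = y, col = col)
}

conv2d_backward <- function(dy, x_dim, p, col) {
  h <- x_dim[1]; w <- x_dim[2]; cin <- x_dim[3]
  dyf <- dy
  dim(dyf) <- c(h * w, p$cout)
  dW <- crossprod(col, dyf)
  db <- colSums(dyf)
  dcol <- tcrossprod(dyf, p$W)   # (h*w) x (cin*k*k)
  dx <- cpp_col2im(dcol, h, w, cin, p$k, p$r)
  list(dx = dx, dW = dW, db = db)
}

# ---- 2x2 max pooling --------------------------------------------------------

maxpool2_forward <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  stopifnot(h %% 2 == 0, w %% 2 == 0)
  q <- list(x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE],
            x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE],
            x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE],
            x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE])
  y <- pmax(q[[1]], q[[2]], q[[3]], q[[4]])
  sel <- vector("list", 4)
  taken <- array(FALSE, dim = dim(y))
  for (i in 1:4) {
    sel[[i]] <- (q[[i]] == y) & !taken
    taken <- taken | sel[[i]]
  }
  list(y = y, sel = sel)
}

maxpool2_backward <- function(dy, sel, x_dim) {
  h <- x_dim[1]; w <- x_dim[2]
  dx <- array(0, dim = x_dim)
  rs <- list(seq(1, h, 2), seq(2, h, 2), seq(1, h, 2), seq(2, h, 2))
  cs <- list(seq(1, w, 2), seq(1, w, 2), seq(2, w, 2), seq(2, w, 2))
  for (i in 1:4) {
    blk <- array(0, dim = dim(dy))
    blk[sel[[i]]] <- dy[sel[[i]]]
    dx[rs[[i]], cs[[i]], ] <- blk
  }
  dx
}

# ---- 2x2 stride-2 transposed convolution ------------------------------------

upconv_param <- function(cin, cout) {
  W <- lapply(1:4, function(i)
    matrix(he_init(cin * cout, cin), cin, cout))
  list(W = W, b = rep(0, cout), cin = as.integer(cin),
       cout = as.integer(cout))
}

upconv2_forward <- function(x, p) {
  h <- dim(x)[1]; w <- dim(x)[2]
  xf <- matrix(x, h * w, p$cin)
  y <- array(0, dim = c(2 * h, 2 * w, p$cout))
  rs <- list(seq(1, 2 * h, 2), seq(2, 2 * h, 2), seq(1, 2 * h, 2), seq(2, 2 * h, 2))
  cs <- list(seq(1, 2 * w, 2), seq(1, 2 * w, 2), seq(2, 2 * w, 2), seq(2, 2 * w, 2))
  for (i in 1:4) {
    q <- xf %*% p$W[[i]]
    dim(q) <- c(h, w, p$cout)
    y[rs[[i]], cs[[i]], ] <- q
  }
  if (any(p$b != 0)) y <- y + rep(p$b, each = 4 * h * w)
  list(y = y, xf = xf)
}

upconv2_backward <- function(dy, p, xf, x_dim) {
  h <- x_dim[1]; w <- x_dim[2]
  rs <- list(seq(1, 2 * h, 2), seq(2, 2 * h, 2), seq(1, 2 * h, 2), seq(2, 2 * h, 2))
  cs <- list(seq(1, 2 * w, 2), seq(1, 2 * w, 2), seq(2, 2 * w, 2), seq(2, 2 * w, 2))
  dW <- vector("list", 4)
  dxf <- matrix(0, h * w, p$cin)
  db <- rep(0, p$cout)
  for (i in 1:4) {
    dq <- dy[rs[[i]], cs[[i]], , drop = FALSE]
    dim(dq) <- c(h * w, p$cout)
    dW[[i]] <- crossprod(xf, dq)
    dxf <- dxf + tcrossprod(dq, p$W[[i]])
    db <- db + colSums(dq)
  }
  list(dx = array(dxf, dim = x_dim), dW = dW, db = db)
}

# ---- Adam optimiser over nested parameter lists -----------------------------

# The optimiser walks the *gradient* tree (whose leaves are exactly the
# trainable tensors) and updates the matching entries of the parameter
# tree, leaving metadata fields (kernel size, channel counts, ...) alone.
# Named list levels are matched by name, unnamed levels by position.

grad_keys <- function(g) {
  nms <- names(g)
  if (is.null(nms) || any(nms == "")) seq_along(g) else nms
}

adam_init <- function(params) list(m = list(), v = list(), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(g)) {
      if (is.null(m)) m <- list()
      if (is.null(v)) v <- list()
      safe_get <- function(l, k) {
        if (is.character(k)) l[[k]]
        else if (k <= length(l)) l[[k]] else NULL
      }
      for (k in grad_keys(g)) {
        r <- upd(p[[k]], g[[k]], safe_get(m, k), safe_get(v, k))
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# plain SGD alternative
sgd_step <- function(params, grads, state, lr = 1e-2) {
  upd <- function(p, g) {
    if (is.null(g)) return(p)
    if (is.list(g)) {
      for (k in grad_keys(g)) p[[k]] <- upd(p[[k]], g[[k]])
      return(p)
    }
    p - lr * g
  }
  list(params = upd(params, grads), state = state)
}
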