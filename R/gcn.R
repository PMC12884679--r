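# Graph convolutional artery/vein classifier.
#
# Layer rule: H_{l+1} = sigma(W_hat H_l Theta_l) with W_hat the
# symmetrically normalised self-looped adjacency; ReLU on hidden layers,
# linear final layer, per-node softmax head.  Trained with an equally
# weighted sum of Dice loss and masked binary cross-entropy.

#' GCN configuration
#'
#' @param n_layers number of graph-convolution layers (>= 1), default 2.
#' @param hidden_dim hidden width, default 64.
#' @param n_classes 2 (artery/vein) or 3 (with an explicit undefined
#'   class).
#' @param dropout_rate dropout on hidden activations during training.
#' @param seed RNG seed.
#' @param loss_weights `c(w_dice, w_ce)`, non-negative, not both zero.
#' @param learning_rate,epochs training schedule.
#' @return `gcn_config` list.
#' @export
gcn_config <- function(n_layers = 2L, hidden_dim = 64L, n_classes = 2L,
                       dropout_rate = 0, seed = 1L,
                       loss_weights = c(1, 1), learning_rate = 1e-2,
                       epochs = 150L) {
  if (n_layers < 1 || hidden_dim < 1) stop("n_layers and hidden_dim >= 1")
  if (any(loss_weights < 0) || sum(loss_weights) == 0)
    stop("loss weights must be non-negative and not both zero")
  list(n_layers = as.integer(n_layers), hidden_dim = as.integer(hidden_dim),
       n_classes = as.integer(n_classes), dropout_rate = dropout_rate,
       seed = as.integer(seed), loss_weights = loss_weights,
       learning_rate = learning_rate, epochs = as.integer(epochs))
}

#' One graph-convolution layer
#'
#' `sigma(W_hat %*% H %*% Theta)`.
#'
#' @param H n x d node feature matrix.
#' @param W_hat normalised adjacency (from [normalize_adjacency()]).
#' @param theta d x d' weight matrix.
#' @param bias optional length-d' bias added after propagation.
#' @param activation `"relu"` or `"identity"`.
#' @return n x d' matrix.
#' @export
gcn_layer <- function(H, W_hat, theta, bias = NULL,
                      activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(H) != nrow(theta)) stop("feature/weight dimension mismatch")
  Z <- as.matrix(W_hat %*% (H %*% theta))
  if (!is.null(bias)) Z <- Z + rep(bias, each = nrow(Z))
  if (activation == "relu") relu(Z) else Z
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

gcn_init_params <- function(m, cfg) {
  set.seed(cfg$seed)
  dims <- c(m, rep(cfg$hidden_dim, cfg$n_layers - 1L), cfg$n_classes)
  lapply(seq_len(cfg$n_layers), function(l)
    list(W = matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                    dims[l], dims[l + 1]),
         b = rep(0, dims[l + 1])))
}

#' Forward pass of the GCN
#'
#' Hidden layers use ReLU; the final layer is linear and followed by a
#' per-node softmax.
#'
#' @param g a `pixel_graph` with features.
#' @param params list of layer weight matrices.
#' @param W_hat optional precomputed normalised adjacency.
#' @return `node_prediction` list: `scores` (n x n_classes, rows sum
#'   to 1), `labels` (argmax class per node, 1 = artery, 2 = vein; ties go
#'   to the lower index), `hidden` (list of layer activations).
#' @export
gcn_forward <- function(g, params, W_hat = NULL) {
  if (is.null(g$features)) stop("graph has no node features")
  if (is.null(W_hat)) W_hat <- normalize_adjacency(g)
  H <- g$features
  hidden <- list(H)
  L <- length(params)
  for (l in seq_len(L)) {
    act <- if (l < L) "relu" else "identity"
    H <- gcn_layer(H, W_hat, params[[l]]$W, params[[l]]$b, act)
    hidden[[l + 1]] <- H
  }
  scores <- row_softmax(H)
  labels <- max.col(scores, ties.method = "first")
  structure(list(scores = scores, labels = labels, hidden = hidden),
            class = "node_prediction")
}

#' Dice loss
#'
#' `1 - (2 sum(g ghat) + eps) / (sum(g^2) + sum(ghat^2) + eps)` by
#' default (`eps_placement = "symmetric"`); `"printed"` adds eps to the
#' numerator only.
#'
#' @param g_true 0/1 vector (ground truth indicator).
#' @param g_hat predicted probabilities, same length.
#' @param eps stabiliser.
#' @param eps_placement `"symmetric"` or `"printed"`.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(g_true, g_hat, eps = 1e-6,
                      eps_placement = c("symmetric", "printed")) {
  eps_placement <- match.arg(eps_placement)
  if (length(g_true) != length(g_hat)) stop("shape mismatch")
  if (eps <= 0) stop("eps must be positive")
  num <- 2 * sum(g_true * g_hat) + eps
  den <- sum(g_true^2) + sum(g_hat^2) +
    if (eps_placement == "symmetric") eps else 0
  1 - num / den
}

#' Binary cross-entropy over supervised nodes
#'
#' @param b_true 0/1 vector; `NA` entries (undefined nodes) are masked
#'   out.
#' @param b_hat predicted probabilities.
#' @param eps clipping epsilon.
#' @return non-negative scalar.
#' @export
ce_loss <- function(b_true, b_hat, eps = 1e-7) {
  if (length(b_true) != length(b_hat)) stop("shape mismatch")
  keep <- !is.na(b_true)
  if (!any(keep)) stop("no supervised nodes (all masked)")
  bce_loss(b_hat[keep], b_true[keep], eps)
}

# combined loss and its gradient w.r.t. the final-layer logits.
# y: n x C one-hot (rows of NA for masked nodes); S: softmax scores.
# With C = 2 the Dice term is the binary Dice on the artery probability;
# with C > 2 it is averaged one-vs-rest over classes.
gcn_loss_grad <- function(S, y, w_dice, w_ce, eps = 1e-6) {
  sup <- !is.na(y[, 1])
  n_sup <- sum(sup)
  if (n_sup == 0) stop("no supervised nodes (all masked)")
  C <- ncol(S)
  Ssup <- S[sup, , drop = FALSE]
  Ysup <- y[sup, , drop = FALSE]
  # categorical cross-entropy (== Eq.-style binary CE when C = 2)
  pc <- pmin(pmax(Ssup, 1e-7), 1 - 1e-7)
  lc <- -mean(rowSums(Ysup * log(pc)))
  dZ_ce <- matrix(0, nrow(S), C)
  dZ_ce[sup, ] <- (Ssup - Ysup) / n_sup
  # Dice on class-1 probability (C = 2) or one-vs-rest average (C > 2)
  dice_classes <- if (C == 2) 1L else seq_len(C)
  ld <- 0
  dP <- matrix(0, n_sup, C)   # dDice/ds over supervised nodes
  for (cidx in dice_classes) {
    t <- Ysup[, cidx]; p <- Ssup[, cidx]
    den <- sum(t^2) + sum(p^2) + eps
    num <- 2 * sum(t * p) + eps
    ld <- ld + (1 - num / den)
    dP[, cidx] <- dP[, cidx] - (2 * t * den - num * 2 * p) / den^2
  }
  ld <- ld / length(dice_classes)
  dP <- dP / length(dice_classes)
  # softmax Jacobian: dZ = S * (dP - rowSums(dP * S))
  dZ_dice <- matrix(0, nrow(S), C)
  dZ_dice[sup, ] <- Ssup * (dP - rowSums(dP * Ssup))
  list(loss = w_dice * ld + w_ce * lc, dice = ld, ce = lc,
       dZ = w_dice * dZ_dice + w_ce * dZ_ce)
}

#' Train the artery/vein GCN
#'
#' Full-batch Adam on `w_dice * Dice + w_ce * CE` over the supervised
#' (artery/vein) nodes of all training graphs; undefined nodes are masked
#' out.  Deterministic for a fixed seed.
#'
#' @param graphs list of `pixel_graph`s with features.
#' @param labels list of per-node integer vectors
#'   (1 = artery, 2 = vein, `NA` = undefined / unsupervised).
#' @param cfg a [gcn_config()].
#' @return a `gcn_model` list with `params`, `cfg` and a per-epoch loss
#'   `history`.
#' @export
train_gcn <- function(graphs, labels, cfg = gcn_config()) {
  if (!length(graphs)) stop("no training graphs")
  stopifnot(length(graphs) == length(labels))
  m <- ncol(graphs[[1]]$features)
  params <- gcn_init_params(m, cfg)
  W_hats <- lapply(graphs, normalize_adjacency)
  onehots <- lapply(labels, function(lb) {
    y <- matrix(NA_real_, length(lb), cfg$n_classes)
    ok <- !is.na(lb)
    y[ok, ] <- 0
    y[cbind(which(ok), lb[ok])] <- 1
    y
  })
  state <- adam_init(params)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     dice = numeric(), ce = numeric())
  for (ep in seq_len(cfg$epochs)) {
    tot <- 0; totd <- 0; totc <- 0
    grads <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
    for (gi in seq_along(graphs)) {
      g <- graphs[[gi]]; W_hat <- W_hats[[gi]]
      fw <- gcn_forward(g, params, W_hat)
      lg <- gcn_loss_grad(fw$scores, onehots[[gi]],
                          cfg$loss_weights[1], cfg$loss_weights[2])
      tot <- tot + lg$loss; totd <- totd + lg$dice; totc <- totc + lg$ce
      # backprop through the layers
      dH <- lg$dZ
      L <- length(params)
      for (l in rev(seq_len(L))) {
        Hin <- fw$hidden[[l]]
        if (l < L) dH <- dH * (fw$hidden[[l + 1]] > 0)
        grads[[l]]$b <- grads[[l]]$b + colSums(dH)
        WH <- as.matrix(Matrix::crossprod(W_hat, dH))  # W_hat symmetric
        grads[[l]]$W <- grads[[l]]$W + crossprod(Hin, WH)
        dH <- WH %*% t(params[[l]]$W)
      }
    }
    st <- adam_step(params, grads, state, lr = cfg$learning_rate)
    params <- st$params; state <- st$state
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot / length(graphs),
                                   dice = totd / length(graphs),
                                   ce = totc / length(graphs)))
  }
  structure(list(params = params, cfg = cfg, history = hist),
            class = "gcn_model")
}

#' Classify the nodes of a graph with a trained GCN
#'
#' @param model a `gcn_model`.
#' @param g a `pixel_graph` with features.
#' @return a `node_prediction`.
#' @export
predict_av <- function(model, g) gcn_forward(g, model$params)

#' Paint node predictions back into an A/V label image
#'
#' @param pred a `node_prediction`.
#' @param g the `pixel_graph` the prediction came from.
#' @param shape `c(H, W)` of the output map (defaults to the graph's).
#' @return integer label matrix (0 background, 1 artery, 2 vein).
#' @export
labels_to_image <- function(pred, g, shape = g$shape) {
  r <- g$nodes$row + 1L; c <- g$nodes$col + 1L
  if (any(r > shape[1]) || any(c > shape[2]))
    stop("node coordinates fall outside the requested shape")
  out <- matrix(AV_BACKGROUND, shape[1], shape[2])
  out[cbind(r, c)] <- ifelse(pred$labels == 1L, AV_ARTERY, AV_VEIN)
  out
}
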