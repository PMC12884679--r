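# Independent oracles used across the suite.  These deliberately take the
# dumbest correct path (double loops, direct formula evaluation) and stay
# separate from the package implementations they check.

# exhaustive 8-neighbour edge oracle: every pair of vessel pixels
oracle_edge_set <- function(mask) {
  nodes <- which(mask != 0, arr.ind = TRUE)
  nodes <- nodes[order(nodes[, 1], nodes[, 2]), , drop = FALSE]
  n <- nrow(nodes)
  edges <- character(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (abs(nodes[i, 1] - nodes[j, 1]) <= 1 &&
          abs(nodes[i, 2] - nodes[j, 2]) <= 1)
        edges <- c(edges, paste(i, j))
    }
  }
  edges
}

# vectorised variant for larger masks (still an independent code path)
oracle_edge_set_fast <- function(mask) {
  nodes <- which(mask != 0, arr.ind = TRUE)
  nodes <- nodes[order(nodes[, 1], nodes[, 2]), , drop = FALSE]
  n <- nrow(nodes)
  if (n < 2) return(character(0))
  dr <- abs(outer(nodes[, 1], nodes[, 1], `-`)) <= 1
  dc <- abs(outer(nodes[, 2], nodes[, 2], `-`)) <= 1
  adj <- dr & dc
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  paste(idx[, 1], idx[, 2])
}

# package edge set as "i j" strings (self-loops removed), node order is
# row-major like the oracle's
pkg_edge_set <- function(g) {
  tri <- Matrix::which(g$adjacency != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  paste(tri[, 1], tri[, 2])
}

# brute-force 1-D dilated convolution (valid region)
oracle_dilated_1d <- function(x, w, r) {
  K <- length(w)
  n_out <- length(x) - r * (K - 1)
  vapply(seq_len(n_out), function(i)
    sum(vapply(seq_len(K), function(k) x[i + r * (k - 1)] * w[k],
               numeric(1))), numeric(1))
}

# brute-force 2-D convolution with same zero padding (r = 1 oracle)
oracle_conv2d_same <- function(x, w4) {
  k <- dim(w4)[1]; cin <- dim(w4)[3]; cout <- dim(w4)[4]
  h <- dim(x)[1]; wd <- dim(x)[2]
  p <- (k - 1) %/% 2
  y <- array(0, dim = c(h, wd, cout))
  for (co in seq_len(cout)) for (a in seq_len(h)) for (b in seq_len(wd)) {
    acc <- 0
    for (ci in seq_len(cin)) for (i in seq_len(k)) for (j in seq_len(k)) {
      sa <- a + i - 1 - p; sb <- b + j - 1 - p
      if (sa >= 1 && sa <= h && sb >= 1 && sb <= wd)
        acc <- acc + x[sa, sb, ci] * w4[i, j, ci, co]
    }
    y[a, b, co] <- acc
  }
  y
}

# rank-sum (probability of correct ordering) AUC oracle
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

dice_coef <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))

# straight-vessel mask through the image centre at a given angle/width
straight_vessel_mask <- function(size, width, angle_deg) {
  th <- angle_deg * pi / 180
  c0 <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  # distance from pixel to the line through centre with direction theta
  d <- abs(-sin(th) * (cc - c0) + cos(th) * (rr - c0))
  (d <= width / 2) * 1L
}
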