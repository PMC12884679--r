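# Pixel graph over a binary vessel mask: one node per vessel pixel,
# edges between 8-adjacent vessel pixels, self-loops on every node,
# symmetric degree normalisation W = D^(-1/2) A D^(-1/2).
#
# Node indices follow row-major scan order of the 0-based (row, col)
# coordinates; background pixels are not materialised (they are isolated,
# inert under propagation) unless `full_nodes = TRUE`.

#' Build the 8-connected pixel graph of a vessel mask
#'
#' @param mask 0/1 matrix.
#' @param full_nodes also materialise background pixels as isolated
#'   self-looped nodes (strict whole-image view).
#' @return a `pixel_graph` list: `nodes` (data.frame `row`, `col`,
#'   0-based), `adjacency` (sparse symmetric 0/1 Matrix with unit
#'   diagonal), `degree` (row sums), `n_nodes`, `shape`, `features`
#'   (NULL until [extract_node_features()]).
#' @export
build_graph <- function(mask, full_nodes = FALSE) {
  h <- nrow(mask); w <- ncol(mask)
  sel <- if (full_nodes) rep(TRUE, h * w) else as.vector(mask != 0)
  # row-major scan order: sort by (row, col)
  coord <- which(matrix(sel, h, w), arr.ind = TRUE)
  ord <- order(coord[, 1], coord[, 2])
  coord <- coord[ord, , drop = FALSE]
  n <- nrow(coord)
  if (n == 0) {
    return(structure(list(nodes = data.frame(row = integer(),
                                             col = integer()),
                          adjacency = Matrix::sparseMatrix(
                            i = integer(), j = integer(), dims = c(0, 0)),
                          degree = numeric(0), n_nodes = 0L,
                          shape = c(h, w), features = NULL),
                     class = "pixel_graph"))
  }
  # node id lookup by linear pixel index
  id_of <- rep(NA_integer_, h * w)
  lin <- coord[, 1] + (coord[, 2] - 1L) * h
  id_of[lin] <- seq_len(n)
  vessel <- mask != 0
  ii <- integer(0); jj <- integer(0)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  vr <- coord[, 1]; vc <- coord[, 2]
  is_vessel_node <- vessel[cbind(vr, vc)]
  for (k in seq_len(nrow(offs))) {
    nr <- vr + offs[k, 1]; nc <- vc + offs[k, 2]
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w & is_vessel_node
    ok[ok] <- vessel[cbind(nr[ok], nc[ok])]
    src <- which(ok)
    dst <- id_of[nr[ok] + (nc[ok] - 1L) * h]
    ii <- c(ii, src); jj <- c(jj, dst)
  }
  # self-loops on every node
  ii <- c(ii, seq_len(n)); jj <- c(jj, seq_len(n))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A@x[] <- 1  # deduplicate to 0/1
  deg <- Matrix::rowSums(A)
  structure(list(nodes = data.frame(row = coord[, 1] - 1L,
                                    col = coord[, 2] - 1L),
                 adjacency = A, degree = deg, n_nodes = n,
                 shape = c(h, w), features = NULL),
            class = "pixel_graph")
}

#' Symmetric degree normalisation of the adjacency
#'
#' `W_ij = a_ij / sqrt(d_i d_j)`, i.e. `D^(-1/2) A D^(-1/2)`.
#'
#' @param g a `pixel_graph`.
#' @return sparse symmetric Matrix with entries in `[0, 1]`.
#' @export
normalize_adjacency <- function(g) {
  if (g$n_nodes == 0) return(g$adjacency)
  stopifnot(all(g$degree >= 1))  # guaranteed by self-loops
  dinv <- 1 / sqrt(g$degree)
  Dm <- Matrix::Diagonal(x = dinv)
  Dm %*% g$adjacency %*% Dm
}

#' Attach per-node features sampled from feature maps
#'
#' Node i's feature vector is the channel profile of the feature maps at
#' its pixel.
#'
#' @param g a `pixel_graph`.
#' @param feature_maps H x W x C array (or H x W matrix for C = 1) whose
#'   spatial dims equal the mask's.
#' @return the graph with an `n x C` `features` matrix.
#' @export
extract_node_features <- function(g, feature_maps) {
  if (is.matrix(feature_maps))
    feature_maps <- array(feature_maps, dim = c(dim(feature_maps), 1L))
  if (!identical(dim(feature_maps)[1:2], as.integer(g$shape)))
    stop("feature map spatial dims must match the mask")
  ch <- dim(feature_maps)[3]
  f <- matrix(0, g$n_nodes, ch)
  r <- g$nodes$row + 1L; c <- g$nodes$col + 1L
  for (k in seq_len(ch)) f[, k] <- feature_maps[, , k][cbind(r, c)]
  g$features <- f
  g
}

#' Export / import a pixel graph as plain text
#'
#' Writes `<stem>_edges.tsv` (pairs of node ids, self-loops included) and
#' `<stem>_nodes.csv` (id, row, col, feature columns).
#'
#' @param g a `pixel_graph`.
#' @param stem output path stem.
#' @return `stem` (write) or a `pixel_graph` (read).
#' @export
write_graph <- function(g, stem) {
  tri <- Matrix::which(g$adjacency != 0, arr.ind = TRUE)
  utils::write.table(tri[tri[, 1] <= tri[, 2], , drop = FALSE],
                     paste0(stem, "_edges.tsv"),
                     row.names = FALSE, col.names = c("i", "j"), sep = "\t")
  nd <- cbind(id = seq_len(g$n_nodes), g$nodes)
  if (!is.null(g$features)) {
    ft <- as.data.frame(g$features)
    names(ft) <- paste0("feature_", seq_len(ncol(ft)) - 1L)
    nd <- cbind(nd, ft)
  }
  write.csv(nd, paste0(stem, "_nodes.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_graph
#' @export
read_graph <- function(stem) {
  ed <- utils::read.table(paste0(stem, "_edges.tsv"), header = TRUE)
  nd <- read.csv(paste0(stem, "_nodes.csv"))
  n <- nrow(nd)
  A <- Matrix::sparseMatrix(i = c(ed$i, ed$j), j = c(ed$j, ed$i), x = 1,
                            dims = c(n, n))
  A@x[] <- 1
  fcols <- grep("^feature_", names(nd))
  structure(list(nodes = nd[, c("row", "col")],
                 adjacency = A, degree = Matrix::rowSums(A),
                 n_nodes = n, shape = c(max(nd$row) + 1L, max(nd$col) + 1L),
                 features = if (length(fcols))
                   as.matrix(nd[, fcols, drop = FALSE]) else NULL),
            class = "pixel_graph")
}
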