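# Fundus preprocessing: green-channel extraction, global histogram
# equalisation, CLAHE, mild Gaussian denoising, and joint geometric
# augmentation of (image, mask, label) triples.
#
# Enhanced images are plain numeric matrices in [0, 1] carrying a
# "provenance" attribute listing the transforms applied, in order.

add_provenance <- function(out, src, step) {
  attr(out, "provenance") <- c(attr(src, "provenance"), step)
  out
}

#' Construct a fundus image object
#'
#' @param pixels H x W x 3 numeric array, values in `[0, 1]` (or integers in
#'   `[0, maxval]`, which are rescaled).
#' @param fov_mask optional H x W binary field-of-view mask.
#' @param pixel_spacing physical pixel size in micrometres per pixel
#'   (used when converting vessel widths to calibres); `NA` if unknown.
#' @return an object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, fov_mask = NULL, pixel_spacing = NA_real_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("fundus image must be an H x W x 3 array")
  if (max(pixels) > 1) pixels <- pixels / max(pixels)
  if (!is.null(fov_mask) &&
      !identical(dim(fov_mask), dim(pixels)[1:2]))
    stop("fov_mask dimensions must match the image")
  structure(list(pixels = pixels, fov_mask = fov_mask,
                 colourspace = "RGB", pixel_spacing = pixel_spacing),
            class = "fundus_image")
}

#' Extract the (normalised) green channel
#'
#' The default mode divides the green component by the channel sum,
#' `Gch = G / (R + G + B)`, with 0 returned where the sum is 0.  Mode
#' `"raw"` returns the plain green channel.
#'
#' @param img a `fundus_image` or H x W x 3 array.
#' @param mode `"normalised"` (default) or `"raw"`.
#' @return numeric matrix in `[0, 1]` with provenance attribute.
#' @export
extract_green_normalized <- function(img, mode = c("normalised", "raw")) {
  mode <- match.arg(mode)
  px <- if (inherits(img, "fundus_image")) img$pixels else img
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("expected a 3-channel image")
  g <- px[, , 2]
  if (mode == "normalised") {
    s <- px[, , 1] + px[, , 2] + px[, , 3]
    out <- ifelse(s == 0, 0, g / s)
  } else out <- g
  out <- matrix(pmin(pmax(out, 0), 1), nrow(g), ncol(g))
  add_provenance(out, NULL, paste0("green:", mode))
}

#' Global histogram equalisation
#'
#' Maps each grey level through the cumulative histogram:
#' `Gf(g) = (Gmax / N0) * sum_{i <= g} P_i`, where `P_i` is the pixel count
#' at level `i`, `N0` the total pixel count and `Gmax = L - 1`.  Output is
#' rescaled back to `[0, 1]` unless `rescale = FALSE`, in which case values
#' are on the `[0, Gmax]` grey-level scale.
#'
#' @param img single-channel numeric matrix in `[0, 1]`.
#' @param levels number of grey levels L (>= 2), default 256.
#' @param rescale divide the mapped levels by Gmax (default TRUE).
#' @return numeric matrix, same shape.
#' @export
histogram_equalize <- function(img, levels = 256L, rescale = TRUE) {
  if (!is.matrix(img)) stop("expected a single-channel image matrix")
  if (levels < 2) stop("levels must be >= 2")
  gmax <- levels - 1L
  q <- pmin(pmax(as.integer(round(img * gmax)), 0L), gmax)
  counts <- tabulate(q + 1L, nbins = levels)
  lut <- pmin((gmax / length(q)) * cumsum(counts), gmax)
  out <- matrix(lut[q + 1L], nrow(img), ncol(img))
  if (rescale) out <- out / gmax
  add_provenance(out, img, sprintf("he:L=%d", levels))
}

# clip a tile histogram at `limit` counts per bin and redistribute the
# excess uniformly (single redistribution pass, remainder spread evenly --
# the classical scheme)
clip_histogram <- function(counts, limit) {
  if (!is.finite(limit)) return(counts)
  excess <- sum(pmax(counts - limit, 0))
  counts <- pmin(counts, limit)
  counts + excess / length(counts)
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Tiled histogram equalisation with per-tile histograms clipped at
#' `clip_limit` times the mean bin count; pixel mappings are bilinearly
#' blended between the four nearest tile mappings.
#'
#' @param img single-channel numeric matrix in `[0, 1]`.
#' @param clip_limit clip factor (multiple of the uniform bin count);
#'   `Inf` disables clipping.  Default 2.
#' @param tile_grid integer vector `c(rows, cols)` of tiles, default 8 x 8.
#' @param levels grey levels used for the histograms, default 256.
#' @return numeric matrix in `[0, 1]`, same shape.
#' @export
clahe <- function(img, clip_limit = 2, tile_grid = c(8L, 8L), levels = 256L) {
  if (!is.matrix(img)) stop("expected a single-channel image matrix")
  if (clip_limit <= 0) stop("clip_limit must be positive")
  tile_grid <- as.integer(tile_grid)
  if (any(tile_grid < 1)) stop("tile_grid entries must be >= 1")
  h <- nrow(img); w <- ncol(img)
  ty <- tile_grid[1]; tx <- tile_grid[2]
  if (h < ty || w < tx) stop("image smaller than the tile grid")
  gmax <- levels - 1L
  q <- matrix(pmin(pmax(as.integer(round(img * gmax)), 0L), gmax), h, w)

  # tile extents (as equal as possible)
  row_brk <- round(seq(0, h, length.out = ty + 1))
  col_brk <- round(seq(0, w, length.out = tx + 1))
  luts <- array(0, dim = c(ty, tx, levels))
  for (i in seq_len(ty)) for (j in seq_len(tx)) {
    tq <- q[(row_brk[i] + 1):row_brk[i + 1], (col_brk[j] + 1):col_brk[j + 1]]
    counts <- tabulate(tq + 1L, nbins = levels)
    limit <- clip_limit * length(tq) / levels
    counts <- clip_histogram(counts, limit)
    luts[i, j, ] <- gmax / length(tq) * cumsum(counts)
  }

  # tile centres in pixel coordinates (1-based)
  rcent <- (row_brk[-1] + row_brk[-(ty + 1)] + 1) / 2
  ccent <- (col_brk[-1] + col_brk[-(tx + 1)] + 1) / 2

  interp_idx <- function(coord, cent) {
    # returns lower tile index (1-based) and weight of the *upper* tile
    if (length(cent) == 1L) return(list(lo = rep(1L, length(coord)),
                                        wt = rep(0, length(coord))))
    lo <- findInterval(coord, cent)
    lo <- pmin(pmax(lo, 1L), length(cent) - 1L)
    wt <- (coord - cent[lo]) / (cent[lo + 1L] - cent[lo])
    list(lo = lo, wt = pmin(pmax(wt, 0), 1))
  }
  ri <- interp_idx(seq_len(h), rcent)
  ci <- interp_idx(seq_len(w), ccent)

  RI <- matrix(ri$lo, h, w); RW <- matrix(ri$wt, h, w)
  CI <- matrix(ci$lo, h, w, byrow = TRUE); CW <- matrix(ci$wt, h, w, byrow = TRUE)
  lut_at <- function(ti, tj) {
    # fetch luts[ti, tj, q+1] elementwise
    idx <- ti + (tj - 1L) * ty + (q) * (ty * tx)
    matrix(luts[idx + 0L], h, w)  # linear indexing into 3-d array
  }
  out <- (1 - RW) * ((1 - CW) * lut_at(RI, CI) + CW * lut_at(RI, CI + (tx > 1))) +
    RW * ((1 - CW) * lut_at(RI + (ty > 1), CI) +
            CW * lut_at(RI + (ty > 1), CI + (tx > 1)))
  out <- out / gmax
  add_provenance(matrix(out, h, w), img,
                 sprintf("clahe:clip=%g,tiles=%dx%d", clip_limit, ty, tx))
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with reflected borders (preserves constants)
convolve_sep <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  reflect <- function(n, r) c(rev(seq_len(r) + 1L), seq_len(n),
                              n - seq_len(r))
  h <- nrow(img); w <- ncol(img)
  pad <- img[reflect(h, r), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + h - 1L), , drop = FALSE]
  pad <- out[, reflect(w, r), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * pad[, i:(i + w - 1L), drop = FALSE]
  out
}

#' Gaussian denoising
#'
#' @param img single-channel numeric matrix.
#' @param sigma Gaussian scale in pixels; 0 is the identity.
#' @return smoothed matrix, same shape.
#' @export
denoise <- function(img, sigma = 0.8) {
  if (!is.matrix(img)) stop("expected a single-channel image matrix")
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(add_provenance(img, img, "denoise:0"))
  out <- convolve_sep(img, gaussian_kernel(sigma))
  add_provenance(out, img, sprintf("denoise:%g", sigma))
}

#' Standard enhancement chain: green channel, CLAHE, denoise
#'
#' @param img `fundus_image` or H x W x 3 array.
#' @param green_mode `"normalised"` or `"raw"` (Eq.-style channel ratio vs
#'   plain green).
#' @param clip_limit,tile_grid CLAHE parameters.
#' @param sigma denoising scale.
#' @return enhanced single-channel matrix in `[0, 1]`.
#' @export
enhance_fundus <- function(img, green_mode = "normalised", clip_limit = 2,
                           tile_grid = c(8L, 8L), sigma = 0.8) {
  g <- extract_green_normalized(img, green_mode)
  g <- clahe(g, clip_limit, tile_grid)
  denoise(g, sigma)
}

# ---- joint augmentation ----------------------------------------------------

rot90k <- function(m, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[nrow(t(m)):1, , drop = FALSE]
  m
}

# generic inverse-mapping affine resampler about the image centre.
# theta in degrees (counter-clockwise), scale s, optional horizontal flip.
affine_resample <- function(img, theta = 0, scale = 1, flip = FALSE,
                            interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- theta * pi / 180
  # output (r, c) pulls from input coords via the inverse map
  rc <- expand.grid(r = seq_len(h), c = seq_len(w))
  dy <- rc$r - cy; dx <- rc$c - cx
  if (flip) dx <- -dx
  sy <- ( cos(th) * dy - sin(th) * dx) / scale + cy
  sx <- ( sin(th) * dy + cos(th) * dx) / scale + cx
  if (interp == "nearest") {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    val <- rep(fill, h * w)
    val[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sy); c0 <- floor(sx)
    fr <- sy - r0; fc <- sx - c0
    val <- rep(fill, h * w)
    gv <- function(ri, ci) {
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      v <- rep(fill, length(ri)); v[ok] <- img[cbind(ri[ok], ci[ok])]
      v
    }
    val <- (1 - fr) * ((1 - fc) * gv(r0, c0) + fc * gv(r0, c0 + 1)) +
      fr * ((1 - fc) * gv(r0 + 1, c0) + fc * gv(r0 + 1, c0 + 1))
  }
  matrix(val, h, w)
}

transform_triple <- function(img, mask, labels, theta = 0, scale = 1,
                             flip = FALSE, brightness = 0) {
  if (scale == 1 && theta %% 90 == 0) {
    k <- (theta %/% 90) %% 4
    ti <- rot90k(img, k); tm <- rot90k(mask, k); tl <- rot90k(labels, k)
    if (flip) { ti <- ti[, ncol(ti):1]; tm <- tm[, ncol(tm):1]
                tl <- tl[, ncol(tl):1] }
  } else {
    ti <- affine_resample(img, theta, scale, flip, "bilinear", fill = 0)
    tm <- affine_resample(mask, theta, scale, flip, "nearest", fill = 0)
    tl <- affine_resample(labels, theta, scale, flip, "nearest",
                          fill = AV_BACKGROUND)
  }
  ti <- pmin(pmax(ti + brightness, 0), 1)
  list(image = ti, mask = tm, labels = tl,
       params = list(theta = theta, scale = scale, flip = flip,
                     brightness = brightness))
}

#' Default augmentation plan
#'
#' Rotations at small (+-20 deg), moderate (+-40, +-60 deg) and right
#' angles (90/180/270), plus horizontal flipping and mild brightness and
#' scale jitter.
#'
#' @param angles rotation angles in degrees.
#' @param flip include a horizontally flipped copy.
#' @param brightness_range additive brightness jitter range (image only).
#' @param scale_range multiplicative scale jitter range (all three rasters);
#'   `NULL` disables.
#' @param seed RNG seed for the jitter draws.
#' @return a plan list consumed by [augment()].
#' @export
augment_plan <- function(angles = c(-20, 20, -40, 40, -60, 60, 90, 180, 270),
                         flip = TRUE, brightness_range = c(-0.1, 0.1),
                         scale_range = c(0.95, 1.05), seed = 1L) {
  list(angles = angles, flip = flip, brightness_range = brightness_range,
       scale_range = scale_range, seed = seed)
}

#' Jointly augment an image / mask / label triple
#'
#' Every output triple is produced by one geometric map applied to all
#' three rasters (bilinear for the image, nearest-neighbour for mask and
#' labels); brightness jitter touches the image only.
#'
#' @param img single-channel image matrix.
#' @param mask binary vessel mask.
#' @param labels integer A/V label matrix.
#' @param plan a list from [augment_plan()].
#' @return list of triples `list(image, mask, labels, params)`.
#' @export
augment <- function(img, mask, labels, plan = augment_plan()) {
  if (!identical(dim(img), dim(mask)) || !identical(dim(img), dim(labels)))
    stop("image, mask and labels must share dimensions")
  n_out <- length(plan$angles) + as.integer(isTRUE(plan$flip))
  set.seed(plan$seed)
  br <- if (is.null(plan$brightness_range)) rep(0, n_out) else
    runif(n_out, plan$brightness_range[1], plan$brightness_range[2])
  sc <- if (is.null(plan$scale_range)) rep(1, n_out) else
    runif(n_out, plan$scale_range[1], plan$scale_range[2])
  out <- vector("list", n_out)
  i <- 0L
  for (a in plan$angles) {
    i <- i + 1L
    out[[i]] <- transform_triple(img, mask, labels, theta = a,
                                 scale = sc[i], brightness = br[i])
  }
  if (isTRUE(plan$flip)) {
    i <- i + 1L
    out[[i]] <- transform_triple(img, mask, labels, flip = TRUE,
                                 scale = sc[i], brightness = br[i])
  }
  out
}
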