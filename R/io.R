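#' @useDynLib retavr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median quantile sd setNames
#' @importFrom utils write.csv read.csv head tail
NULL

# Raster I/O uses the NetPBM family (PGM for single-channel, PPM for RGB).
# 8-bit round-trips are lossless; binary (P5/P6) written by default, ASCII
# (P2/P3) readable too.

#' Write a grey image as PGM
#'
#' @param img numeric matrix in `[0, 1]` (or 0/1 for masks).
#' @param path output file path.
#' @param maxval maximum grey value written (default 255).
#' @param ascii write ASCII (P2) instead of binary (P5).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L, ascii = FALSE) {
  stopifnot(is.matrix(img))
  v <- as.integer(round(pmin(pmax(img, 0), 1) * maxval))
  # PNM is row-major, R matrices column-major
  v <- matrix(v, nrow = nrow(img))
  vr <- as.vector(t(v))
  con <- file(path, "wb")
  on.exit(close(con))
  if (ascii) {
    writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
    writeLines(paste(vr, collapse = " "), con)
  } else {
    writeLines(c("P5", paste(ncol(img), nrow(img)), as.character(maxval)), con)
    writeBin(as.raw(vr), con)
  }
  invisible(path)
}

#' Write an RGB image as PPM
#'
#' @param img H x W x 3 numeric array in `[0, 1]`.
#' @param path output file path.
#' @param maxval maximum channel value (default 255).
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path, maxval = 255L) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  v <- as.integer(round(pmin(pmax(img, 0), 1) * maxval))
  arr <- array(v, dim = dim(img))
  # interleave channels row-major
  out <- integer(h * w * 3L)
  for (ch in 1:3) out[seq(ch, by = 3L, length.out = h * w)] <-
      as.vector(t(arr[, , ch]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(w, h), as.character(maxval)), con)
  writeBin(as.raw(out), con)
  invisible(path)
}

read_pnm_header <- function(con) {
  magic <- readChar(con, 2L, useBytes = TRUE)
  tok <- character(0)
  buf <- ""
  while (length(tok) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "") stop("truncated PNM header")
    if (ch == "#") { # comment to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (ch %in% c("\n", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { tok <- c(tok, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  list(magic = magic, width = as.integer(tok[1]), height = as.integer(tok[2]),
       maxval = as.integer(tok[3]))
}

#' Read a PGM or PPM image
#'
#' @param path file path.
#' @return numeric matrix (PGM) or H x W x 3 array (PPM), values in `[0, 1]`.
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- read_pnm_header(con)
  npix <- hd$width * hd$height
  nch <- if (hd$magic %in% c("P3", "P6")) 3L else 1L
  if (hd$magic %in% c("P5", "P6")) {
    raw <- readBin(con, "integer", n = npix * nch, size = 1L, signed = FALSE)
  } else if (hd$magic %in% c("P2", "P3")) {
    raw <- scan(con, what = integer(), n = npix * nch, quiet = TRUE)
  } else stop("unsupported PNM magic: ", hd$magic)
  if (length(raw) < npix * nch) stop("truncated PNM data in ", path)
  if (nch == 1L) {
    t(matrix(raw, nrow = hd$width)) / hd$maxval
  } else {
    out <- array(0, dim = c(hd$height, hd$width, 3L))
    for (ch in 1:3) out[, , ch] <-
        t(matrix(raw[seq(ch, by = 3L, length.out = npix)], nrow = hd$width))
    out / hd$maxval
  }
}

# ---- artery/vein label maps ------------------------------------------------

# Integer label codes used throughout the package.
AV_BACKGROUND <- 0L
AV_ARTERY <- 1L
AV_VEIN <- 2L
AV_UNDEFINED <- 3L

#' Encode an integer A/V label matrix as an RGB image
#'
#' Convention: artery = red, vein = blue, undefined = green,
#' background = black.
#'
#' @param labels integer matrix with values 0 (background), 1 (artery),
#'   2 (vein), 3 (undefined).
#' @return H x W x 3 array in `[0, 1]`.
#' @export
av_labels_to_rgb <- function(labels) {
  stopifnot(is.matrix(labels))
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad)) stop("unknown label code(s): ", paste(bad, collapse = ", "))
  rgb <- array(0, dim = c(dim(labels), 3L))
  r <- matrix(0, nrow(labels), ncol(labels)); g <- r; b <- r
  r[labels == AV_ARTERY] <- 1
  b[labels == AV_VEIN] <- 1
  g[labels == AV_UNDEFINED] <- 1
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  rgb
}

#' Decode an RGB A/V label image to integer labels
#'
#' @param rgb H x W x 3 array in `[0, 1]` using the red/blue/green/black
#'   convention.
#' @return integer matrix of label codes.
#' @export
rgb_to_av_labels <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  r <- round(rgb[, , 1]); g <- round(rgb[, , 2]); b <- round(rgb[, , 3])
  lab <- matrix(NA_integer_, nrow(r), ncol(r))
  lab[r == 0 & g == 0 & b == 0] <- AV_BACKGROUND
  lab[r == 1 & g == 0 & b == 0] <- AV_ARTERY
  lab[r == 0 & g == 0 & b == 1] <- AV_VEIN
  lab[r == 0 & g == 1 & b == 0] <- AV_UNDEFINED
  if (anyNA(lab)) {
    idx <- which(is.na(lab), arr.ind = TRUE)[1, ]
    stop(sprintf("unknown label colour at pixel (row %d, col %d)",
                 idx[1], idx[2]))
  }
  lab
}

#' Write / read a binary vessel mask as PGM (0/255)
#' @param mask 0/1 matrix.
#' @param path file path.
#' @return `path` invisibly (write) or a 0/1 integer matrix (read).
#' @export
write_mask <- function(mask, path) write_pgm(mask, path)

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- read_pnm(path)
  if (!is.matrix(m)) stop("mask file is not single-channel: ", path)
  (m >= 0.5) * 1L
}

# ---- JSON helpers ----------------------------------------------------------

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
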