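# Vessel morphometry: centreline extraction by thinning, cross-sectional
# width measurement at centreline pixels, branch selection in an annulus
# around the optic disc, and the CRAE/CRVE/AVR calibre summaries.

shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbour stack in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
neighbour_stack <- function(m) {
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  lapply(offs, function(o) shift_mat(m, -o[1], -o[2]))
}

#' Skeletonise a binary vessel mask
#'
#' Zhang-Suen two-subiteration thinning: connectivity-preserving,
#' 1-pixel-wide centrelines.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- (mask != 0) * 1L
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- neighbour_stack(m)
      B <- Reduce(`+`, nb)
      seq9 <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(1:8, function(i)
        (seq9[[i]] == 0L) * (seq9[[i + 1L]] == 1L)))
      if (phase == 1) {
        c3 <- nb[[1]] * nb[[3]] * nb[[5]]  # P2 P4 P6
        c4 <- nb[[3]] * nb[[5]] * nb[[7]]  # P4 P6 P8
      } else {
        c3 <- nb[[1]] * nb[[3]] * nb[[7]]  # P2 P4 P8
        c4 <- nb[[1]] * nb[[5]] * nb[[7]]  # P2 P6 P8
      }
      del <- m == 1L & B >= 2 & B <= 6 & A == 1L & c3 == 0L & c4 == 0L
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

binary_dilate3 <- function(m) {
  nb <- neighbour_stack(m)
  ((m + Reduce(`+`, nb)) > 0) * 1L
}

binary_erode3 <- function(m) {
  nb <- neighbour_stack(m)
  ((m + Reduce(`+`, nb)) == 9L) * 1L
}

#' Clean a segmented vessel mask before morphometry
#'
#' Binary closing (3x3), filling of small interior holes, and removal of
#' small isolated components.  Noisy probability maps produce pinholes
#' and debris whose skeletons fragment into spurious junctions; cleaning
#' stabilises centreline extraction.
#'
#' @param mask 0/1 matrix.
#' @param min_object smallest kept foreground component (pixels).
#' @param min_hole largest filled background hole (pixels).
#' @param close apply 3x3 closing first.
#' @return cleaned 0/1 matrix.
#' @export
clean_mask <- function(mask, min_object = 30L, min_hole = 64L,
                       close = TRUE) {
  m <- (mask != 0) * 1L
  if (close) m <- binary_erode3(binary_dilate3(m))
  # fill interior holes: background components not touching the border
  bg <- label_components(1L - m)
  if (max(bg) > 0) {
    border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    sizes <- tabulate(bg[bg > 0])
    fill <- which(sizes <= min_hole)
    fill <- setdiff(fill, border_ids)
    if (length(fill)) m[bg %in% fill] <- 1L
  }
  fg <- label_components(m)
  if (max(fg) > 0) {
    sizes <- tabulate(fg[fg > 0])
    drop <- which(sizes < min_object)
    if (length(drop)) m[fg %in% drop] <- 0L
  }
  m
}

#' Prune short skeleton spurs
#'
#' Iteratively removes endpoint pixels (exactly one skeleton neighbour),
#' erasing side twigs shorter than `iterations` pixels; long branches
#' only lose their tips.
#'
#' @param skel 0/1 skeleton matrix.
#' @param iterations number of endpoint-erosion passes.
#' @return pruned skeleton.
#' @export
prune_skeleton <- function(skel, iterations = 5L) {
  for (i in seq_len(iterations)) {
    nb <- Reduce(`+`, neighbour_stack(skel))
    tips <- skel == 1L & nb == 1L
    if (!any(tips)) break
    skel[tips] <- 0L
  }
  skel
}

#' Label 8-connected components
#'
#' @param mask 0/1 matrix.
#' @return integer matrix of component ids (0 = background).
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  todo <- which(mask != 0)
  offs <- c(-1 - h, -h, 1 - h, -1, 1, h - 1, h, h + 1)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% h) + 1L
      nb <- p + offs
      ok <- nb >= 1 & nb <= h * w
      # guard row wrap-around at matrix top/bottom edges
      if (r == 1L) ok <- ok & !(offs %in% c(-1 - h, -1, h - 1))
      if (r == h) ok <- ok & !(offs %in% c(1 - h, 1, h + 1))
      nb <- nb[ok]
      nb <- nb[mask[nb] != 0 & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

# split a skeleton into simple branches: branch points are pixels whose
# crossing number (0->1 transitions around the 8-neighbourhood) is >= 3,
# i.e. three or more arms meet there; they are removed and the remaining
# 8-connected runs labelled.  Plain neighbour counting would fragment
# stair-step diagonal lines, whose interior pixels have 3 neighbours but
# only 2 arms.
split_branches <- function(skel) {
  nb <- neighbour_stack(skel)
  seq9 <- c(nb, nb[1])
  crossings <- Reduce(`+`, lapply(1:8, function(i)
    (seq9[[i]] == 0L) * (seq9[[i + 1L]] == 1L)))
  junction <- skel == 1L & crossings >= 3L
  core <- skel
  core[junction] <- 0L
  label_components(core)
}

# local orientation theta (radians) of a skeleton pixel from the principal
# axis of same-branch pixels in a (2r+1)^2 window; theta = atan2(dr, dc)
local_orientation <- function(branch_lab, row, col, r = 4L) {
  h <- nrow(branch_lab); w <- ncol(branch_lab)
  rs <- max(1, row - r):min(h, row + r)
  cs <- max(1, col - r):min(w, col + r)
  win <- branch_lab[rs, cs, drop = FALSE]
  pts <- which(win == branch_lab[row, col], arr.ind = TRUE)
  if (nrow(pts) < 2) return(list(theta = 0, n = nrow(pts)))
  dr <- pts[, 1] - mean(pts[, 1]); dc <- pts[, 2] - mean(pts[, 2])
  list(theta = 0.5 * atan2(2 * sum(dr * dc), sum(dc^2) - sum(dr^2)),
       n = nrow(pts))
}

#' Find the two edge pixels of a vessel cross-section
#'
#' Marches from a centreline pixel perpendicular to the local vessel
#' orientation, in both opposite directions, and returns the last
#' in-mask pixel on each side.
#'
#' @param mask 0/1 vessel mask.
#' @param centre `c(row, col)` centreline pixel (must lie in the mask).
#' @param theta local vessel orientation in radians (`theta = 0` is a
#'   horizontal vessel, so the march is vertical).
#' @param max_march maximum half-width searched, pixels.
#' @return list with `edge_a` and `edge_b`, each `c(row, col)`.
#' @export
find_edge_pair <- function(mask, centre, theta, max_march = 40) {
  if (mask[centre[1], centre[2]] == 0) stop("centre is outside the mask")
  perp <- c(cos(theta), -sin(theta))
  march <- function(sign) {
    last <- centre
    s <- 0
    repeat {
      s <- s + 0.25
      if (s > max_march) break
      p <- round(centre + sign * s * perp)
      if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask))
        break
      if (mask[p[1], p[2]] == 0) break
      last <- p
    }
    # boundary refinement: on diagonal vessels the ray only samples one
    # pixel parity, which under-reaches the true boundary; pick the
    # in-mask pixel in the 3 x 3 around the exit with the largest
    # perpendicular projection (ties keep the on-ray pixel)
    best <- last
    best_proj <- sum((last - centre) * (sign * perp))
    for (dr in -1:1) for (dc in -1:1) {
      q <- last + c(dr, dc)
      if (q[1] < 1 || q[1] > nrow(mask) || q[2] < 1 || q[2] > ncol(mask))
        next
      if (mask[q[1], q[2]] == 0) next
      proj <- sum((q - centre) * (sign * perp))
      if (proj > best_proj + 1e-9) { best <- q; best_proj <- proj }
    }
    best
  }
  list(edge_a = march(+1), edge_b = march(-1))
}

#' Euclidean cross-section width
#'
#' @param edge_a,edge_b `c(row, col)` edge pixels.
#' @return Euclidean distance in pixels.
#' @export
vessel_width <- function(edge_a, edge_b) {
  sqrt(sum((edge_a - edge_b)^2))
}

#' Measure vessel widths at every centreline pixel
#'
#' Skeletonises the mask, splits the skeleton into branches, estimates a
#' local orientation per centreline pixel and measures the cross-section
#' width between the two opposite mask-boundary pixels.  If an A/V label
#' map is supplied, each branch is assigned the majority class of its
#' pixels.
#'
#' @param mask 0/1 vessel mask.
#' @param av_labels optional integer A/V label matrix (codes 0-3).
#' @param prune endpoint-erosion passes applied to the skeleton before
#'   branch splitting (suppresses junction twigs); 0 disables.
#' @param min_support centreline pixels need at least this many
#'   same-branch neighbours in the orientation window, else they are
#'   skipped (unreliable orientation).
#' @return data.frame with columns `branch`, `class`, `row`, `col`,
#'   `theta`, `width`.
#' @export
measure_vessel_widths <- function(mask, av_labels = NULL, prune = 4L,
                                  min_support = 4L) {
  skel <- prune_skeleton(skeletonize(mask), prune)
  bl <- split_branches(skel)
  px <- which(bl != 0L, arr.ind = TRUE)
  if (!nrow(px))
    return(data.frame(branch = integer(), class = character(),
                      row = integer(), col = integer(),
                      theta = numeric(), width = numeric()))
  out <- data.frame(branch = bl[px], row = px[, 1], col = px[, 2],
                    theta = NA_real_, width = NA_real_)
  for (i in seq_len(nrow(out))) {
    lo <- local_orientation(bl, out$row[i], out$col[i])
    if (lo$n < min_support) next
    e <- find_edge_pair(mask, c(out$row[i], out$col[i]), lo$theta)
    out$theta[i] <- lo$theta
    # +1: the cross-section spans one pixel beyond the edge-centre
    # distance (half a pixel of support on each side)
    out$width[i] <- vessel_width(e$edge_a, e$edge_b) + 1
  }
  out <- out[!is.na(out$width), , drop = FALSE]
  if (!nrow(out))
    return(data.frame(branch = integer(), class = character(),
                      row = integer(), col = integer(),
                      theta = numeric(), width = numeric()))
  out$class <- "vessel"
  if (!is.null(av_labels)) {
    # per-pixel class by majority over a 5 x 5 label window: robust to
    # scattered classifier errors, yet keeps both classes of a branch
    # that runs through merged artery/vein mask regions
    h <- nrow(av_labels); w <- ncol(av_labels)
    out$class <- vapply(seq_len(nrow(out)), function(i) {
      rs <- max(1, out$row[i] - 2):min(h, out$row[i] + 2)
      cs <- max(1, out$col[i] - 2):min(w, out$col[i] + 2)
      codes <- av_labels[rs, cs]
      na <- sum(codes == AV_ARTERY); nv <- sum(codes == AV_VEIN)
      if (na + nv == 0) "undefined" else if (na >= nv) "artery" else "vein"
    }, character(1))
  }
  rownames(out) <- NULL
  out[, c("branch", "class", "row", "col", "theta", "width")]
}

#' Select the two widest arterial and venous branches in the annulus
#'
#' Keeps measurements whose centreline pixel falls in the annular zone
#' `[inner, outer] * disc_radius` around the disc centre, summarises each
#' branch by its median width, and returns the two largest per class
#' (descending; ties kept in branch-id order).
#'
#' @param measurements data.frame from [measure_vessel_widths()].
#' @param disc_center `c(row, col)`.
#' @param disc_radius pixels.
#' @param annulus `c(inner, outer)` multiples of the disc radius,
#'   default `c(2, 3)`.
#' @param min_samples minimum measurements per branch inside the annulus.
#' @param max_width branches whose median width exceeds this value
#'   (pixels) are treated as merged vessel segments and excluded; the
#'   default, one disc radius, is far above any single retinal vessel
#'   calibre.  `Inf` disables the filter.
#' @return list with `Da1`, `Da2`, `Dv1`, `Dv2` (pixels) and the per-branch
#'   median table `branches`.
#' @export
select_branches <- function(measurements, disc_center, disc_radius,
                            annulus = c(2, 3), min_samples = 3L,
                            max_width = disc_radius) {
  d <- sqrt((measurements$row - disc_center[1])^2 +
              (measurements$col - disc_center[2])^2)
  m <- measurements[d >= annulus[1] * disc_radius &
                      d <= annulus[2] * disc_radius, , drop = FALSE]
  if (!nrow(m)) stop_insufficient("no measurements inside the annulus")
  # aggregate by (branch, class): a skeleton run through a merged
  # artery/vein region contributes to both classes
  agg <- do.call(rbind, lapply(split(m, list(m$branch, m$class),
                                     drop = TRUE), function(g)
    data.frame(branch = g$branch[1], class = g$class[1], n = nrow(g),
               median_width = median(g$width))))
  agg <- agg[agg$n >= min_samples & agg$median_width <= max_width, ,
             drop = FALSE]
  top2 <- function(cls) {
    g <- agg[agg$class == cls, , drop = FALSE]
    if (nrow(g) < 2)
      stop_insufficient(sprintf(
        "need >= 2 %s branches in the annulus, found %d", cls, nrow(g)))
    g <- g[order(-g$median_width, g$branch), , drop = FALSE]
    g$median_width[1:2]
  }
  a <- top2("artery"); v <- top2("vein")
  list(Da1 = a[1], Da2 = a[2], Dv1 = v[1], Dv2 = v[2], branches = agg)
}

stop_insufficient <- function(msg) {
  stop(structure(class = c("retavr_insufficient_vessels", "error",
                           "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Central retinal artery equivalent (CRAE)
#'
#' Combines the two largest arteriolar diameters.  Mode `"paper"` uses the
#' quadratic form exactly as printed in the source model
#' (`Da1^2 + 1.01 Da2^2 - 0.22 Da1 Da2 - 10.73`); mode `"canonical"` is the
#' classical Parr-Hubbard root form
#' `sqrt(0.87 Da1^2 + 1.01 Da2^2 - 0.22 Da1 Da2 - 10.76)` (diameters in
#' micrometres).
#'
#' @param Da1,Da2 arteriolar diameters (Da1 >= Da2 conventionally).
#' @param mode `"paper"` or `"canonical"`.
#' @return calibre value.
#' @export
crae <- function(Da1, Da2, mode = c("paper", "canonical")) {
  mode <- match.arg(mode)
  if (Da1 < 0 || Da2 < 0) stop("diameters must be non-negative")
  if (mode == "paper")
    return(Da1^2 + 1.01 * Da2^2 - 0.22 * Da1 * Da2 - 10.73)
  rad <- 0.87 * Da1^2 + 1.01 * Da2^2 - 0.22 * Da1 * Da2 - 10.76
  if (rad < 0) stop("canonical CRAE radicand is negative (diameters too small)")
  sqrt(rad)
}

#' Central retinal vein equivalent (CRVE)
#'
#' Mode `"paper"`: `1.72 Dv1^2 + 0.91 Dv2^2 + 450.02` as printed;
#' mode `"canonical"`: `sqrt(0.72 Dv1^2 + 0.91 Dv2^2 + 450.05)`.
#'
#' @param Dv1,Dv2 venular diameters.
#' @param mode `"paper"` or `"canonical"`.
#' @return calibre value.
#' @export
crve <- function(Dv1, Dv2, mode = c("paper", "canonical")) {
  mode <- match.arg(mode)
  if (Dv1 < 0 || Dv2 < 0) stop("diameters must be non-negative")
  if (mode == "paper")
    return(1.72 * Dv1^2 + 0.91 * Dv2^2 + 450.02)
  sqrt(0.72 * Dv1^2 + 0.91 * Dv2^2 + 450.05)
}

#' Arteriovenous ratio
#'
#' @param crae,crve calibres from [crae()] and [crve()] in the same mode.
#' @return `crae / crve`.
#' @export
avr <- function(crae, crve) {
  if (crve <= 0) stop("CRVE must be positive to form an AVR")
  crae / crve
}

#' Full calibre summary from a mask and label map
#'
#' @param mask binary vessel mask.
#' @param av_labels integer A/V label matrix.
#' @param disc_center,disc_radius optic-disc geometry (pixels).
#' @param annulus annular zone in disc radii.
#' @param pixel_spacing micrometres per pixel; measured widths are
#'   converted to micrometres before the calibre formulas.  Use 1 to stay
#'   in pixel units.
#' @param mode calibre formula mode, `"canonical"` (default here: it yields
#'   clinically scaled AVR values) or `"paper"`.
#' @return list with the selected diameters (pixels and micrometres),
#'   `crae`, `crve`, `avr`, `mode` and the per-branch table.
#' @export
calibre_summary <- function(mask, av_labels, disc_center, disc_radius,
                            annulus = c(2, 3), pixel_spacing = 1,
                            mode = "canonical") {
  meas <- measure_vessel_widths(mask, av_labels)
  sel <- select_branches(meas, disc_center, disc_radius, annulus)
  um <- lapply(sel[c("Da1", "Da2", "Dv1", "Dv2")],
               function(x) x * pixel_spacing)
  cr <- crae(um$Da1, um$Da2, mode = mode)
  cv <- crve(um$Dv1, um$Dv2, mode = mode)
  list(Da1 = sel$Da1, Da2 = sel$Da2, Dv1 = sel$Dv1, Dv2 = sel$Dv2,
       Da1_um = um$Da1, Da2_um = um$Da2, Dv1_um = um$Dv1, Dv2_um = um$Dv2,
       crae = cr, crve = cv, avr = avr(cr, cv), mode = mode,
       annulus = annulus, pixel_spacing = pixel_spacing,
       branches = sel$branches, measurements = meas)
}
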