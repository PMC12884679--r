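# Synthetic fundus generator: tree-structured vessels grown from the optic
# disc rim, rasterised with known per-branch widths and artery/vein labels,
# plus ground-truth CRAE/CRVE/AVR computed from the root calibres.
#
# Emulated contrasts (fixed by the stated world, not tuned): arteries are
# brighter and narrower with a central light-reflex stripe; veins are darker
# and wider; both classes form disjoint trees rooted on the disc boundary.

#' Specification of a synthetic vessel tree sample
#'
#' Defaults describe a DRIVE-like healthy eye at 256 x 256 with an
#' 8 um/pixel spacing: artery roots ~13 px (104 um), vein roots ~19 px
#' (152 um), giving a canonical-mode AVR of about 0.69.
#'
#' @param seed RNG seed (single global stream per sample).
#' @param image_size `c(H, W)` in pixels.
#' @param disc_center `c(row, col)` of the optic disc.
#' @param disc_radius disc radius in pixels.
#' @param n_arteries,n_veins number of root vessels per class.
#' @param root_width_artery,root_width_vein widest root calibre per class
#'   (pixels); the k-th root of a class is tapered by `0.95^(k-1)`.
#' @param branch_depth bifurcation generations below the root.
#' @param width_decay child width = parent width * width_decay, in (0, 1).
#' @param tortuosity perturbation amplitude of the midpoint-displaced
#'   centrelines (0 = straight).
#' @param artery_intensity,vein_intensity,background_intensity green-channel
#'   grey levels in `[0, 1]`; arteries must be brighter than veins.
#' @param reflex_strength added brightness of the arterial central reflex.
#' @param noise_sd additive Gaussian noise (grey levels).
#' @param pixel_spacing micrometres per pixel.
#' @param formula_mode `"canonical"` or `"paper"`; the mode used to derive
#'   the ground-truth calibres (kept equal to the pipeline's mode so
#'   recovery tests are self-consistent).
#' @return a `vessel_tree_spec` list.
#' @export
vessel_tree_spec <- function(seed = 1L,
                             image_size = c(256L, 256L),
                             disc_center = c(128, 128),
                             disc_radius = 25,
                             n_arteries = 4L, n_veins = 4L,
                             root_width_artery = 13,
                             root_width_vein = 19,
                             branch_depth = 3L,
                             width_decay = 0.8,
                             tortuosity = 0.5,
                             artery_intensity = 0.75,
                             vein_intensity = 0.45,
                             background_intensity = 0.15,
                             reflex_strength = 0.4,
                             noise_sd = 0.02,
                             pixel_spacing = 8,
                             formula_mode = "canonical") {
  spec <- list(seed = as.integer(seed), image_size = as.integer(image_size),
               disc_center = disc_center, disc_radius = disc_radius,
               n_arteries = as.integer(n_arteries),
               n_veins = as.integer(n_veins),
               root_width_artery = root_width_artery,
               root_width_vein = root_width_vein,
               branch_depth = as.integer(branch_depth),
               width_decay = width_decay, tortuosity = tortuosity,
               artery_intensity = artery_intensity,
               vein_intensity = vein_intensity,
               background_intensity = background_intensity,
               reflex_strength = reflex_strength, noise_sd = noise_sd,
               pixel_spacing = pixel_spacing, formula_mode = formula_mode)
  validate_tree_spec(spec)
  structure(spec, class = "vessel_tree_spec")
}

validate_tree_spec <- function(spec) {
  if (spec$root_width_vein <= spec$root_width_artery)
    stop("veins must be wider than arteries (root_width_vein > root_width_artery)")
  if (spec$artery_intensity <= spec$vein_intensity)
    stop("arteries must be brighter than veins")
  if (spec$root_width_artery <= 0 || spec$root_width_vein <= 0)
    stop("root widths must be strictly positive")
  if (spec$width_decay <= 0 || spec$width_decay >= 1)
    stop("width_decay must lie in (0, 1)")
  if (spec$tortuosity < 0) stop("tortuosity must be >= 0")
  # the disc plus the measurement annulus (3 * disc radius) must fit
  room <- min(spec$disc_center[1], spec$disc_center[2],
              spec$image_size[1] - spec$disc_center[1],
              spec$image_size[2] - spec$disc_center[2])
  if (room < 3 * spec$disc_radius)
    stop("image_size too small to contain the disc and measurement annulus")
  invisible(spec)
}

#' Healthy / hypertensive presets
#'
#' The healthy preset keeps the defaults of [vessel_tree_spec()]
#' (canonical AVR ~0.69); the `"hr"` preset narrows arteries to 8 px and
#' dilates veins to 22 px, pushing the true AVR to ~0.37 (< 0.5).
#'
#' @param preset `"healthy"` or `"hr"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [vessel_tree_spec()].
#' @return a `vessel_tree_spec`.
#' @export
preset_spec <- function(preset = c("healthy", "hr"), seed = 1L, ...) {
  preset <- match.arg(preset)
  if (preset == "healthy") vessel_tree_spec(seed = seed, ...)
  else vessel_tree_spec(seed = seed, root_width_artery = 8,
                        root_width_vein = 22, ...)
}

# subdivide a straight segment into a midpoint-displaced polyline;
# amplitude scales with tortuosity and segment length, halving per level
perturb_polyline <- function(p0, p1, tortuosity, levels = 3L) {
  pts <- rbind(p0, p1)
  if (tortuosity <= 0 || levels < 1) return(pts)
  amp <- tortuosity * sqrt(sum((p1 - p0)^2)) * 0.08
  for (lv in seq_len(levels)) {
    n <- nrow(pts)
    mid <- (pts[-n, , drop = FALSE] + pts[-1, , drop = FALSE]) / 2
    d <- pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE]
    # unit normal of each edge
    len <- sqrt(rowSums(d^2)); len[len == 0] <- 1
    nrm <- cbind(-d[, 2] / len, d[, 1] / len)
    mid <- mid + nrm * rnorm(n - 1, sd = amp)
    out <- matrix(0, 2 * n - 1, 2)
    out[seq(1, 2 * n - 1, by = 2), ] <- pts
    out[seq(2, 2 * n - 2, by = 2), ] <- mid
    pts <- out
    amp <- amp / 2
  }
  pts
}

grow_branch <- function(origin, angle, length, width, depth, spec, class,
                        tree_id, env) {
  p1 <- origin + length * c(sin(angle), cos(angle))
  poly <- perturb_polyline(origin, p1, spec$tortuosity)
  env$segments[[length(env$segments) + 1L]] <- list(
    polyline = poly, width = max(width, 1), class = class,
    depth = depth, tree = tree_id)
  if (depth < spec$branch_depth) {
    spread <- (25 + runif(1, -5, 5)) * pi / 180
    for (s in c(-1, 1)) {
      grow_branch(p1, angle + s * spread + rnorm(1, sd = 0.05),
                  length * 0.7, width * spec$width_decay,
                  depth + 1L, spec, class, tree_id, env)
    }
  }
}

#' Grow the synthetic vessel trees
#'
#' Roots alternate artery/vein around the disc rim and extend radially;
#' every bifurcation multiplies the width by `width_decay`.  The root
#' segments are long enough that no bifurcation falls inside the default
#' measurement annulus (2-3 disc radii).
#'
#' @param spec a `vessel_tree_spec`.
#' @return list of segments, each `list(polyline, width, class, depth, tree)`
#'   with `class` in `{"artery", "vein"}` and polyline rows `(row, col)`.
#' @export
generate_tree <- function(spec) {
  validate_tree_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_arteries + spec$n_veins
  # alternate classes around the rim: a, v, a, v, ...
  classes <- rep("vein", n)
  slots <- unique(round(seq(1, n, length.out = spec$n_arteries)))
  if (length(slots) < spec$n_arteries)
    slots <- seq_len(spec$n_arteries)
  classes[slots] <- "artery"
  base_angle <- runif(1, 0, 2 * pi)
  angles <- base_angle + 2 * pi * (seq_len(n) - 1) / n +
    runif(n, -0.3, 0.3) * pi / n
  env <- new.env()
  env$segments <- list()
  a_rank <- 0L; v_rank <- 0L
  root_len <- 2.3 * spec$disc_radius  # branch point beyond the 3R annulus
  for (i in seq_len(n)) {
    cls <- classes[i]
    if (cls == "artery") {
      a_rank <- a_rank + 1L
      w0 <- spec$root_width_artery * 0.95^(a_rank - 1L)
    } else {
      v_rank <- v_rank + 1L
      w0 <- spec$root_width_vein * 0.95^(v_rank - 1L)
    }
    origin <- spec$disc_center +
      spec$disc_radius * c(sin(angles[i]), cos(angles[i]))
    grow_branch(origin, angles[i], root_len, w0, 0L, spec, cls, i, env)
  }
  env$segments
}

# distance from every pixel in a bounding box to a polyline; returns the
# pixel coordinates within `radius` of the curve
stroke_polyline <- function(poly, radius, h, w) {
  rmin <- max(1L, floor(min(poly[, 1]) - radius - 1))
  rmax <- min(h, ceiling(max(poly[, 1]) + radius + 1))
  cmin <- max(1L, floor(min(poly[, 2]) - radius - 1))
  cmax <- min(w, ceiling(max(poly[, 2]) + radius + 1))
  if (rmin > rmax || cmin > cmax) return(NULL)
  gr <- expand.grid(r = rmin:rmax, c = cmin:cmax)
  d2 <- rep(Inf, nrow(gr))
  for (k in seq_len(nrow(poly) - 1L)) {
    a <- poly[k, ]; b <- poly[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      dd <- (gr$r - a[1])^2 + (gr$c - a[2])^2
    } else {
      t <- ((gr$r - a[1]) * ab[1] + (gr$c - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      dd <- (gr$r - (a[1] + t * ab[1]))^2 + (gr$c - (a[2] + t * ab[2]))^2
    }
    d2 <- pmin(d2, dd)
  }
  keep <- d2 <= radius^2
  list(rows = gr$r[keep], cols = gr$c[keep], dist = sqrt(d2[keep]))
}

# dense sample of integer centreline pixels along a polyline
trace_centreline <- function(poly) {
  pts <- NULL
  for (k in seq_len(nrow(poly) - 1L)) {
    a <- poly[k, ]; b <- poly[k + 1L, ]
    n <- max(2L, ceiling(2 * sqrt(sum((b - a)^2))))
    t <- seq(0, 1, length.out = n)
    pts <- rbind(pts, cbind(a[1] + t * (b[1] - a[1]),
                            a[2] + t * (b[2] - a[2])))
  }
  unique(round(pts))
}

#' Rasterise a synthetic sample
#'
#' Produces the RGB image, the exact binary vessel mask, the A/V label
#' map, a per-centreline-pixel width table and the ground-truth calibres.
#' Vessel pixels carry their class intensity exactly (no anti-aliasing on
#' the mask); the intensity image adds an illumination gradient on the
#' background, the arterial central reflex, and Gaussian noise.
#'
#' @param spec a `vessel_tree_spec`.
#' @return a `synthetic_sample` list with elements `image`
#'   (a [fundus_image()]), `vessel_mask`, `av_labels`, `width_map`
#'   (data.frame row/col/width/class/branch), `true_crae`, `true_crve`,
#'   `true_avr`, `disc_center`, `disc_radius`, `spec`.
#' @export
render_sample <- function(spec) {
  segments <- generate_tree(spec)  # also seeds the RNG stream
  h <- spec$image_size[1]; w <- spec$image_size[2]
  mask <- matrix(0L, h, w)
  labels <- matrix(AV_BACKGROUND, h, w)
  green <- matrix(0, h, w)

  # background illumination gradient (radial falloff)
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  dist_c <- sqrt((rr - (h + 1) / 2)^2 + (cc - (w + 1) / 2)^2)
  illum <- 1 - 0.35 * (dist_c / max(dist_c))^2
  green[] <- spec$background_intensity * illum

  # veins first, arteries drawn over them (arteries cross over veins)
  ord <- order(vapply(segments, function(s) s$class == "artery", logical(1)))
  for (s in segments[ord]) {
    st <- stroke_polyline(s$polyline, s$width / 2, h, w)
    if (is.null(st) || !length(st$rows)) next
    idx <- cbind(st$rows, st$cols)
    mask[idx] <- 1L
    if (s$class == "artery") {
      labels[idx] <- AV_ARTERY
      green[idx] <- spec$artery_intensity
      # central light reflex: bright stripe along the core
      core <- st$dist <= s$width / 6
      if (any(core))
        green[idx[core, , drop = FALSE]] <-
          pmin(spec$artery_intensity + spec$reflex_strength *
                 (1 - spec$artery_intensity), 1)
    } else {
      labels[idx] <- AV_VEIN
      green[idx] <- spec$vein_intensity
    }
  }

  # optic disc: bright plateau (kept out of the vessel mask)
  disc <- (rr - spec$disc_center[1])^2 + (cc - spec$disc_center[2])^2 <=
    spec$disc_radius^2
  bgdisc <- disc & mask == 0L
  green[bgdisc] <- pmin(green[bgdisc] + 0.35, 1)

  if (spec$noise_sd > 0)
    green <- pmin(pmax(green + rnorm(h * w, sd = spec$noise_sd), 0), 1)

  red <- pmin(pmax(0.80 * illum, 0), 1)
  blue <- matrix(0.12, h, w)
  img <- array(0, dim = c(h, w, 3L))
  img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue

  # per-centreline-pixel true widths
  wm <- NULL
  for (bi in seq_along(segments)) {
    s <- segments[[bi]]
    cl <- trace_centreline(s$polyline)
    keep <- cl[, 1] >= 1 & cl[, 1] <= h & cl[, 2] >= 1 & cl[, 2] <= w
    cl <- cl[keep, , drop = FALSE]
    if (!nrow(cl)) next
    wm <- rbind(wm, data.frame(row = cl[, 1], col = cl[, 2],
                               width = max(s$width, 1), class = s$class,
                               branch = bi))
  }
  # centreline pixels of covered veins at crossings keep their own width
  wm <- wm[mask[cbind(wm$row, wm$col)] == 1L, , drop = FALSE]

  truth <- true_calibres(spec)
  structure(list(image = fundus_image(img, pixel_spacing = spec$pixel_spacing),
                 vessel_mask = mask, av_labels = labels, width_map = wm,
                 true_crae = truth$crae, true_crve = truth$crve,
                 true_avr = truth$avr,
                 disc_center = spec$disc_center,
                 disc_radius = spec$disc_radius, spec = spec),
            class = "synthetic_sample")
}

# ground-truth calibres from the two widest roots per class, converted to
# micrometres and combined with the configured calibre formula mode
true_calibres <- function(spec) {
  a <- sort(spec$root_width_artery * 0.95^(seq_len(spec$n_arteries) - 1L),
            decreasing = TRUE)
  v <- sort(spec$root_width_vein * 0.95^(seq_len(spec$n_veins) - 1L),
            decreasing = TRUE)
  if (length(a) < 2L || length(v) < 2L)
    stop("need at least two roots per class for ground-truth calibres")
  sp <- spec$pixel_spacing
  cr <- crae(a[1] * sp, a[2] * sp, mode = spec$formula_mode)
  cv <- crve(v[1] * sp, v[2] * sp, mode = spec$formula_mode)
  list(crae = cr, crve = cv, avr = avr(cr, cv))
}

#' Write a sample bundle to disk
#'
#' Writes `image.ppm`, `mask.pgm`, `av.ppm`, `widths.csv` and `meta.json`
#' into `dir`.
#'
#' @param sample a `synthetic_sample`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ppm(sample$image$pixels, file.path(dir, "image.ppm"))
  write_mask(sample$vessel_mask, file.path(dir, "mask.pgm"))
  write_ppm(av_labels_to_rgb(sample$av_labels), file.path(dir, "av.ppm"))
  write.csv(sample$width_map, file.path(dir, "widths.csv"), row.names = FALSE)
  meta <- c(sample$spec,
            list(true_crae = sample$true_crae, true_crve = sample$true_crve,
                 true_avr = sample$true_avr))
  write_json_report(meta, file.path(dir, "meta.json"))
  invisible(dir)
}
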