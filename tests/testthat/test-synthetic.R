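# Synthetic fundus generator: determinism, geometry, rasterisation and
# ground-truth calibres.

small_spec <- function(...) {
  vessel_tree_spec(seed = 5L, image_size = c(64L, 64L),
                   disc_center = c(32, 32), disc_radius = 8,
                   n_arteries = 2L, n_veins = 2L,
                   root_width_artery = 4, root_width_vein = 6,
                   branch_depth = 0L, tortuosity = 0, noise_sd = 0,
                   reflex_strength = 0, ...)
}

test_that("spec invariants are enforced", {
  expect_error(vessel_tree_spec(root_width_artery = 10, root_width_vein = 8),
               "wider")
  expect_error(vessel_tree_spec(artery_intensity = 0.4, vein_intensity = 0.5),
               "brighter")
  expect_error(vessel_tree_spec(width_decay = 1), "width_decay")
  expect_error(vessel_tree_spec(image_size = c(80L, 80L)), "too small")
})

test_that("generate_tree is deterministic and respects depth and decay", {
  sp <- vessel_tree_spec(seed = 11L, branch_depth = 2L, width_decay = 0.8,
                         root_width_artery = 10, root_width_vein = 19,
                         n_arteries = 1L, n_veins = 1L)
  t1 <- generate_tree(sp)
  t2 <- generate_tree(sp)
  expect_identical(t1, t2)

  # depth 0: exactly one unbranched segment per root
  sp0 <- small_spec()
  segs <- generate_tree(sp0)
  expect_length(segs, sp0$n_arteries + sp0$n_veins)
  expect_true(all(vapply(segs, function(s) s$depth, integer(1)) == 0L))

  # decay rule: widest artery root is 10, its depth-2 descendants 6.4
  a_widths <- vapply(Filter(function(s) s$class == "artery", t1),
                     function(s) s$width, numeric(1))
  a_depths <- vapply(Filter(function(s) s$class == "artery", t1),
                     function(s) s$depth, integer(1))
  expect_equal(max(a_widths[a_depths == 0L]), 10)
  expect_equal(max(a_widths[a_depths == 2L]), 10 * 0.8^2, tolerance = 1e-12)

  # arteries and veins form disjoint trees
  tree_cls <- vapply(t1, function(s) paste(s$tree, s$class), character(1))
  expect_equal(length(unique(vapply(t1, function(s) s$tree, integer(1)))),
               2L)
  expect_true(all(table(tree_cls) > 0))
})

test_that("render_sample is bitwise deterministic", {
  sp <- small_spec()
  s1 <- render_sample(sp)
  s2 <- render_sample(sp)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$vessel_mask, s2$vessel_mask)
  expect_identical(s1$av_labels, s2$av_labels)
})

test_that("noise-free artery pixels carry exactly the artery intensity", {
  s <- render_sample(small_spec())
  g <- s$image$pixels[, , 2]
  a <- s$av_labels == 1L
  expect_true(any(a))
  expect_true(all(g[a] == s$spec$artery_intensity))
})

test_that("labels and mask agree, and the mask matches a per-pixel oracle", {
  sp <- small_spec()
  s <- render_sample(sp)
  expect_true(all((s$av_labels %in% c(1L, 2L)) == (s$vessel_mask == 1L)))

  # independent rasteriser: point-to-polyline distance per pixel
  segs <- generate_tree(sp)
  h <- sp$image_size[1]; w <- sp$image_size[2]
  oracle <- matrix(0L, h, w)
  for (seg in segs) {
    for (r in seq_len(h)) for (cc in seq_len(w)) {
      dmin <- Inf
      for (k in seq_len(nrow(seg$polyline) - 1)) {
        a <- seg$polyline[k, ]; b <- seg$polyline[k + 1, ]
        ab <- b - a; t <- sum((c(r, cc) - a) * ab) / sum(ab^2)
        t <- min(max(t, 0), 1)
        dmin <- min(dmin, sqrt(sum((c(r, cc) - (a + t * ab))^2)))
      }
      if (dmin <= seg$width / 2) oracle[r, cc] <- 1L
    }
  }
  expect_identical(s$vessel_mask, oracle)
})

test_that("arteries are brighter than veins across seeds", {
  ok <- vapply(1:10, function(sd) {
    s <- render_sample(vessel_tree_spec(seed = sd, image_size = c(128L, 128L),
                                        disc_center = c(64, 64),
                                        disc_radius = 14,
                                        root_width_artery = 7,
                                        root_width_vein = 10,
                                        branch_depth = 1L))
    g <- s$image$pixels[, , 2]
    mean(g[s$av_labels == 1L]) > mean(g[s$av_labels == 2L])
  }, logical(1))
  expect_true(all(ok))
})

test_that("rasterised thickness of a straight horizontal vessel is w +- 1", {
  for (w in c(4, 7, 10)) {
    poly <- rbind(c(20, 5), c(20, 59))
    st <- retavr:::stroke_polyline(poly, w / 2, 64L, 64L)
    m <- matrix(0L, 64, 64); m[cbind(st$rows, st$cols)] <- 1L
    thick <- colSums(m[, 10:55])
    expect_true(all(abs(thick - w) <= 1), info = paste("width", w))
  }
})

test_that("ground-truth calibres are self-consistent and directionally right", {
  s <- fixture_sample()
  expect_equal(s$true_avr, s$true_crae / s$true_crve, tolerance = 1e-12)
  expect_true(all(s$width_map$width >= 1))
  narrower <- render_sample(vessel_tree_spec(seed = 7L,
                                             root_width_artery = 10))
  expect_lt(narrower$true_avr, s$true_avr)
})

test_that("sample bundles round-trip through disk", {
  s <- render_sample(small_spec())
  dir <- withr::local_tempdir()
  write_sample(s, dir)
  expect_identical(read_mask(file.path(dir, "mask.pgm")), s$vessel_mask)
  av <- rgb_to_av_labels(read_pnm(file.path(dir, "av.ppm")))
  expect_identical(av, s$av_labels)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$true_avr, s$true_avr, tolerance = 1e-9)
  widths <- read.csv(file.path(dir, "widths.csv"))
  expect_equal(nrow(widths), nrow(s$width_map))
})

test_that("the hr preset pushes the true AVR below 0.5", {
  h <- render_sample(preset_spec("healthy", seed = 3L))
  r <- render_sample(preset_spec("hr", seed = 3L))
  expect_gt(h$true_avr, 0.6)
  expect_lt(r$true_avr, 0.5)
})
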