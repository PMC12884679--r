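# End-to-end pipeline: preprocess -> segment -> pixel graph -> A/V GCN ->
# calibre measurement -> AVR -> HR grade, with every intermediate
# persisted when an output directory is given.

#' Pipeline configuration
#'
#' @param seed global seed, logged in the report.
#' @param green_mode,clip_limit,tile_grid,sigma preprocessing options.
#' @param threshold vessel-probability binarisation threshold.
#' @param annulus measurement annulus in disc radii.
#' @param formula_mode `"canonical"` (default: micrometre-scaled
#'   Parr-Hubbard, clinically interpretable AVR) or `"paper"` (the printed
#'   quadratic forms).
#' @param pixel_spacing micrometres per pixel used for calibre conversion
#'   when the input image does not carry its own spacing.
#' @param use_intensity_feature append the enhanced intensity to the
#'   segmenter feature maps as a GCN node feature.
#' @param out_dir artefact directory (`NULL` = keep everything in memory).
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, green_mode = "normalised",
                            clip_limit = 2, tile_grid = c(8L, 8L),
                            sigma = 0.8, threshold = 0.5,
                            annulus = c(2, 3), formula_mode = "canonical",
                            pixel_spacing = 8,
                            use_intensity_feature = TRUE, out_dir = NULL) {
  list(seed = as.integer(seed), green_mode = green_mode,
       clip_limit = clip_limit, tile_grid = tile_grid, sigma = sigma,
       threshold = threshold, annulus = annulus,
       formula_mode = formula_mode, pixel_spacing = pixel_spacing,
       use_intensity_feature = use_intensity_feature, out_dir = out_dir)
}

pipeline_features <- function(seg_model, enhanced, cfg) {
  pr <- predict_vessels(seg_model, enhanced, return_features = TRUE)
  feats <- pr$features
  if (isTRUE(cfg$use_intensity_feature)) {
    feats2 <- array(0, dim = dim(feats) + c(0, 0, 1))
    feats2[, , seq_len(dim(feats)[3])] <- feats
    feats2[, , dim(feats2)[3]] <- enhanced
    feats <- feats2
  }
  list(prob = pr$prob, features = feats)
}

#' Train the pipeline's segmentation and A/V models on synthetic data
#'
#' Generates `n_train` healthy-preset samples (half-size, 128 x 128),
#' trains the Res-UNet on enhanced-image/mask pairs and the GCN on
#' ground-truth vessel graphs whose node features are the segmenter's
#' decoder feature maps (plus the enhanced intensity).
#'
#' @param n_train number of synthetic training images.
#' @param seed master seed.
#' @param seg_cfg,tcfg,gcn_cfg model and schedule configurations.
#' @param cfg a [pipeline_config()].
#' @param n_gcn_graphs how many of the samples also feed GCN training.
#' @return list with `seg_model` and `gcn_model`.
#' @export
fit_pipeline_models <- function(n_train = 12L, seed = 1L,
                                seg_cfg = seg_config(),
                                tcfg = train_config(seed = seed,
                                                    patches_per_image = 2L),
                                gcn_cfg = gcn_config(seed = seed,
                                                     epochs = 100L),
                                cfg = pipeline_config(seed = seed),
                                n_gcn_graphs = 4L) {
  # alternate healthy / hypertensive geometry so both calibre regimes are
  # represented in training
  specs <- lapply(seq_len(n_train), function(i)
    preset_spec(if (i %% 3 == 0) "hr" else "healthy",
                seed = seed * 1000L + i))
  samples <- lapply(specs, render_sample)
  seg_samples <- lapply(samples, function(s)
    list(x = enhance_fundus(s$image, cfg$green_mode, cfg$clip_limit,
                            cfg$tile_grid, cfg$sigma),
         y = s$vessel_mask))
  seg_model <- train_segmenter(seg_samples, seg_cfg, tcfg)
  graphs <- list(); labels <- list()
  for (i in seq_len(min(n_gcn_graphs, n_train))) {
    s <- samples[[i]]
    pf <- pipeline_features(seg_model, seg_samples[[i]]$x, cfg)
    g <- build_graph(s$vessel_mask)
    g <- extract_node_features(g, pf$features)
    lb <- s$av_labels[cbind(g$nodes$row + 1L, g$nodes$col + 1L)]
    lb <- ifelse(lb == AV_ARTERY, 1L, ifelse(lb == AV_VEIN, 2L, NA_integer_))
    graphs[[i]] <- g; labels[[i]] <- lb
  }
  gcn_model <- train_gcn(graphs, labels, gcn_cfg)
  list(seg_model = seg_model, gcn_model = gcn_model)
}

# half-size spec used for model fitting (128 x 128 keeps desk-scale
# training inside minutes); geometry scales with the smaller frame
training_spec <- function(seed, preset = "healthy") {
  preset_spec(preset, seed = seed,
              image_size = c(128L, 128L), disc_center = c(64, 64),
              disc_radius = 14, root_width_artery = 7,
              root_width_vein = 10, branch_depth = 2L,
              pixel_spacing = 16)
}

#' Run the full analysis pipeline on one image
#'
#' @param input a `synthetic_sample`, or a list with `image`
#'   (a [fundus_image()]), `disc_center` and `disc_radius`.
#' @param models list with `seg_model` and `gcn_model` (from
#'   [fit_pipeline_models()] or loaded checkpoints).
#' @param cfg a [pipeline_config()].
#' @return a `run_report` list: per-stage timings, mask statistics, the
#'   calibre summary, the HR verdict, and (in memory) the intermediate
#'   rasters.
#' @export
run_pipeline <- function(input, models, cfg = pipeline_config()) {
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, code) {
    t0 <- tic()
    out <- tryCatch(code, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    t_all[[name]] <<- round(tic() - t0, 3)
    out
  }
  if (inherits(input, "synthetic_sample")) {
    img <- input$image
    disc_center <- input$disc_center; disc_radius <- input$disc_radius
  } else {
    img <- input$image
    disc_center <- input$disc_center; disc_radius <- input$disc_radius
    if (is.null(disc_center) || is.null(disc_radius))
      stop("disc_center and disc_radius are required inputs")
  }
  spacing <- img$pixel_spacing
  if (is.null(spacing) || is.na(spacing)) spacing <- cfg$pixel_spacing

  enhanced <- stage("preprocess", enhance_fundus(
    img, cfg$green_mode, cfg$clip_limit, cfg$tile_grid, cfg$sigma))
  seg <- stage("segment", pipeline_features(models$seg_model, enhanced, cfg))
  mask <- clean_mask(binarize(seg$prob, cfg$threshold))
  graph <- stage("graph", {
    g <- build_graph(mask)
    if (g$n_nodes == 0) stop("no vessel pixels segmented")
    extract_node_features(g, seg$features)
  })
  avpred <- stage("classify", predict_av(models$gcn_model, graph))
  av_map <- labels_to_image(avpred, graph)
  calibre <- stage("measure", calibre_summary(
    mask, av_map, disc_center, disc_radius, annulus = cfg$annulus,
    pixel_spacing = spacing, mode = cfg$formula_mode))
  verdict <- stage("grade", hr_verdict(calibre$avr))

  report <- list(
    seed = cfg$seed,
    stages = t_all,
    mask_pixels = sum(mask),
    graph_nodes = graph$n_nodes,
    graph_edges = (sum(graph$adjacency) - graph$n_nodes) / 2,
    calibre = calibre[c("Da1", "Da2", "Dv1", "Dv2", "crae", "crve",
                        "avr", "mode")],
    verdict = verdict,
    artefacts = NULL)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      enhanced = file.path(cfg$out_dir, "enhanced.pgm"),
      probability = file.path(cfg$out_dir, "probability.pgm"),
      mask = file.path(cfg$out_dir, "mask.pgm"),
      av = file.path(cfg$out_dir, "av.ppm"),
      measurements = file.path(cfg$out_dir, "measurements.csv"),
      report = file.path(cfg$out_dir, "report.json"))
    write_pgm(enhanced, paths$enhanced)
    write_pgm(seg$prob, paths$probability)
    write_mask(mask, paths$mask)
    write_ppm(av_labels_to_rgb(av_map), paths$av)
    write.csv(calibre$measurements, paths$measurements, row.names = FALSE)
    report$artefacts <- paths
    write_json_report(report[setdiff(names(report), "artefacts")],
                      paths$report)
  }
  report$enhanced <- enhanced
  report$probability <- seg$prob
  report$mask <- mask
  report$av_map <- av_map
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("retavr run report\n")
  cat(sprintf("  vessel pixels: %d   graph nodes: %d   edges: %d\n",
              x$mask_pixels, x$graph_nodes, as.integer(x$graph_edges)))
  cat(sprintf("  diameters (px): Da1=%.2f Da2=%.2f Dv1=%.2f Dv2=%.2f\n",
              x$calibre$Da1, x$calibre$Da2, x$calibre$Dv1, x$calibre$Dv2))
  cat(sprintf("  CRAE=%.2f CRVE=%.2f AVR=%.3f (%s mode)\n",
              x$calibre$crae, x$calibre$crve, x$calibre$avr,
              x$calibre$mode))
  cat(sprintf("  grade: %s   decision: %s\n",
              x$verdict$grade, x$verdict$binary))
  invisible(x)
}
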