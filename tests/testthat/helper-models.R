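# Shared, lazily fitted model fixtures.  Fitting the pipeline models is
# the most expensive step of the suite, so tests share one fit (cached in
# this environment for the duration of the run).

.fixtures <- new.env(parent = emptyenv())

# full pipeline models on the default preset world (used by the
# end-to-end acceptance tests and pipeline unit tests)
fixture_pipeline_models <- function() {
  if (is.null(.fixtures$models)) {
    .fixtures$models <- fit_pipeline_models(
      n_train = 12L, seed = 1L,
      tcfg = train_config(epochs = 8L, seed = 1L, patch_size = 64L,
                          patches_per_image = 2L),
      gcn_cfg = gcn_config(seed = 1L, epochs = 100L))
  }
  .fixtures$models
}

# one rendered healthy sample, shared by read-only tests
fixture_sample <- function() {
  if (is.null(.fixtures$sample))
    .fixtures$sample <- render_sample(vessel_tree_spec(seed = 7L))
  .fixtures$sample
}

# small enhanced-image / mask training set at 128 px for segmentation
# smoke tests (not the full acceptance schedule)
fixture_seg_samples <- function(n, seed) {
  lapply(seq_len(n), function(i) {
    s <- render_sample(retavr:::training_spec(seed * 1000L + i))
    list(x = enhance_fundus(s$image), y = s$vessel_mask)
  })
}
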