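# Shared fixtures: small scene specs and a lazily trained tiny detector
# reused by the detector, evaluation and pipeline tests.

test_spec <- function(seed = 1L, ...) {
  scene_spec(96, 96, head_size_range = c(18, 24),
             body_size_range = c(32, 44), seed = seed, ...)
}

clean_spec <- function(seed = 1L) {
  test_spec(seed, noise_sd = 0, occlusion_fraction = 0, brightness_jitter = 0)
}

tiny_anchors <- function() anchor_config(scales = c(20, 34, 48)^2)

.fixture_env <- new.env(parent = emptyenv())

# A quickly trained desk-scale model shared across test files (trained once
# per test run). Good enough to detect reliably on its own training
# distribution; the full learning bar lives in the acceptance tests.
cached_tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    ds <- generate_dataset(test_spec(seed = 42L), 150, c(0.85, 0.15, 0))
    tc <- train_config(learning_rate = 2e-3, max_epochs = 12, patience = 4,
                       lr_decay_after = 8, roi_batch = 8, seed = 42L)
    .fixture_env$model <- suppressMessages(
      sleepose_fit(ds$train, ds$val, config = tc, anchors = tiny_anchors()))
  }
  .fixture_env$model
}

random_boxes <- function(n, size = 50, max_side = 30) {
  x0 <- runif(n, 0, size - 2); y0 <- runif(n, 0, size - 2)
  w <- runif(n, 1, max_side); h <- runif(n, 1, max_side)
  cbind(x0, y0, pmin(x0 + w, size), pmin(y0 + h, size))
}
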