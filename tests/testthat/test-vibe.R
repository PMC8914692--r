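test_that("histogram equalization spreads the intensity CDF", {
  # constant frame: single occupied bin, returned unchanged
  expect_equal(equalize_histogram(matrix(77, 10, 10)), matrix(77, 10, 10))
  # two-level frame keeps its levels at the extremes
  two <- matrix(c(0, 255), 10, 10)
  eq <- equalize_histogram(two)
  expect_setequal(unique(as.vector(eq)), c(0, 255))
  # random frame: output CDF within 1/256 of uniform at every level
  set.seed(1)
  f <- matrix(sample(0:255, 256 * 256, replace = TRUE), 256)
  out <- equalize_histogram(f)
  cdf <- cumsum(tabulate(out + 1, 256)) / length(out)
  expect_lt(max(abs(cdf - (1:256) / 256)), 1 / 256)
  expect_error(equalize_histogram(matrix(numeric(0), 0, 0)), "empty")
})

test_that("background model initialization draws from the 8-neighborhood", {
  # constant frame: every sample equals the constant
  m <- init_background_model(matrix(42, 8, 8), vibe_params(), seed = 1)
  expect_true(all(m$samples == 42))
  # seeded reproducibility
  f <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  m1 <- init_background_model(f, vibe_params(), seed = 9)
  m2 <- init_background_model(f, vibe_params(), seed = 9)
  expect_identical(m1$samples, m2$samples)
  # every sample of pixel p lies in p's (clamped) neighborhood value set
  for (y in c(1, 4, 10)) for (x in c(1, 7, 10)) {
    ys <- max(1, y - 1):min(10, y + 1)
    xs <- max(1, x - 1):min(10, x + 1)
    expect_true(all(m1$samples[y, x, ] %in% f[ys, xs]))
  }
})

test_that("pixel classification follows the match-count rule", {
  p <- vibe_params(n_samples = 3, match_radius = 5, min_matches = 2)
  mk_model <- function(vals, H = 1, W = 1) {
    structure(list(samples = array(rep(vals, each = H * W), c(H, W, 3)),
                   shape = c(H, W), params = p),
              class = "background_model")
  }
  # v equal to all samples -> background
  expect_equal(classify_frame(matrix(10), mk_model(c(10, 10, 10)))[1, 1], 0L)
  # samples {10,12,30}, R=5, v=11: matches {10,12} -> 2 >= 2 -> background
  expect_equal(classify_frame(matrix(11), mk_model(c(10, 12, 30)))[1, 1], 0L)
  # v beyond every sample by more than R -> foreground
  expect_equal(classify_frame(matrix(36), mk_model(c(10, 12, 30)))[1, 1], 1L)
  expect_error(classify_frame(matrix(0, 2, 2), mk_model(c(1, 2, 3))),
               "shape")
})

test_that("classification matches the brute-force rule on random frames", {
  set.seed(7)
  for (rep in 1:25) {
    H <- 8; W <- 8
    N <- sample(2:6, 1)
    p <- vibe_params(n_samples = N, match_radius = runif(1, 1, 40),
                     min_matches = sample(1:N, 1))
    samples <- array(sample(0:255, H * W * N, TRUE), c(H, W, N))
    model <- structure(list(samples = samples, shape = c(H, W), params = p),
                       class = "background_model")
    f <- matrix(sample(0:255, H * W, TRUE), H, W)
    expect_identical(classify_frame(f, model),
                     oracle_vibe_classify(f, samples, p$match_radius,
                                          p$min_matches))
  }
})

test_that("model updates are gated, subsampled and value-correct", {
  p <- vibe_params(n_samples = 4, update_subsampling = 1,
                   neighbor_update = FALSE)
  f0 <- matrix(0, 6, 6)
  model <- init_background_model(f0, p, seed = 1)
  f1 <- matrix(9, 6, 6)
  # all-foreground mask: model unchanged
  m1 <- update_background_model(f1, matrix(1L, 6, 6), model, p, seed = 2)
  expect_identical(m1$samples, model$samples)
  # phi = 1, all background: every pixel now holds its current value
  m2 <- update_background_model(f1, matrix(0L, 6, 6), model, p, seed = 2)
  expect_true(all(apply(m2$samples == 9, c(1, 2), any)))
})

test_that("the empirical update rate recovers 1 in 16", {
  phi <- 16
  p <- vibe_params(n_samples = 4, update_subsampling = phi,
                   neighbor_update = FALSE)
  H <- 100; W <- 100
  n_frames <- 10
  hits <- 0
  for (t in seq_len(n_frames)) {
    model <- structure(list(samples = array(0, c(H, W, 4)), shape = c(H, W),
                            params = p), class = "background_model")
    upd <- update_background_model(matrix(1, H, W), matrix(0L, H, W), model,
                                   p, seed = 1000 + t)
    hits <- hits + sum(apply(upd$samples == 1, c(1, 2), any))
  }
  n <- H * W * n_frames
  rate <- hits / n
  se <- sqrt((1 / phi) * (1 - 1 / phi) / n)
  expect_lt(abs(rate - 1 / phi), 3 * se)
})

test_that("neighbor diffusion absorbs a ghost into the background", {
  sp <- scene_spec(48, 48, noise_sd = 2, seed = 3)
  p <- vibe_params(update_subsampling = 2, neighbor_update = TRUE)
  # object present at model initialization, gone afterwards: its stale model
  # region is a ghost that spatial diffusion must erase
  path <- rbind(c(18, 18), matrix(rep(c(200, 200), 119), ncol = 2,
                                  byrow = TRUE))
  v <- suppressWarnings(generate_motion_video(sp, 120, object_path = path,
                                              object_size = 10))
  model <- init_background_model(v$frames[[1]], p, seed = 1)
  frac <- numeric(119)
  for (t in 2:120) {
    mask <- classify_frame(v$frames[[t]], model, p)
    model <- update_background_model(v$frames[[t]], mask, model, p,
                                     seed = t)
    frac[t - 1] <- mean(mask)
  }
  expect_gt(max(frac[1:10]), 0.02)        # the ghost is visible at first
  expect_lt(mean(tail(frac, 10)), 0.1 * max(frac[1:10]))  # then absorbed
})

test_that("mask clean-up matches the set-based morphology oracle", {
  # stated behaviors
  single <- matrix(0L, 9, 9); single[5, 5] <- 1L
  expect_equal(sum(clean_mask(single, kernel_size = 1, min_area = 4)), 0)
  blob <- matrix(0L, 16, 16); blob[4:13, 4:13] <- 1L
  holed <- blob; holed[8:9, 8:9] <- 0L
  expect_equal(clean_mask(holed, kernel_size = 1, min_area = 1), blob)
  expect_error(clean_mask(matrix(2, 3, 3)), "binary")
  # randomized equivalence on 16x16 grids
  set.seed(11)
  for (rep in 1:30) {
    m <- matrix(rbinom(256, 1, 0.45), 16, 16)
    k <- sample(c(1, 3), 1)
    a <- sample(c(1, 3, 5), 1)
    expect_identical(clean_mask(m, kernel_size = k, min_area = a),
                     oracle_clean_mask(m, k, a),
                     info = sprintf("rep %d k %d area %d", rep, k, a))
  }
})

test_that("motion events bracket a moving object and respect thresholds", {
  sp <- scene_spec(64, 64, noise_sd = 2, seed = 6)
  n <- 60
  # static until frame 19, moves frames 20-40, static afterwards
  xs <- c(rep(5, 19), seq(5, 45, length.out = 21), rep(45, 20))
  v <- generate_motion_video(sp, n, object_path = cbind(round(xs), 20),
                             object_size = 10)
  ev <- detect_motion_events(v$frames, vibe_params(), trigger_fraction = 0.01,
                             min_event_frames = 3)
  expect_equal(nrow(ev), 1)
  expect_lte(ev$start_frame, 22)
  expect_gte(ev$end_frame, 38)
  # static noisy video: no events after the model settles
  v0 <- generate_motion_video(sp, 30, object_size = 10)
  ev0 <- detect_motion_events(v0$frames[11:30], vibe_params(),
                              trigger_fraction = 0.01)
  expect_equal(nrow(ev0), 0)
  # degenerate threshold: one event spanning all frames
  ev_all <- detect_motion_events(v0$frames[1:10], vibe_params(),
                                 trigger_fraction = 0, min_event_frames = 1)
  expect_equal(nrow(ev_all), 1)
  expect_equal(c(ev_all$start_frame, ev_all$end_frame), c(1, 10))
})
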