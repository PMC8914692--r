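test_that("image rescaling follows the shortest/longest side rule", {
  r <- resize_for_network(matrix(0, 600, 800))
  expect_equal(dim(r$image), c(600, 800))
  expect_equal(r$scale, 1)
  r2 <- resize_for_network(matrix(runif(300 * 400), 300, 400))
  expect_equal(dim(r2$image), c(600, 800))
  expect_equal(r2$scale, 2)
  # longest-side cap binds
  r3 <- resize_for_network(matrix(0, 600, 1200))
  expect_equal(dim(r3$image), c(500, 1000))
  expect_equal(r3$scale, 5 / 6)
  # test mode bypasses the rule for small synthetic images
  r4 <- resize_for_network(matrix(0, 96, 96), test_mode = TRUE)
  expect_equal(dim(r4$image), c(96, 96))
  expect_error(resize_for_network(matrix(numeric(0), 0, 0)), "zero-area")
})

test_that("the backbone keeps its stride-16 contract", {
  net <- sleepose_net(net_config(), tiny_anchors(), seed = 2)
  f <- extract_features(matrix(runif(64 * 64, 0, 255), 64, 64), net)
  expect_equal(dim(f)[1:2], c(4, 4))
  f2 <- extract_features(matrix(runif(128 * 128, 0, 255), 128, 128), net)
  expect_equal(dim(f2)[1:2], c(8, 8))
  # non-multiples of the stride round up
  f3 <- extract_features(matrix(0, 100, 70), net)
  expect_equal(dim(f3)[1:2], c(7, 5))
  # deterministic at fixed parameters
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_identical(extract_features(img, net), extract_features(img, net))
  expect_error(extract_features(matrix(0, 8, 8), net), "stride")
})

test_that("the paper-scale backbone is a declared but unavailable contract", {
  expect_error(sleepose_net(net_config(backbone = "paper_resnet50")),
               "pretrained")
})

test_that("region proposals are clipped, sorted and truncated", {
  net <- sleepose_net(net_config(), tiny_anchors(), seed = 3)
  img <- generate_scene(test_spec(seed = 4), "supine", "left")$image
  f <- extract_features(img, net)
  pr <- rpn_propose(f, net, image_size = dim(img), post_nms_top_k = 10)
  expect_lte(nrow(pr$boxes), 10)
  expect_true(all(pr$boxes[, c(1, 3)] >= 0 & pr$boxes[, c(1, 3)] <= 96))
  expect_true(all(pr$boxes[, c(2, 4)] >= 0 & pr$boxes[, c(2, 4)] <= 96))
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))
  expect_true(all(diff(pr$scores) <= 1e-12))
})

test_that("RoI pooling matches the exhaustive window-max oracle", {
  net <- sleepose_net(net_config(), tiny_anchors(), seed = 5)
  set.seed(21)
  # direct kernel check on random maps and boxes
  for (i in 1:100) {
    H <- sample(4:8, 1); W <- sample(4:8, 1); C <- sample(1:3, 1)
    X <- array(runif(H * W * C), c(H, W, C))
    S <- sample(1:3, 1)
    x0 <- runif(1, 0, W - 1); y0 <- runif(1, 0, H - 1)
    box <- c(x0, y0, runif(1, x0 + 0.5, W), runif(1, y0 + 0.5, H))
    got <- sleepose:::cn_roipool_fwd(X, matrix(box, 1), S)$out
    expect_equal(array(got, c(S, S, C)), oracle_roipool(X, box, S),
                 tolerance = 1e-12)
  }
  # a box covering the whole map pooled to 1x1 is the global max
  X <- array(runif(4 * 4 * 2), c(4, 4, 2))
  g <- sleepose:::cn_roipool_fwd(X, matrix(c(0, 0, 4, 4), 1), 1)$out
  expect_equal(as.vector(g), apply(X, 3, max))
  # identical boxes give identical region features
  img <- generate_scene(test_spec(seed = 6), "prone", "right")$image
  f <- extract_features(img, net)
  feats <- roi_extract(f, rbind(c(8, 8, 60, 60), c(8, 8, 60, 60)), net)
  expect_equal(feats[1, ], feats[2, ])
})

test_that("detection and pose heads have the contracted arities", {
  net <- sleepose_net(net_config(), tiny_anchors(), seed = 7)
  img <- generate_scene(test_spec(seed = 8), "left", "supine")$image
  f <- extract_features(img, net)
  feats <- roi_extract(f, rbind(c(10, 10, 40, 40), c(5, 30, 35, 75)), net)
  d <- detect(feats, net)
  expect_equal(dim(d$scores), c(2, 3))
  expect_equal(rowSums(d$scores), c(1, 1))
  expect_equal(dim(d$deltas), c(2, 8))   # 4 coordinates x 2 foreground classes
  ps <- classify_poses(feats, net)
  expect_equal(dim(ps$head), c(2, 4))
  expect_equal(dim(ps$body), c(2, 4))
  expect_equal(rowSums(ps$head), c(1, 1))
  expect_equal(rowSums(ps$body), c(1, 1))
})

test_that("the pose heads are independent sibling branches", {
  net <- sleepose_net(net_config(), tiny_anchors(), seed = 9)
  img <- generate_scene(test_spec(seed = 10), "right", "prone")$image
  f <- extract_features(img, net)
  feats <- roi_extract(f, matrix(c(10, 10, 50, 50), 1), net)
  before <- classify_poses(feats, net)
  net$params$fc_head$W[, 1] <- net$params$fc_head$W[, 1] + 0.5
  after <- classify_poses(feats, net)
  expect_false(isTRUE(all.equal(before$head, after$head)))
  expect_equal(before$body, after$body)
})

test_that("augmentation transforms boxes with the image", {
  s <- generate_scene(clean_spec(seed = 12), "supine", "left")
  # zero angle and zero jitter: exact identity
  id <- augment_sample(s, seed = 1, max_angle = 0,
                       contrast_range = c(1, 1), brightness_range = c(0, 0))
  expect_equal(id$image, s$image)
  expect_equal(id$annotations, s$annotations)
  # seeded reproducibility
  a1 <- augment_sample(s, seed = 33)
  a2 <- augment_sample(s, seed = 33)
  expect_identical(a1$image, a2$image)
  # the augmented box is the AABB of the rotated corners
  set.seed(2)
  for (k in 1:10) {
    seed <- 100 + k
    a <- augment_sample(s, seed = seed, max_angle = 15)
    ang <- sleepose:::with_seed(seed, runif(1, 0, 15)) * pi / 180
    H <- nrow(s$image); W <- ncol(s$image)
    for (i in 1:2) {
      b0 <- as.numeric(s$annotations[i, c("x_min", "y_min", "x_max", "y_max")])
      px <- c(b0[1], b0[3], b0[1], b0[3]) - W / 2
      py <- c(b0[2], b0[2], b0[4], b0[4]) - H / 2
      qx <- cos(ang) * px - sin(ang) * py + W / 2
      qy <- sin(ang) * px + cos(ang) * py + H / 2
      want <- clip_boxes(c(min(qx), min(qy), max(qx), max(qy)), H, W)
      got <- as.numeric(a$annotations[i, c("x_min", "y_min",
                                           "x_max", "y_max")])
      expect_equal(got, unname(want[1, ]), tolerance = 1e-9)
    }
  }
})

test_that("an untrained detector still emits well-formed detections", {
  net <- sleepose_net(net_config(), tiny_anchors(), seed = 11)
  img <- generate_scene(test_spec(seed = 13), "supine", "right")$image
  # an impossible score bar yields an empty result
  expect_equal(nrow(predict_frame(img, net, score_threshold = 1)), 0)
  d <- predict_frame(img, net, score_threshold = 0, max_per_class = 3)
  if (nrow(d) > 0) {
    expect_true(all(d$x_min >= 0 & d$x_max <= 96 & d$x_min < d$x_max))
    expect_true(all(d$y_min >= 0 & d$y_max <= 96 & d$y_min < d$y_max))
    expect_true(all(d$region_class %in% c("head", "upper_body")))
    expect_true(all(d$pose_class %in% pose_classes()))
  }
})

test_that("checkpoints round-trip the whole model", {
  net <- sleepose_net(net_config(), tiny_anchors(), seed = 14)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, net$params)
  expect_identical(back$cfg, net$cfg)
  expect_identical(back$classes$pose, pose_classes())
  expect_error(load_checkpoint(tempfile()), "not found")
})
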