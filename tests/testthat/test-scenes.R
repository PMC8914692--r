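test_that("scene generation is deterministic and validates its spec", {
  sp <- test_spec(seed = 5)
  a <- generate_scene(sp, "supine", "left")
  b <- generate_scene(sp, "supine", "left")
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)
  # a different seed moves the blobs
  c <- generate_scene(sp, "supine", "left", seed = 6)
  expect_false(identical(a$image, c$image))
  expect_error(scene_spec(96, 96, occlusion_fraction = 1.5), "occlusion")
  expect_error(generate_scene(scene_spec(32, 32), "supine", "left"),
               "exceed image bounds")
})

test_that("rendered blobs differ from the background and fill their boxes", {
  s <- generate_scene(clean_spec(seed = 3), "prone", "right")
  bg <- 60
  ann <- s$annotations
  for (i in 1:2) {
    box <- ann[i, c("x_min", "y_min", "x_max", "y_max")]
    patch <- s$image[(box$y_min + 1):box$y_max, (box$x_min + 1):box$x_max]
    expect_gt(mean(patch != bg), 0.5)
    # the box is tight: every edge row/column touches rendered pixels
    expect_true(any(patch[1, ] != bg))
    expect_true(any(patch[nrow(patch), ] != bg))
    expect_true(any(patch[, 1] != bg))
    expect_true(any(patch[, ncol(patch)] != bg))
  }
  # nothing rendered outside the union of the two boxes
  outside <- matrix(TRUE, nrow(s$image), ncol(s$image))
  for (i in 1:2) {
    outside[(ann$y_min[i] + 1):ann$y_max[i],
            (ann$x_min[i] + 1):ann$x_max[i]] <- FALSE
  }
  expect_true(all(s$image[outside] == bg))
})

test_that("every pose renders a distinct marker appearance", {
  imgs <- lapply(pose_classes(), function(p) {
    generate_scene(clean_spec(seed = 9), p, p)$image
  })
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(identical(imgs[[i]], imgs[[j]]))
  }
})

test_that("dataset splits are exact, disjoint and pose-stratified", {
  ds <- generate_dataset(test_spec(seed = 2), 100, c(0.8, 0.1, 0.1))
  expect_length(ds$train, 80)
  expect_length(ds$val, 10)
  expect_length(ds$test, 10)
  key <- function(s) paste(s$seed, s$annotations$x_min[1])
  keys <- unlist(lapply(c(ds$train, ds$val, ds$test), key))
  expect_length(unique(keys), 100)
  for (split in ds) {
    body <- vapply(split, function(s) s$annotations$pose_class[2], "")
    head <- vapply(split, function(s) s$annotations$pose_class[1], "")
    expect_setequal(unique(body), pose_classes())
    expect_setequal(unique(head), pose_classes())
  }
  expect_error(generate_dataset(test_spec(), 3), "at least 4")
})

test_that("pose labels are balanced across a generated dataset", {
  ds <- generate_dataset(test_spec(seed = 8), 200, c(1, 0, 0))
  body <- table(vapply(ds$train, function(s) s$annotations$pose_class[2], ""))
  head <- table(vapply(ds$train, function(s) s$annotations$pose_class[1], ""))
  expect_equal(unname(sort(body)), rep(50, 4), ignore_attr = TRUE)
  expect_equal(unname(sort(head)), rep(50, 4), ignore_attr = TRUE)
})

test_that("a nearest-centroid reader of the marker beats chance", {
  # sanity floor for the detector: the pose cue must be trivially learnable
  n <- 40
  poses <- rep(pose_classes(), each = n / 4)
  correct <- 0
  for (i in seq_len(n)) {
    s <- generate_scene(clean_spec(seed = 100 + i), "supine", poses[i])
    b <- s$annotations[2, ]
    patch <- s$image[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max]
    w <- which(patch == max(patch), arr.ind = TRUE)
    dy <- mean(w[, 1]) - (nrow(patch) + 1) / 2
    dx <- mean(w[, 2]) - (ncol(patch) + 1) / 2
    guess <- if (abs(dy) >= abs(dx)) {
      if (dy < 0) "supine" else "prone"
    } else {
      if (dx < 0) "left" else "right"
    }
    correct <- correct + (guess == poses[i])
  }
  expect_gt(correct / n, 0.5)  # chance is 0.25
})

test_that("motion videos honor the path and report exact masks", {
  sp <- scene_spec(64, 64, noise_sd = 0, seed = 4)
  v <- generate_motion_video(sp, 5, object_size = 10)
  expect_length(v$frames, 5)
  for (m in v$masks) expect_equal(sum(m), 100)
  expect_true(all(vapply(v$masks[-1], identical, TRUE, v$masks[[1]])))
  v2 <- generate_motion_video(sp, 5, object_size = 10)
  expect_identical(v$frames, v2$frames)
  expect_warning(
    generate_motion_video(sp, 3, object_path = cbind(c(0, 30, 60), 10),
                          object_size = 10),
    "clipped")
})

test_that("posture timelines expand episodes into frames exactly", {
  ts <- timeline_spec(data.frame(
    head_pose = c("supine", "left", "right"),
    body_pose = c("supine", "left", "right"),
    duration = c(30, 20, 10)), frame_interval = 2)
  tl <- generate_posture_timeline(ts)
  expect_s3_class(tl, "posture_timeline")
  expect_equal(nrow(tl$episodes), 3)
  expect_equal(nrow(tl$frames), 60 * 60 / 2)
  expect_equal(tl$span_min, 60)
  expect_equal(sum(tl$episodes$end_min - tl$episodes$start_min), 60)
  # single-episode night has no transitions
  one <- generate_posture_timeline(timeline_spec(data.frame(
    head_pose = "supine", body_pose = "supine", duration = 60)))
  expect_equal(nrow(one$episodes), 1)
  expect_equal(compute_shifts_per_hour(one), 0)
  expect_error(timeline_spec(data.frame(head_pose = "supine",
                                        body_pose = "supine", duration = 0)),
               "duration")
})

test_that("annotations and timelines round-trip through their file formats", {
  samples <- list(generate_scene(test_spec(seed = 1), "supine", "prone"),
                  generate_scene(test_spec(seed = 2), "left", "right"))
  f <- tempfile(fileext = ".jsonl")
  write_annotations_jsonl(samples, f)
  lines <- readLines(f)
  expect_length(lines, 2)
  r <- jsonlite::fromJSON(lines[2])
  expect_equal(r$region_class, c("head", "upper_body"))
  expect_equal(r$pose_class, c("left", "right"))
  expect_equal(matrix(r$boxes, ncol = 4),
               unname(as.matrix(samples[[2]]$annotations[
                 , c("x_min", "y_min", "x_max", "y_max")])))

  tl <- generate_posture_timeline(timeline_spec(data.frame(
    head_pose = c("supine", "left"), body_pose = c("supine", "left"),
    duration = c(10, 10)), frame_interval = 5))
  g <- tempfile(fileext = ".csv")
  write_timeline_csv(tl, g)
  tl2 <- read_timeline_csv(g)
  expect_equal(tl2$episodes$body_pose, c("supine", "left"))
  expect_equal(tl2$span_min, 20)
})
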