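eight_hour_timeline <- function() {
  # 480 min: supine 120, left 240, right 120 (body); head follows body
  generate_posture_timeline(timeline_spec(data.frame(
    head_pose = c("supine", "left", "right"),
    body_pose = c("supine", "left", "right"),
    duration = c(120, 240, 120)), frame_interval = 60))
}

test_that("the four indicators match hand-computed values exactly", {
  tl <- eight_hour_timeline()
  expect_identical(compute_shifts_per_hour(tl), 2 / 8)
  expect_identical(compute_long_posture_rate(tl), 3 / 8)
  expect_identical(compute_average_duration(tl), 160)
  expect_identical(compute_sleep_efficiency(tl), 100)
  # 48 minutes of turning in 8 h -> 90%
  ev <- data.frame(start_min = c(100, 300), end_min = c(124, 324))
  expect_identical(compute_sleep_efficiency(tl, ev), 90)
  ind <- compute_indicators(tl, ev)
  expect_identical(ind$shifts_per_hour, 0.25)
  expect_identical(ind$long_postures_per_hour, 0.375)
  expect_identical(ind$average_duration, 160)
  expect_identical(ind$sleep_efficiency, 90)
})

test_that("boundary and degenerate cases follow the stated rules", {
  # an episode of exactly 15 min is excluded by the strict rule
  tl15 <- generate_posture_timeline(timeline_spec(data.frame(
    head_pose = c("supine", "left"), body_pose = c("supine", "left"),
    duration = c(15, 45))))
  expect_identical(compute_long_posture_rate(tl15), 1 / 1)
  # all episodes of 10 min: rate 0
  tl10 <- generate_posture_timeline(timeline_spec(data.frame(
    head_pose = rep("supine", 3), body_pose = c("supine", "left", "supine"),
    duration = rep(10, 3))))
  expect_identical(compute_long_posture_rate(tl10), 0)
  # k alternating episodes over one hour -> k - 1 shifts/hour
  k <- 6
  tlk <- generate_posture_timeline(timeline_spec(data.frame(
    head_pose = rep("supine", k),
    body_pose = rep(c("left", "right"), k / 2),
    duration = rep(60 / k, k))))
  expect_identical(compute_shifts_per_hour(tlk), k - 1)
  # single 60-min episode
  one <- generate_posture_timeline(timeline_spec(data.frame(
    head_pose = "prone", body_pose = "prone", duration = 60)))
  expect_identical(compute_average_duration(one), 60)
  expect_identical(compute_shifts_per_hour(one), 0)
  # motion covering the whole span -> efficiency 0; beyond it -> error
  expect_identical(compute_sleep_efficiency(
    one, data.frame(start_min = 0, end_min = 60)), 0)
  expect_error(compute_sleep_efficiency(
    one, data.frame(start_min = 0, end_min = 90)), "exceeds")
  # sub-threshold motion events are ignored
  expect_identical(compute_sleep_efficiency(
    one, data.frame(start_min = 10, end_min = 10.1), min_event_s = 10), 100)
})

test_that("timeline building smooths flicker and merges episodes", {
  mk <- function(frame, cls, pose, score = 0.9) {
    data.frame(frame = frame, region_class = cls, pose_class = pose,
               region_score = score)
  }
  # constant labels -> single episode
  det <- rbind(mk(1:20, "upper_body", "supine"), mk(1:20, "head", "supine"))
  tl <- build_timeline(det, frame_interval = 1)
  expect_equal(nrow(tl$episodes), 1)
  expect_equal(tl$span_min, 20 / 60)
  # one-frame flicker inside a 5-frame window is smoothed away
  poses <- rep("supine", 21); poses[11] <- "left"
  det2 <- mk(1:21, "upper_body", poses)
  tl2 <- build_timeline(det2, frame_interval = 1, smoothing_window = 5)
  expect_equal(nrow(tl2$episodes), 1)
  expect_equal(tl2$episodes$body_pose, "supine")
  # missing frames inherit the previous label
  det3 <- mk(c(1:5, 10), "upper_body", c(rep("left", 5), "left"))
  tl3 <- suppressMessages(build_timeline(det3, frame_interval = 1,
                                         n_frames = 10))
  expect_equal(nrow(tl3$frames), 10)
  expect_true(all(tl3$frames$body_pose == "left"))
  empty <- data.frame(frame = integer(0), region_class = character(0),
                      pose_class = character(0), region_score = numeric(0))
  expect_error(build_timeline(empty), "zero detected")
})

test_that("a generated timeline round-trips through detections", {
  ts <- timeline_spec(data.frame(
    head_pose = c("supine", "supine", "right"),
    body_pose = c("supine", "left", "right"),
    duration = c(10, 8, 12)), frame_interval = 30)
  tl <- generate_posture_timeline(ts)
  det <- rbind(
    data.frame(frame = seq_len(nrow(tl$frames)), region_class = "head",
               pose_class = tl$frames$head_pose, region_score = 0.9),
    data.frame(frame = seq_len(nrow(tl$frames)), region_class = "upper_body",
               pose_class = tl$frames$body_pose, region_score = 0.9))
  tl2 <- build_timeline(det, frame_interval = 30, smoothing_window = 1)
  expect_equal(tl2$episodes$body_pose, tl$episodes$body_pose)
  expect_equal(tl2$episodes$head_pose, tl$episodes$head_pose)
  expect_equal(tl2$episodes$start_min, tl$episodes$start_min)
  expect_equal(tl2$span_min, tl$span_min)
  # indicators are invariant to a finer frame interval
  ts_fine <- timeline_spec(data.frame(
    head_pose = c("supine", "supine", "right"),
    body_pose = c("supine", "left", "right"),
    duration = c(10, 8, 12)), frame_interval = 5)
  i1 <- compute_indicators(tl)
  i2 <- compute_indicators(generate_posture_timeline(ts_fine))
  expect_equal(i1$shifts_per_hour, i2$shifts_per_hour)
  expect_equal(i1$average_duration, i2$average_duration)
})

test_that("episode durations always sum to the span", {
  set.seed(12)
  for (rep in 1:10) {
    k <- sample(2:8, 1)
    ts <- timeline_spec(data.frame(
      head_pose = sample(pose_classes(), k, TRUE),
      body_pose = sample(pose_classes(), k, TRUE),
      duration = sample(5:40, k, TRUE)), frame_interval = 60)
    tl <- generate_posture_timeline(ts)
    expect_equal(sum(tl$episodes$end_min - tl$episodes$start_min),
                 tl$span_min)
    # shifts/hour times span in hours is an integer transition count
    n <- compute_shifts_per_hour(tl) * tl$span_min / 60
    expect_equal(n, round(n))
  }
})

test_that("the synopsis SVG encodes episodes as proportional arcs", {
  tl <- eight_hour_timeline()
  f <- tempfile(fileext = ".svg")
  render_synopsis(tl, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  svg <- readLines(f)
  arcs <- grep("data-state", svg, value = TRUE)
  expect_length(arcs, 3)
  dur <- as.numeric(sub('.*data-dur-min="([0-9.]+)".*', "\\1", arcs))
  expect_equal(dur, c(120, 240, 120))
  # angular extent proportional to duration: parse the outer-arc endpoints
  ang <- function(line) {
    d <- sub('.*d="M ([^"]+)".*', "\\1", line)
    nums <- as.numeric(strsplit(gsub("[A-Za-z]", "", d), " +")[[1]])
    nums <- nums[!is.na(nums)]
    p1 <- nums[1:2]; p2 <- nums[8:9]   # outer arc start / end
    a <- atan2(p2[2] - 330, p2[1] - 300) - atan2(p1[2] - 330, p1[1] - 300)
    (a * 180 / pi) %% 360
  }
  angles <- vapply(arcs, ang, numeric(1))
  expect_equal(unname(angles), c(120, 240, 120) / (12 * 60) * 360,
               tolerance = 1e-3)
  # no wake time -> no grey arcs
  expect_false(any(grepl('data-state="wake"', svg)))
  # a timeline longer than the diagram is rejected
  too_long <- generate_posture_timeline(timeline_spec(data.frame(
    head_pose = "supine", body_pose = "supine", duration = 13 * 60)))
  expect_error(render_synopsis(too_long, f), "span")
})
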