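# Synthetic bed scenes, motion videos and posture timelines.
#
# Scenes are desk-scale surrogates for overhead bedroom video: one elliptical
# "head" blob adjacent to one rectangular "upper body" blob on a dim
# background. Each blob carries a bright internal bar (a clock-hand marker)
# whose orientation encodes the posture class -- supine points up, prone down,
# left/right sideways -- giving the 4-way pose heads an unambiguous, learnable
# appearance cue without human data. A uniform grey rectangle over the lower
# part of the body stands in for a blanket; global brightness jitter and
# Gaussian pixel noise emulate varying bedroom illumination.

# intensities of the rendered elements (8-bit scale)
.BODY_LEVEL <- 140
.HEAD_LEVEL <- 190
.MARKER_LEVEL <- 235
.OCCLUDER_LEVEL <- 100

# marker direction (unit vector, image coords: y grows downwards)
.POSE_DIR <- list(
  supine = c(0, -1), prone = c(0, 1), left = c(-1, 0), right = c(1, 0)
)

#' Specification of a synthetic bed scene
#'
#' Bundles the geometry and noise parameters of the synthetic scene renderer.
#' Identical specs (including `seed`) always render bit-identical scenes.
#'
#' @param image_height,image_width Frame size in pixels.
#' @param background_level Background intensity on the 0--255 scale.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (intensity units).
#' @param head_size_range Length-2 range of head diameters, pixels.
#' @param body_size_range Length-2 range of body heights, pixels.
#' @param occlusion_fraction Fraction (0--1) of the body box covered from
#'   below by a uniform "blanket" rectangle.
#' @param brightness_jitter Half-width of the uniform global intensity offset
#'   applied per image (intensity units).
#' @param seed Integer seed; generators are pure functions of (spec, seed).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_height = 256, image_width = 256,
                       background_level = 60, noise_sd = 4,
                       head_size_range = c(28, 36),
                       body_size_range = c(48, 72),
                       occlusion_fraction = 0.25,
                       brightness_jitter = 8, seed = 1L) {
  stop_if_not(image_height >= 16 && image_width >= 16,
              "image dimensions must be at least 16 px")
  stop_if_not(all(head_size_range > 0) && all(body_size_range > 0),
              "blob sizes must be positive")
  stop_if_not(occlusion_fraction >= 0 && occlusion_fraction <= 1,
              "occlusion_fraction must lie in [0, 1]")
  stop_if_not(noise_sd >= 0 && brightness_jitter >= 0,
              "noise_sd and brightness_jitter must be nonnegative")
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    background_level = background_level, noise_sd = noise_sd,
    head_size_range = sort(head_size_range),
    body_size_range = sort(body_size_range),
    occlusion_fraction = occlusion_fraction,
    brightness_jitter = brightness_jitter, seed = as.integer(seed)
  ), class = "scene_spec")
}

# Bounding box (0-based, half-open) of a logical pixel mask.
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  c(x_min = min(w[, 2]) - 1, y_min = min(w[, 1]) - 1,
    x_max = max(w[, 2]), y_max = max(w[, 1]))
}

# Bar-shaped marker mask inside a blob: from centre (cx, cy) towards `dir`,
# length `len`, half-width `hw`. X/Y are pixel-coordinate grids.
marker_mask <- function(X, Y, cx, cy, dir, len, hw) {
  tx <- (X - cx) * dir[1] + (Y - cy) * dir[2]        # along-bar coordinate
  px <- (X - cx) * -dir[2] + (Y - cy) * dir[1]       # perpendicular
  tx >= 0 & tx <= len & abs(px) <= hw
}

#' Render one annotated synthetic bed scene
#'
#' @param spec A [scene_spec()].
#' @param pose_head,pose_body Posture class of the head / upper-body blob,
#'   one of `"supine"`, `"prone"`, `"left"`, `"right"`.
#' @param seed Optional seed overriding `spec$seed` (used when drawing many
#'   scenes from one spec).
#' @return An object of class `scene_sample`: list with `image` (numeric
#'   matrix, 0--255) and `annotations` (data frame with one `head` and one
#'   `upper_body` row: `region_class`, `pose_class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`; 0-based half-open pixel boxes that bound the rendered
#'   blobs exactly).
#' @export
generate_scene <- function(spec, pose_head, pose_body, seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  pose_head <- match.arg(pose_head, POSE_CLASSES)
  pose_body <- match.arg(pose_body, POSE_CLASSES)
  H <- spec$image_height; W <- spec$image_width
  # head sits above the body, so both must fit vertically with margins
  need_h <- max(spec$head_size_range) + max(spec$body_size_range) + 6
  need_w <- max(spec$body_size_range) + 4
  if (need_h > H || need_w > W) {
    stop("blob sizes exceed image bounds: need at least ", need_h, "x",
         need_w, " px for the configured size ranges", call. = FALSE)
  }
  with_seed(seed, {
    # geometry ---------------------------------------------------------------
    hb <- round(runif(1, spec$body_size_range[1], spec$body_size_range[2]))
    wb <- round(hb * runif(1, 0.62, 0.80))
    dh <- round(runif(1, spec$head_size_range[1], spec$head_size_range[2]))
    gap <- 2
    tot_h <- dh + gap + hb
    # body top-left such that head above body stays inside the frame
    bx <- round(runif(1, 2, W - wb - 2))
    by <- round(runif(1, dh + gap + 2, H - hb - 2))
    cx_b <- bx + wb / 2; cy_b <- by + hb / 2
    cx_h <- clamp(round(cx_b + runif(1, -0.15, 0.15) * wb), dh / 2 + 1,
                  W - dh / 2 - 1)
    cy_h <- by - gap - dh / 2

    X <- matrix(rep(0:(W - 1), each = H), H, W)   # pixel x (0-based)
    Y <- matrix(rep(0:(H - 1), times = W), H, W)  # pixel y

    body_mask <- X >= bx & X < bx + wb & Y >= by & Y < by + hb
    head_mask <- (X - cx_h)^2 + (Y - cy_h)^2 <= (dh / 2)^2

    img <- matrix(spec$background_level, H, W)
    img[body_mask] <- .BODY_LEVEL
    img[head_mask] <- .HEAD_LEVEL

    rb <- min(wb, hb) / 2
    mb <- marker_mask(X, Y, cx_b, cy_b, .POSE_DIR[[pose_body]],
                      0.9 * rb, max(2, rb / 3)) & body_mask
    mh <- marker_mask(X, Y, cx_h, cy_h, .POSE_DIR[[pose_head]],
                      0.45 * dh, max(2, dh / 6)) & head_mask
    img[mb] <- .MARKER_LEVEL
    img[mh] <- .MARKER_LEVEL

    # blanket: uniform rectangle over the lower fraction of the body box
    if (spec$occlusion_fraction > 0) {
      occ_h <- round(spec$occlusion_fraction * hb)
      if (occ_h > 0) {
        occ <- X >= bx & X < bx + wb & Y >= by + hb - occ_h & Y < by + hb
        img[occ] <- .OCCLUDER_LEVEL
      }
    }

    ann <- rbind(
      data.frame(region_class = "head", pose_class = pose_head,
                 t(mask_bbox(head_mask))),
      data.frame(region_class = "upper_body", pose_class = pose_body,
                 t(mask_bbox(body_mask)))
    )

    if (spec$brightness_jitter > 0) {
      img <- img + runif(1, -spec$brightness_jitter, spec$brightness_jitter)
    }
    if (spec$noise_sd > 0) img <- img + rnorm(H * W, 0, spec$noise_sd)
    img <- round(clamp(img, 0, 255))

    structure(list(image = img, annotations = ann, spec = spec,
                   seed = as.integer(seed)),
              class = "scene_sample")
  })
}

#' Generate a stratified annotated scene dataset
#'
#' Draws `n` scenes with balanced head- and body-pose labels (independently
#' shuffled) and partitions them into disjoint train/validation/test splits,
#' stratified so each split sees all pose classes.
#'
#' @param spec A [scene_spec()]; sample `i` is rendered with seed
#'   `spec$seed + i`.
#' @param n Number of scenes; must be at least the number of pose classes.
#' @param split_fractions Length-3 numeric summing to 1 (train, val, test).
#' @return Object of class `scene_dataset`: list with `train`, `val`, `test`
#'   lists of [generate_scene()] samples.
#' @export
generate_dataset <- function(spec, n, split_fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(spec, "scene_spec"))
  k <- length(POSE_CLASSES)
  if (n < k) stop("n must be at least ", k, " (one scene per pose class)")
  stop_if_not(length(split_fractions) == 3 &&
                abs(sum(split_fractions) - 1) < 1e-8,
              "split_fractions must be three numbers summing to 1")

  with_seed(spec$seed, {
    body <- sample(rep_len(POSE_CLASSES, n))
    head <- sample(rep_len(POSE_CLASSES, n))
  })
  samples <- lapply(seq_len(n), function(i) {
    generate_scene(spec, head[i], body[i], seed = spec$seed + i)
  })

  # exact split sizes via largest-remainder rounding
  raw <- split_fractions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  # interleave by body pose so contiguous split blocks are stratified
  by_class <- split(seq_len(n), match(body, POSE_CLASSES))
  m <- max(lengths(by_class))
  sched <- unlist(lapply(seq_len(m), function(j) {
    vapply(by_class, function(ix) if (j <= length(ix)) ix[j] else NA_integer_,
           integer(1))
  }), use.names = FALSE)
  ord <- sched[!is.na(sched)]
  lab <- rep(c("train", "val", "test"), sizes)
  out <- list(train = samples[ord[lab == "train"]],
              val = samples[ord[lab == "val"]],
              test = samples[ord[lab == "test"]])
  structure(out, class = "scene_dataset", spec = spec)
}

#' Render a synthetic motion video with ground-truth masks
#'
#' A static noisy background plus one bright square object translated along a
#' caller-supplied path; used to exercise background subtraction end to end.
#'
#' @param spec A [scene_spec()] (frame size, background level, noise).
#' @param n_frames Number of frames.
#' @param object_path `NULL` (static object at the frame centre) or an
#'   `n_frames` x 2 matrix of 0-based (x, y) top-left object positions.
#' @param object_size Side length of the square object in pixels.
#' @param object_level Intensity of the object.
#' @return Object of class `motion_video`: list with `frames` (list of
#'   matrices) and `masks` (list of 0/1 matrices marking object pixels).
#' @export
generate_motion_video <- function(spec, n_frames, object_path = NULL,
                                  object_size = NULL, object_level = 200) {
  stopifnot(inherits(spec, "scene_spec"), n_frames >= 1)
  H <- spec$image_height; W <- spec$image_width
  s <- object_size %||% max(8, round(min(H, W) / 8))
  if (is.null(object_path)) {
    object_path <- matrix(rep(c(round(W / 2 - s / 2), round(H / 2 - s / 2)),
                              each = n_frames), ncol = 2)
  }
  object_path <- as.matrix(object_path)
  stop_if_not(nrow(object_path) == n_frames,
              "object_path must have one position per frame")

  clipped <- FALSE
  with_seed(spec$seed, {
    frames <- vector("list", n_frames)
    masks <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      x0 <- object_path[f, 1]; y0 <- object_path[f, 2]
      if (x0 < 0 || y0 < 0 || x0 + s > W || y0 + s > H) clipped <- TRUE
      cx0 <- clamp(x0, 0, W); cy0 <- clamp(y0, 0, H)
      cx1 <- clamp(x0 + s, 0, W); cy1 <- clamp(y0 + s, 0, H)
      img <- matrix(spec$background_level, H, W)
      msk <- matrix(0L, H, W)
      if (cx1 > cx0 && cy1 > cy0) {
        rows <- (cy0 + 1):cy1; cols <- (cx0 + 1):cx1
        img[rows, cols] <- object_level
        msk[rows, cols] <- 1L
      }
      if (spec$noise_sd > 0) img <- img + rnorm(H * W, 0, spec$noise_sd)
      frames[[f]] <- round(clamp(img, 0, 255))
      masks[[f]] <- msk
    }
    if (clipped) warning("object path leaves the frame; object clipped")
    structure(list(frames = frames, masks = masks, spec = spec),
              class = "motion_video")
  })
}

#' Specification of a synthetic posture timeline
#'
#' @param episodes Data frame with columns `head_pose`, `body_pose`,
#'   `duration` (minutes, positive) and optionally `wake_flag` (logical).
#' @param frame_interval Seconds between frame labels.
#' @param seed Integer seed.
#' @return Object of class `timeline_spec`.
#' @export
timeline_spec <- function(episodes, frame_interval = 1, seed = 1L) {
  episodes <- as.data.frame(episodes)
  stop_if_not(all(c("head_pose", "body_pose", "duration") %in%
                    names(episodes)), "episodes need head/body pose + duration")
  if (any(episodes$duration <= 0)) {
    stop("zero or negative episode duration is not allowed", call. = FALSE)
  }
  if (is.null(episodes$wake_flag)) episodes$wake_flag <- FALSE
  structure(list(episodes = episodes,
                 total_duration = sum(episodes$duration),
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "timeline_spec")
}

#' Generate a ground-truth posture timeline
#'
#' Expands an episode list into per-frame posture labels at the configured
#' frame interval. The result has known indicator values computable by hand.
#'
#' @param tspec A [timeline_spec()].
#' @return Object of class `posture_timeline` (see [build_timeline()]):
#'   `episodes` (start/end in minutes, poses, wake flag), `frames`
#'   (`time_s`, `head_pose`, `body_pose`, `wake_flag`), `span_min`.
#' @export
generate_posture_timeline <- function(tspec) {
  stopifnot(inherits(tspec, "timeline_spec"))
  ep <- tspec$episodes
  end <- cumsum(ep$duration)
  start <- c(0, head(end, -1))
  episodes <- data.frame(start_min = start, end_min = end,
                         head_pose = ep$head_pose, body_pose = ep$body_pose,
                         wake_flag = ep$wake_flag)
  nf <- floor(tspec$total_duration * 60 / tspec$frame_interval)
  t_s <- (seq_len(nf) - 1) * tspec$frame_interval
  idx <- findInterval(t_s / 60, start)
  frames <- data.frame(time_s = t_s,
                       head_pose = ep$head_pose[idx],
                       body_pose = ep$body_pose[idx],
                       wake_flag = ep$wake_flag[idx])
  new_posture_timeline(episodes, frames, span_min = tspec$total_duration)
}

#' Write scene annotations as JSON lines
#'
#' One JSON object per scene with fields `image`, `boxes` (0-based,
#' half-open), `region_class` and `pose_class`.
#'
#' @param samples List of `scene_sample` objects.
#' @param path Output file.
#' @param image_names Optional character vector of image identifiers.
#' @return `path`, invisibly.
#' @export
write_annotations_jsonl <- function(samples, path,
                                    image_names = sprintf("scene_%04d.png",
                                                          seq_along(samples))) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(samples)) {
    a <- samples[[i]]$annotations
    rec <- list(image = image_names[i],
                boxes = unname(as.matrix(a[, c("x_min", "y_min",
                                               "x_max", "y_max")])),
                region_class = a$region_class, pose_class = a$pose_class)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write / read a posture timeline as CSV
#'
#' Per-frame rows `timestamp_s, head_pose, body_pose, wake_flag`.
#'
#' @param timeline A `posture_timeline`.
#' @param path CSV file path.
#' @return `path` (write) or a `posture_timeline` (read).
#' @export
write_timeline_csv <- function(timeline, path) {
  fr <- timeline$frames
  out <- data.frame(timestamp_s = fr$time_s, head_pose = fr$head_pose,
                    body_pose = fr$body_pose, wake_flag = fr$wake_flag)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeline_csv
#' @param frame_interval Frame interval in seconds used to rebuild episodes.
#' @export
read_timeline_csv <- function(path, frame_interval = NULL) {
  df <- read.csv(path)
  fi <- frame_interval %||% (if (nrow(df) > 1) diff(df$timestamp_s[1:2]) else 1)
  frames <- data.frame(time_s = df$timestamp_s, head_pose = df$head_pose,
                       body_pose = df$body_pose,
                       wake_flag = as.logical(df$wake_flag))
  episodes_from_frames(frames, fi)
}

#' @export
print.scene_sample <- function(x, ...) {
  cat("<scene_sample>", nrow(x$image), "x", ncol(x$image), "px\n")
  print(x$annotations, row.names = FALSE)
  invisible(x)
}

#' @export
print.scene_dataset <- function(x, ...) {
  cat("<scene_dataset> train:", length(x$train), " val:", length(x$val),
      " test:", length(x$test), "\n")
  invisible(x)
}
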