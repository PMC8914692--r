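# End-to-end orchestration: video in -> motion-gated inference -> posture
# timeline -> indicators + synopsis, plus train/eval entry points. Frame
# input is an in-memory list/array of matrices or a directory of PNG frames.

#' Pipeline configuration
#'
#' @param input Frames: list of matrices, H x W x T array, or a directory of
#'   PNG files (read in name order).
#' @param checkpoint Path to a detector checkpoint (see
#'   [save_checkpoint()]), or a `sleepose_model`/`sleepose_net` object.
#' @param output_dir Directory for report artifacts.
#' @param frame_interval Seconds between frames of the recording.
#' @param vibe A [vibe_params()].
#' @param trigger_fraction,min_event_frames Motion-event thresholds, see
#'   [detect_motion_events()].
#' @param sample_rate_hz Detector sampling rate outside motion events
#'   (default 1 frame per second).
#' @param event_stride Process every `event_stride`-th frame inside motion
#'   events.
#' @param score_threshold,nms_threshold Detector thresholds.
#' @param smoothing_window,wake_threshold_s,min_event_s Analysis parameters,
#'   see [build_timeline()] and [compute_sleep_efficiency()].
#' @param equalize Histogram-equalize frames before background modelling.
#' @param seed Integer seed recorded in every report.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, checkpoint = NULL,
                            output_dir = tempfile("sleepose_run_"),
                            frame_interval = 1, vibe = vibe_params(),
                            trigger_fraction = 0.02, min_event_frames = 2,
                            sample_rate_hz = 1, event_stride = 1,
                            score_threshold = 0.5, nms_threshold = 0.3,
                            smoothing_window = 5, wake_threshold_s = 300,
                            min_event_s = 10, equalize = FALSE, seed = 1L) {
  stop_if_not(frame_interval > 0 && sample_rate_hz > 0 && event_stride >= 1,
              "rates must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are `pipeline_config()`
#'   arguments (a `vibe:` block maps to [vibe_params()]).
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$vibe)) y$vibe <- do.call(vibe_params, y$vibe)
  do.call(pipeline_config, y)
}

#' Load video frames
#'
#' @param input List of matrices, an H x W x T array, or a directory of PNG
#'   frames.
#' @return List of intensity matrices (0--255).
#' @export
load_frames <- function(input) {
  if (is.character(input)) {
    stop_if_not(dir.exists(input), paste("unreadable video input:", input))
    files <- sort(list.files(input, pattern = "\\.png$", full.names = TRUE))
    stop_if_not(length(files) > 0, "no PNG frames found in input directory")
    return(lapply(files, function(f) luminance(png::readPNG(f) * 255)))
  }
  if (is.array(input) && length(dim(input)) == 3) {
    return(lapply(seq_len(dim(input)[3]), function(i) input[, , i]))
  }
  if (is.list(input)) return(lapply(input, luminance))
  stop("input must be a PNG directory, an array, or a list of frames",
       call. = FALSE)
}

resolve_model <- function(checkpoint) {
  if (is.null(checkpoint)) {
    stop("missing checkpoint: configure `checkpoint`", call. = FALSE)
  }
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  if (inherits(checkpoint, "sleepose_model")) return(checkpoint$net)
  if (inherits(checkpoint, "sleepose_net")) return(checkpoint)
  stop("checkpoint is not a sleepose model", call. = FALSE)
}

#' Write detections as JSON lines
#'
#' One object per detection: `frame`, `region_class`, `pose_class`, `box`
#' (half-open pixel coordinates), `region_score`, `pose_score`.
#'
#' @param det Detections data frame with a `frame` column.
#' @param path Output file.
#' @export
write_detections_jsonl <- function(det, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(det))) {
    writeLines(jsonlite::toJSON(list(
      frame = det$frame[i], region_class = det$region_class[i],
      pose_class = det$pose_class[i],
      box = c(det$x_min[i], det$y_min[i], det$x_max[i], det$y_max[i]),
      region_score = det$region_score[i], pose_score = det$pose_score[i]),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Run contact-free sleep monitoring end to end
#'
#' ViBe processes every frame and yields motion events; the detector runs on
#' every `event_stride`-th frame inside events and at `sample_rate_hz`
#' outside them; detections are smoothed into a posture timeline from which
#' the four sleep-quality indicators and the night synopsis are computed.
#' Artifacts written to `output_dir`: `detections.jsonl`, `timeline.csv`,
#' `indicators.json`/`.csv`, `events.csv`, `synopsis.svg`, `run_info.json`.
#'
#' @param config A [pipeline_config()] with `input` and `checkpoint` set.
#' @return Invisible list: `detections`, `events`, `timeline`,
#'   `indicators`, `paths`, `frame_accounting`.
#' @export
run_monitoring <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  net <- resolve_model(config$checkpoint)
  frames <- load_frames(config$input)
  n <- length(frames)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  sp_log("monitoring %d frames (%.1f s interval)", n, config$frame_interval)

  events <- detect_motion_events(
    frames, config$vibe, trigger_fraction = config$trigger_fraction,
    min_event_frames = config$min_event_frames, equalize = config$equalize,
    seed = config$seed)

  # frame scheduling: every frame is processed by the detector (inside an
  # event, at the configured stride), sampled (quiescent sampling), or
  # skipped -- each frame exactly once
  status <- rep("skipped", n)
  step <- max(1L, round(1 / (config$frame_interval * config$sample_rate_hz)))
  status[seq(1, n, by = step)] <- "sampled"
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      idx <- seq(events$start_frame[i], events$end_frame[i],
                 by = config$event_stride)
      status[idx] <- "event"
    }
  }
  run_frames <- which(status != "skipped")

  det <- NULL
  for (f in run_frames) {
    d <- predict_frame(frames[[f]], net,
                       score_threshold = config$score_threshold,
                       nms_threshold = config$nms_threshold)
    if (nrow(d) > 0) det <- rbind(det, cbind(frame = f, d))
  }
  stop_if_not(!is.null(det) && nrow(det) > 0,
              "no detections in the whole recording; cannot build a timeline")

  timeline <- build_timeline(det, events,
                             frame_interval = config$frame_interval,
                             n_frames = n,
                             smoothing_window = config$smoothing_window,
                             wake_threshold_s = config$wake_threshold_s)
  ind <- compute_indicators(timeline, events,
                            frame_interval = config$frame_interval,
                            min_event_s = config$min_event_s)

  paths <- list(
    detections = file.path(config$output_dir, "detections.jsonl"),
    timeline = file.path(config$output_dir, "timeline.csv"),
    indicators_json = file.path(config$output_dir, "indicators.json"),
    indicators_csv = file.path(config$output_dir, "indicators.csv"),
    events = file.path(config$output_dir, "events.csv"),
    synopsis = file.path(config$output_dir, "synopsis.svg"),
    run_info = file.path(config$output_dir, "run_info.json"))
  write_detections_jsonl(det, paths$detections)
  write_timeline_csv(timeline, paths$timeline)
  write_indicators(ind, paths$indicators_json, paths$indicators_csv)
  write_events_csv(events, paths$events)
  render_synopsis(timeline, paths$synopsis,
                  span_hours = max(12, ceiling(timeline$span_min / 60)))
  acct <- table(factor(status, c("event", "sampled", "skipped")))
  jsonlite::write_json(list(
    seed = config$seed, n_frames = n,
    frames_event = unname(acct[["event"]]),
    frames_sampled = unname(acct[["sampled"]]),
    frames_skipped = unname(acct[["skipped"]]),
    detector_invocations = length(run_frames),
    n_events = nrow(events), n_detections = nrow(det)),
    paths$run_info, auto_unbox = TRUE)
  sp_log("frames: %d event, %d sampled, %d skipped; %d detections",
         acct[["event"]], acct[["sampled"]], acct[["skipped"]], nrow(det))
  invisible(list(detections = det, events = events, timeline = timeline,
                 indicators = ind, paths = paths,
                 frame_accounting = as.list(acct)))
}

#' Train a detector from a pipeline configuration
#'
#' @param config List/`pipeline_config` with either `dataset` (a
#'   `scene_dataset` or list with `train`/`val`) or `dataset_dir` (PNG
#'   frames + `annotations.jsonl` written by [write_dataset_dir()]), plus
#'   optional `train` ([train_config()]), `weights` ([loss_weights()]),
#'   `anchors` ([anchor_config()]), and `output_dir`.
#' @return The fitted `sleepose_model`; writes `checkpoint.rds` and
#'   `loss_history.csv` under `output_dir`.
#' @export
run_train <- function(config) {
  ds <- config[["dataset"]] %||%
    (if (!is.null(config$dataset_dir)) read_dataset_dir(config$dataset_dir))
  if (is.null(ds) || length(ds$train) == 0) {
    stop("empty dataset: configure `dataset` or `dataset_dir`",
         call. = FALSE)
  }
  tc <- config$train %||% train_config()
  fit <- sleepose_fit(ds$train, ds$val, config = tc,
                      weights = config$weights %||% loss_weights(),
                      anchors = config$anchors %||% anchor_config())
  out <- config$output_dir %||% tempfile("sleepose_train_")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  save_checkpoint(fit, file.path(out, "checkpoint.rds"))
  write.csv(fit$history, file.path(out, "loss_history.csv"),
            row.names = FALSE)
  sp_log("checkpoint written to %s", file.path(out, "checkpoint.rds"))
  fit
}

#' Evaluate a detector on an annotated test set
#'
#' @param config List with `checkpoint` (path or model), `dataset` (list of
#'   annotated samples) or `dataset_dir`, optional `score_threshold`,
#'   `iou_threshold` and `output_dir`.
#' @return List of class `eval_report`: `mAP` result, pose accuracies,
#'   confusion matrices; written as JSON/CSV when `output_dir` is set.
#' @export
run_eval <- function(config) {
  net <- resolve_model(config$checkpoint)
  samples <- config[["dataset"]] %||%
    (if (!is.null(config$dataset_dir)) read_dataset_dir(config$dataset_dir)$train)
  if (inherits(samples, "scene_dataset")) samples <- samples$test
  stop_if_not(length(samples) > 0, "empty evaluation set")

  det_all <- NULL; gt_all <- NULL
  truth <- list(head = character(0), body = character(0))
  pred <- list(head = character(0), body = character(0))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    bad <- setdiff(s$annotations$pose_class, POSE_CLASSES)
    if (length(bad) > 0) {
      stop("label-set mismatch: unknown pose ", paste(bad, collapse = ","),
           call. = FALSE)
    }
    d <- predict_frame(s$image, net,
                       score_threshold = config$score_threshold %||% 0.5)
    if (nrow(d) > 0) det_all <- rbind(det_all, cbind(image = i, d))
    gt_all <- rbind(gt_all, cbind(image = i, s$annotations))
    mr <- if (nrow(d) > 0) {
      match_detections(d, s$annotations,
                       config$iou_threshold %||% 0.5)
    } else NULL
    if (!is.null(mr) && any(mr$tp)) {
      for (j in which(mr$tp)) {
        g <- mr$matched_gt[j]
        key <- if (s$annotations$region_class[g] == "head") "head" else "body"
        truth[[key]] <- c(truth[[key]], s$annotations$pose_class[g])
        pred[[key]] <- c(pred[[key]], d$pose_class[j])
      }
    }
  }
  if (is.null(det_all)) det_all <- data.frame()
  map <- mean_average_precision(det_all, gt_all,
                                config$iou_threshold %||% 0.5)
  acc <- function(k) {
    if (length(truth[[k]]) == 0) NA_real_
    else classification_accuracy(truth[[k]], pred[[k]])
  }
  pooled_t <- c(truth$head, truth$body); pooled_p <- c(pred$head, pred$body)
  rep_ <- structure(list(
    mAP = map,
    head_pose_accuracy = acc("head"),
    body_pose_accuracy = acc("body"),
    pose_accuracy = if (length(pooled_t) > 0) {
      classification_accuracy(pooled_t, pooled_p)
    } else NA_real_,
    confusion_head = if (length(truth$head) > 0) {
      confusion_matrix(truth$head, pred$head)
    },
    confusion_body = if (length(truth$body) > 0) {
      confusion_matrix(truth$body, pred$body)
    },
    n_images = length(samples)), class = "eval_report")
  out <- config$output_dir
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(
      mAP = map$mAP, ap = as.list(map$ap),
      head_pose_accuracy = rep_$head_pose_accuracy,
      body_pose_accuracy = rep_$body_pose_accuracy,
      pose_accuracy = rep_$pose_accuracy, n_images = rep_$n_images),
      file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(rep_$confusion_head)) {
      write_confusion_csv(rep_$confusion_head,
                          file.path(out, "confusion_head.csv"))
    }
    if (!is.null(rep_$confusion_body)) {
      write_confusion_csv(rep_$confusion_body,
                          file.path(out, "confusion_body.csv"))
    }
  }
  rep_
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Detector evaluation on %d images\n", x$n_images))
  cat(sprintf("  mAP@%.2f: %.4f (", x$mAP$iou_threshold, x$mAP$mAP))
  cat(paste(names(x$mAP$ap), sprintf("%.4f", x$mAP$ap), collapse = ", "),
      ")\n")
  cat(sprintf("  pose accuracy: head %.2f%%, body %.2f%%, overall %.2f%%\n",
              x$head_pose_accuracy, x$body_pose_accuracy, x$pose_accuracy))
  invisible(x)
}

#' Write / read an annotated dataset directory
#'
#' PNG frames plus an `annotations.jsonl` in the documented JSON-lines
#' format.
#'
#' @param samples List of `scene_sample` objects.
#' @param dir Directory path.
#' @return `dir` (write) / a list with `train` = samples (read).
#' @export
write_dataset_dir <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names_ <- sprintf("scene_%04d.png", seq_along(samples))
  for (i in seq_along(samples)) {
    png::writePNG(samples[[i]]$image / 255, file.path(dir, names_[i]))
  }
  write_annotations_jsonl(samples, file.path(dir, "annotations.jsonl"),
                          image_names = names_)
  invisible(dir)
}

#' @rdname write_dataset_dir
#' @export
read_dataset_dir <- function(dir) {
  ann_path <- file.path(dir, "annotations.jsonl")
  stop_if_not(file.exists(ann_path), "annotations.jsonl not found")
  lines <- readLines(ann_path)
  samples <- lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln)
    img <- luminance(png::readPNG(file.path(dir, r$image)) * 255)
    boxes <- matrix(r$boxes, ncol = 4)
    list(image = img,
         annotations = data.frame(region_class = r$region_class,
                                  pose_class = r$pose_class,
                                  x_min = boxes[, 1], y_min = boxes[, 2],
                                  x_max = boxes[, 3], y_max = boxes[, 4]))
  })
  list(train = samples, val = NULL)
}
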