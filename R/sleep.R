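# Posture timeline construction and posture-focused sleep-quality
# indicators: shifts per hour, rate of postures held longer than 15 min,
# average posture duration, and turning-based sleep efficiency; plus a
# circular night-synopsis diagram.

new_posture_timeline <- function(episodes, frames, span_min) {
  structure(list(episodes = episodes, frames = frames, span_min = span_min),
            class = "posture_timeline")
}

#' @export
print.posture_timeline <- function(x, ...) {
  cat("<posture_timeline>", nrow(x$episodes), "episodes over",
      round(x$span_min, 2), "min\n")
  print(x$episodes, row.names = FALSE)
  invisible(x)
}

# merge consecutive frames with identical (head, body, wake) into episodes
episodes_from_frames <- function(frames, frame_interval) {
  key <- paste(frames$head_pose, frames$body_pose, frames$wake_flag)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  episodes <- data.frame(
    start_min = frames$time_s[starts] / 60,
    end_min = (frames$time_s[ends] + frame_interval) / 60,
    head_pose = frames$head_pose[starts],
    body_pose = frames$body_pose[starts],
    wake_flag = frames$wake_flag[starts])
  new_posture_timeline(episodes, frames,
                       span_min = episodes$end_min[nrow(episodes)] -
                         episodes$start_min[1])
}

#' Build a posture timeline from per-frame detections
#'
#' Per-frame head/body pose labels are taken from the top-scoring detection
#' of each region class, majority-smoothed over a centred window (ties keep
#' the previous label), and merged into episodes. Frames without a detection
#' inherit the previous label. Frames inside motion events carry a
#' transition flag; events longer than `wake_threshold_s` mark wake time.
#'
#' @param detections Data frame with columns `frame` (1-based index),
#'   `region_class`, `pose_class`, `region_score`.
#' @param motion_events A [detect_motion_events()] data frame (or `NULL`).
#' @param frame_interval Seconds between consecutive frames.
#' @param n_frames Total number of frames in the recording; defaults to the
#'   largest frame index seen.
#' @param smoothing_window Odd window length (frames) for majority
#'   smoothing.
#' @param wake_threshold_s Motion events longer than this mark wake.
#' @return A `posture_timeline`: `episodes`, per-frame `frames`, `span_min`.
#' @export
build_timeline <- function(detections, motion_events = NULL,
                           frame_interval = 1, n_frames = NULL,
                           smoothing_window = 5, wake_threshold_s = 300) {
  if (is.null(n_frames)) n_frames <- max(detections$frame, 0)
  stop_if_not(n_frames >= 1 && nrow(detections) > 0,
              "timeline has zero detected frames")
  lab <- function(region) {
    v <- rep(NA_character_, n_frames)
    d <- detections[detections$region_class == region, , drop = FALSE]
    if (nrow(d) > 0) {
      d <- d[order(d$frame, -d$region_score), ]
      d <- d[!duplicated(d$frame), ]
      v[d$frame] <- d$pose_class
    }
    v
  }
  head_lab <- lab("head"); body_lab <- lab("upper_body")
  if (all(is.na(head_lab)) && all(is.na(body_lab))) {
    stop("timeline has zero detected frames", call. = FALSE)
  }
  n_missing <- sum(is.na(head_lab) & is.na(body_lab))
  if (n_missing > 0) {
    sp_log("%d of %d frames have no detection; labels carried forward",
           n_missing, n_frames)
  }
  head_lab <- fill_forward(head_lab)
  body_lab <- fill_forward(body_lab)
  head_lab <- majority_smooth(head_lab, smoothing_window)
  body_lab <- majority_smooth(body_lab, smoothing_window)

  in_motion <- wake <- logical(n_frames)
  if (!is.null(motion_events) && nrow(motion_events) > 0) {
    for (i in seq_len(nrow(motion_events))) {
      s <- motion_events$start_frame[i]; e <- motion_events$end_frame[i]
      rng <- max(1, s):min(n_frames, e)
      in_motion[rng] <- TRUE
      if ((e - s + 1) * frame_interval > wake_threshold_s) wake[rng] <- TRUE
    }
  }
  frames <- data.frame(time_s = (seq_len(n_frames) - 1) * frame_interval,
                       head_pose = head_lab, body_pose = body_lab,
                       wake_flag = wake, in_motion = in_motion)
  episodes_from_frames(frames, frame_interval)
}

fill_forward <- function(v) {
  # leading NAs take the first observed label
  first <- which(!is.na(v))[1]
  if (is.na(first)) return(v)
  if (first > 1) v[seq_len(first - 1)] <- v[first]
  for (i in seq_along(v)) if (is.na(v[i])) v[i] <- v[i - 1]
  v
}

majority_smooth <- function(v, window) {
  if (window <= 1 || length(v) < 2 || all(is.na(v))) return(v)
  half <- floor(window / 2)
  out <- v
  prev <- v[1]
  for (i in seq_along(v)) {
    w <- v[max(1, i - half):min(length(v), i + half)]
    w <- w[!is.na(w)]
    if (length(w) == 0) { out[i] <- prev; next }
    tab <- table(w)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (length(top) == 1) top else prev
    prev <- out[i]
  }
  out
}

timeline_span_hours <- function(timeline) {
  span <- timeline$span_min / 60
  if (span <= 0) stop("timeline has zero span", call. = FALSE)
  span
}

#' Posture shifts per hour
#'
#' Number of body-posture transitions between consecutive episodes divided
#' by the monitored span in hours. Head-pose transitions are reported
#' separately by [compute_indicators()] and do not count here.
#'
#' @param timeline A `posture_timeline`.
#' @return Shifts per hour.
#' @export
compute_shifts_per_hour <- function(timeline) {
  ep <- timeline$episodes
  stop_if_not(nrow(ep) > 0, "empty timeline")
  n_shift <- sum(ep$body_pose[-1] != ep$body_pose[-nrow(ep)])
  n_shift / timeline_span_hours(timeline)
}

#' Rate of long-held postures
#'
#' Count of episodes held strictly longer than `min_duration` minutes,
#' divided by the span in hours. An episode of exactly `min_duration`
#' minutes is excluded.
#'
#' @param timeline A `posture_timeline`.
#' @param min_duration Minutes; default 15.
#' @return Long postures per hour.
#' @export
compute_long_posture_rate <- function(timeline, min_duration = 15) {
  ep <- timeline$episodes
  stop_if_not(nrow(ep) > 0, "empty timeline")
  n_long <- sum((ep$end_min - ep$start_min) > min_duration)
  n_long / timeline_span_hours(timeline)
}

#' Average posture duration
#'
#' @param timeline A `posture_timeline`.
#' @return Arithmetic mean of episode durations, minutes.
#' @export
compute_average_duration <- function(timeline) {
  ep <- timeline$episodes
  stop_if_not(nrow(ep) > 0, "empty timeline")
  mean(ep$end_min - ep$start_min)
}

#' Turning-based sleep efficiency
#'
#' Percentage of the monitored span not spent turning. Turning time is the
#' union of motion events at least `min_event_s` seconds long.
#'
#' @param timeline A `posture_timeline`.
#' @param motion_events `NULL`, a [detect_motion_events()] data frame (frame
#'   units; give `frame_interval`), or a data frame with `start_min` /
#'   `end_min` columns.
#' @param frame_interval Seconds per frame for frame-unit events.
#' @param min_event_s Events shorter than this are ignored.
#' @return Efficiency percentage in \[0, 100\].
#' @export
compute_sleep_efficiency <- function(timeline, motion_events = NULL,
                                     frame_interval = 1, min_event_s = 10) {
  span <- timeline$span_min
  stop_if_not(span > 0, "timeline has zero span")
  turning <- 0
  if (!is.null(motion_events) && nrow(motion_events) > 0) {
    dur_min <- if (all(c("start_min", "end_min") %in% names(motion_events))) {
      motion_events$end_min - motion_events$start_min
    } else {
      (motion_events$end_frame - motion_events$start_frame + 1) *
        frame_interval / 60
    }
    turning <- sum(dur_min[dur_min * 60 >= min_event_s])
  }
  if (turning > span) {
    stop("motion time exceeds the timeline span", call. = FALSE)
  }
  100 * (span - turning) / span
}

#' Compute the four sleep-quality indicators
#'
#' Bundles [compute_shifts_per_hour()], [compute_long_posture_rate()],
#' [compute_average_duration()] and [compute_sleep_efficiency()]; head-pose
#' shifts are reported alongside for reference.
#'
#' @inheritParams compute_sleep_efficiency
#' @param min_duration Long-posture threshold, minutes.
#' @return Object of class `sleep_indicators`.
#' @export
compute_indicators <- function(timeline, motion_events = NULL,
                               frame_interval = 1, min_duration = 15,
                               min_event_s = 10) {
  ep <- timeline$episodes
  head_shifts <- sum(ep$head_pose[-1] != ep$head_pose[-nrow(ep)]) /
    timeline_span_hours(timeline)
  structure(list(
    shifts_per_hour = compute_shifts_per_hour(timeline),
    long_postures_per_hour = compute_long_posture_rate(timeline,
                                                       min_duration),
    average_duration = compute_average_duration(timeline),
    sleep_efficiency = compute_sleep_efficiency(timeline, motion_events,
                                                frame_interval, min_event_s),
    head_shifts_per_hour = head_shifts,
    span_min = timeline$span_min), class = "sleep_indicators")
}

#' @export
print.sleep_indicators <- function(x, ...) {
  cat("Sleep-quality indicators over", sprintf("%.1f h", x$span_min / 60),
      "\n")
  cat(sprintf("  Shifts in sleep posture (n/hour)        %.2f\n",
              x$shifts_per_hour))
  cat(sprintf("  Postures longer than 15 min (n/hour)    %.2f\n",
              x$long_postures_per_hour))
  cat(sprintf("  Average duration in a posture (min)     %.2f\n",
              x$average_duration))
  cat(sprintf("  Sleep efficiency (percentage)           %.2f\n",
              x$sleep_efficiency))
  invisible(x)
}

#' Write the indicator report
#'
#' JSON plus a four-row CSV (indicator, value).
#'
#' @param indicators A [compute_indicators()] result.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @export
write_indicators <- function(indicators, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(indicators), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(csv_path)) {
    df <- data.frame(
      indicator = c("Shifts in sleep posture (n/hour)",
                    "Number of postures that last longer than 15 min (n/hour)",
                    "Average duration in a posture (min)",
                    "Sleep efficiency (percentage)"),
      value = c(indicators$shifts_per_hour,
                indicators$long_postures_per_hour,
                indicators$average_duration, indicators$sleep_efficiency))
    write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(indicators)
}

.POSE_COLORS <- c(supine = "#4C72B0", prone = "#DD8452", left = "#55A868",
                  right = "#C44E52", wake = "#B0B0B0")

#' Render the circular night synopsis
#'
#' A clock-like diagram of one night: the ring covers `span_hours` hours,
#' one coloured arc per posture episode (coloured by body posture), grey
#' arcs for wake periods. Written as SVG (with machine-readable
#' `data-start-min` / `data-dur-min` / `data-state` attributes per arc) or
#' PNG.
#'
#' @param timeline A `posture_timeline`.
#' @param path Output file ending in `.svg` or `.png`.
#' @param span_hours Angular span of the full circle; the timeline must fit.
#' @return `path`, invisibly.
#' @export
render_synopsis <- function(timeline, path, span_hours = 12) {
  ep <- timeline$episodes
  stop_if_not(timeline$span_min <= span_hours * 60 + 1e-9,
              "timeline span exceeds the diagram span")
  total_min <- span_hours * 60
  a0 <- -90  # midnight at the top, clockwise
  arcs <- lapply(seq_len(nrow(ep)), function(i) {
    state <- if (isTRUE(ep$wake_flag[i])) "wake" else ep$body_pose[i]
    list(start = a0 + 360 * ep$start_min[i] / total_min,
         end = a0 + 360 * ep$end_min[i] / total_min,
         color = .POSE_COLORS[[state]], state = state,
         start_min = ep$start_min[i],
         dur_min = ep$end_min[i] - ep$start_min[i])
  })
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    svg_synopsis(arcs, path, span_hours)
  } else if (ext == "png") {
    grDevices::png(path, 600, 600)
    on.exit(grDevices::dev.off())
    plot_arcs(arcs, span_hours)
  } else {
    stop("synopsis path must end in .svg or .png", call. = FALSE)
  }
  invisible(path)
}

arc_path_d <- function(cx, cy, r1, r2, a_start, a_end) {
  pt <- function(r, a) c(cx + r * cos(a * pi / 180),
                         cy + r * sin(a * pi / 180))
  large <- as.integer((a_end - a_start) %% 360 > 180)
  p1 <- pt(r2, a_start); p2 <- pt(r2, a_end)
  p3 <- pt(r1, a_end); p4 <- pt(r1, a_start)
  sprintf(paste0("M %.3f %.3f A %.3f %.3f 0 %d 1 %.3f %.3f ",
                 "L %.3f %.3f A %.3f %.3f 0 %d 0 %.3f %.3f Z"),
          p1[1], p1[2], r2, r2, large, p2[1], p2[2],
          p3[1], p3[2], r1, r1, large, p4[1], p4[2])
}

svg_synopsis <- function(arcs, path, span_hours) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    '<svg xmlns="http://www.w3.org/2000/svg" width="600" height="640">',
    '<rect width="600" height="640" fill="white"/>',
    paste0('<text x="300" y="28" text-anchor="middle" font-size="18" ',
           'font-family="sans-serif">Night synopsis (',
           span_hours, ' h)</text>')), con)
  for (a in arcs) {
    # arcs shorter than numerical resolution still get a sliver
    a_end <- max(a$end, a$start + 0.05)
    writeLines(sprintf(
      paste0('<path d="%s" fill="%s" stroke="white" stroke-width="0.5" ',
             'data-state="%s" data-start-min="%.6f" data-dur-min="%.6f"/>'),
      arc_path_d(300, 330, 150, 250, a$start, a_end), a$color, a$state,
      a$start_min, a$dur_min), con)
  }
  leg <- names(.POSE_COLORS)
  for (i in seq_along(leg)) {
    y <- 600 + 0  # single legend row
    x <- 30 + (i - 1) * 115
    writeLines(c(
      sprintf('<rect x="%d" y="%d" width="14" height="14" fill="%s"/>',
              x, y, .POSE_COLORS[[leg[i]]]),
      sprintf(paste0('<text x="%d" y="%d" font-size="13" ',
                     'font-family="sans-serif">%s</text>'),
              x + 20, y + 12, leg[i])), con)
  }
  writeLines("</svg>", con)
}

plot_arcs <- function(arcs, span_hours) {
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Night synopsis (%g h)", span_hours))
  for (a in arcs) {
    th <- seq(a$start, max(a$end, a$start + 0.05), length.out = 64) * pi / 180
    # y negated: plot coordinates grow upwards
    graphics::polygon(c(cos(th), rev(0.6 * cos(th))),
                      -c(sin(th), rev(0.6 * sin(th))),
                      col = a$color, border = "white")
  }
  graphics::legend("center", legend = names(.POSE_COLORS),
                   fill = unname(.POSE_COLORS), bty = "n", cex = 0.8)
}
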