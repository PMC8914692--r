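# ViBe background subtraction.
#
# Each pixel x keeps a set M(x) = {v1, ..., vN} of past intensity values.
# A pixel of a new frame is background when at least #min stored samples lie
# within intensity radius R of its current value; background pixels update
# their sample set by random replacement with probability 1/phi (the paper's
# "1 chance in 16"), optionally diffusing the value into a random
# 8-neighbour's set. Conservative updating lets slow-moving sleepers stay in
# the foreground while lighting drift is absorbed.

#' ViBe parameters
#'
#' @param n_samples Number of background samples per pixel (N).
#' @param match_radius Intensity radius R of the match test.
#' @param min_matches Minimum number of matching samples (#min) for a pixel
#'   to be classified as background.
#' @param update_subsampling Subsampling factor phi: a background pixel
#'   updates its sample set with probability 1/phi.
#' @param neighbor_update If `TRUE`, an updating pixel also writes its value
#'   into one sample of a uniform-random 8-neighbour (spatial diffusion).
#' @return Object of class `vibe_params`.
#' @export
vibe_params <- function(n_samples = 20, match_radius = 20, min_matches = 2,
                        update_subsampling = 16, neighbor_update = TRUE) {
  stop_if_not(n_samples >= min_matches && min_matches >= 1,
              "need n_samples >= min_matches >= 1")
  stop_if_not(match_radius > 0, "match_radius must be positive")
  stop_if_not(update_subsampling >= 1, "update_subsampling must be >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 match_radius = match_radius,
                 min_matches = as.integer(min_matches),
                 update_subsampling = update_subsampling,
                 neighbor_update = isTRUE(neighbor_update)),
            class = "vibe_params")
}

#' Convert an RGB frame to single-channel luminance
#'
#' @param frame Matrix (returned unchanged) or H x W x 3 array.
#' @return Numeric matrix.
#' @export
luminance <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3 && dim(frame)[3] == 3) {
    return(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
  }
  if (length(dim(frame)) == 3 && dim(frame)[3] == 1) return(frame[, , 1])
  stop("frame must be a matrix or an H x W x 3 array", call. = FALSE)
}

#' Histogram equalization
#'
#' Spreads the cumulative intensity histogram towards uniform over 0--255,
#' compensating varying bedroom lighting before background modelling.
#' Intensities are treated as 8-bit levels; the lowest occupied level maps to
#' 0 and the highest to 255. A single-level (constant) frame is returned
#' unchanged.
#'
#' @param frame Single-channel intensity matrix (0--255).
#' @return Equalized matrix of the same shape.
#' @export
equalize_histogram <- function(frame) {
  frame <- luminance(frame)
  if (length(frame) == 0) stop("empty frame", call. = FALSE)
  v <- as.integer(clamp(round(frame), 0, 255))
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(v)
  occupied <- which(counts > 0)
  if (length(occupied) <= 1) return(frame)
  cdf_min <- cdf[occupied[1]]
  lut <- round(255 * (cdf - cdf_min) / (1 - cdf_min))
  matrix(lut[v + 1L], nrow(frame), ncol(frame))
}

#' Initialize the ViBe background model
#'
#' Fills each pixel's N samples with values drawn uniformly from its
#' 8-neighbourhood in the first frame (border neighbourhoods are clamped to
#' the frame).
#'
#' @param first_frame Single-channel intensity matrix.
#' @param params A [vibe_params()].
#' @param seed Integer seed.
#' @return Object of class `background_model`: `samples` array
#'   (H x W x N) and `shape`.
#' @export
init_background_model <- function(first_frame, params = vibe_params(),
                                  seed = 1L) {
  first_frame <- luminance(first_frame)
  if (length(first_frame) == 0) stop("empty frame", call. = FALSE)
  H <- nrow(first_frame); W <- ncol(first_frame); N <- params$n_samples
  offs <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  rows <- matrix(rep(seq_len(H), W), H, W)
  cols <- matrix(rep(seq_len(W), each = H), H, W)
  with_seed(seed, {
    samples <- array(0, dim = c(H, W, N))
    for (n in seq_len(N)) {
      k <- sample.int(8L, H * W, replace = TRUE)
      ny <- clamp(rows + offs[k, 1], 1, H)
      nx <- clamp(cols + offs[k, 2], 1, W)
      samples[, , n] <- first_frame[cbind(as.vector(ny), as.vector(nx))]
    }
    structure(list(samples = samples, shape = c(H, W), params = params),
              class = "background_model")
  })
}

#' Classify a frame against the background model
#'
#' A pixel is background when at least `min_matches` of its stored samples
#' lie within `match_radius` of its current value (scalar Euclidean
#' distance); otherwise it is foreground.
#'
#' @param frame Single-channel intensity matrix.
#' @param model A [init_background_model()] result.
#' @param params A [vibe_params()]; defaults to the model's.
#' @return Binary motion mask (matrix of 0/1, 1 = moving foreground).
#' @export
classify_frame <- function(frame, model, params = model$params) {
  frame <- luminance(frame)
  if (!all(dim(frame) == model$shape)) {
    stop("frame shape does not match the background model", call. = FALSE)
  }
  counts <- matrix(0L, nrow(frame), ncol(frame))
  for (n in seq_len(params$n_samples)) {
    counts <- counts + (abs(model$samples[, , n] - frame) < params$match_radius)
  }
  mask <- matrix(0L, nrow(frame), ncol(frame))
  mask[counts < params$min_matches] <- 1L
  mask
}

#' Update the background model by random replacement
#'
#' Only background-classified pixels are eligible; each updates one
#' uniform-random sample of its set with its current value with probability
#' `1/update_subsampling`, and (if `neighbor_update`) the same event also
#' writes the value into one sample of a uniform-random 8-neighbour.
#'
#' @inheritParams classify_frame
#' @param mask Binary motion mask from [classify_frame()].
#' @param seed Integer seed.
#' @return The updated `background_model`.
#' @export
update_background_model <- function(frame, mask, model,
                                    params = model$params, seed = 1L) {
  frame <- luminance(frame)
  stop_if_not(all(dim(frame) == model$shape) && all(dim(mask) == model$shape),
              "frame/mask shape does not match the background model")
  H <- model$shape[1]; W <- model$shape[2]; N <- params$n_samples
  bg <- which(mask == 0)
  if (length(bg) == 0) return(model)
  with_seed(seed, {
    sel <- bg[runif(length(bg)) < 1 / params$update_subsampling]
    if (length(sel) > 0) {
      slot <- sample.int(N, length(sel), replace = TRUE)
      model$samples[sel + (slot - 1L) * H * W] <- frame[sel]
      if (params$neighbor_update) {
        offs <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
                      dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
        k <- sample.int(8L, length(sel), replace = TRUE)
        y <- clamp((sel - 1L) %% H + 1L + offs[k, 1], 1, H)
        x <- clamp((sel - 1L) %/% H + 1L + offs[k, 2], 1, W)
        nidx <- y + (x - 1L) * H
        slot2 <- sample.int(N, length(sel), replace = TRUE)
        model$samples[nidx + (slot2 - 1L) * H * W] <- frame[sel]
      }
    }
    model
  })
}

#' Morphological clean-up of a motion mask
#'
#' Opening (erosion then dilation) with a square structuring element, removal
#' of connected components smaller than `min_area`, and interior hole
#' filling.
#'
#' @param mask Binary matrix (0/1).
#' @param kernel_size Side of the square structuring element (odd).
#' @param min_area Minimum component area in pixels^2 to keep;
#'   default 0.1% of the frame area.
#' @return Cleaned binary mask.
#' @export
clean_mask <- function(mask, kernel_size = 3, min_area = NULL) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  min_area <- min_area %||% (0.001 * length(mask))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  kern <- EBImage::makeBrush(as.integer(kernel_size), shape = "box")
  m <- EBImage::dilate(EBImage::erode(m, kern), kern)
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < min_area)
    if (length(drop) > 0) m[lab %in% drop] <- 0
  }
  m <- EBImage::fillHull(m)
  matrix(as.integer(m > 0), nrow(mask), ncol(mask))
}

#' Detect motion events in a frame sequence
#'
#' Runs the full ViBe chain (optional histogram equalization, initialization
#' from the first frame, per-frame classification, model update, mask
#' clean-up) and groups frames whose cleaned foreground fraction reaches
#' `trigger_fraction` into motion events.
#'
#' @param frames List of single-channel matrices (or an H x W x T array).
#' @param params A [vibe_params()].
#' @param trigger_fraction Foreground fraction (0--1) that triggers an event.
#' @param min_event_frames Events shorter than this are dropped.
#' @param kernel_size,min_area Passed to [clean_mask()].
#' @param equalize Apply [equalize_histogram()] to every frame first.
#' @param seed Integer seed for model initialization and updates.
#' @return Data frame of class `motion_events` with columns `start_frame`,
#'   `end_frame`, `peak_fraction` (1-based inclusive frame indices).
#'   Attribute `foreground_fraction` holds the per-frame cleaned fraction.
#' @export
detect_motion_events <- function(frames, params = vibe_params(),
                                 trigger_fraction = 0.02,
                                 min_event_frames = 2, kernel_size = 3,
                                 min_area = NULL, equalize = FALSE,
                                 seed = 1L) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  stop_if_not(length(frames) >= 2, "need at least 2 frames")
  prep <- function(f) if (equalize) equalize_histogram(f) else luminance(f)
  model <- init_background_model(prep(frames[[1]]), params, seed = seed)
  frac <- numeric(length(frames))
  for (t in seq_along(frames)) {
    f <- prep(frames[[t]])
    if (t == 1) next
    mask <- classify_frame(f, model, params)
    model <- update_background_model(f, mask, model, params, seed = seed + t)
    cleaned <- clean_mask(mask, kernel_size, min_area)
    frac[t] <- mean(cleaned)
  }
  hot <- frac >= trigger_fraction
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_event_frames
  ev <- data.frame(start_frame = starts[keep], end_frame = ends[keep],
                   peak_fraction = vapply(which(keep), function(i) {
                     max(frac[starts[i]:ends[i]])
                   }, numeric(1)))
  structure(ev, class = c("motion_events", "data.frame"),
            foreground_fraction = frac)
}

#' Write motion events as CSV
#'
#' @param events A `motion_events` data frame.
#' @param path Output file.
#' @export
write_events_csv <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
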