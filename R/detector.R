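# Public surface of the two-stage multi-task detector: a shared backbone
# feeds (a) an anchor-based region-proposal stage and (b) a region head with
# three sibling outputs -- region class + box regression, head pose, body
# pose. Proposal boxes are treated as constants in the backward pass
# (approximate joint training, as in the original two-stage framework).

#' Create an untrained detector network
#'
#' @param cfg A [net_config()].
#' @param anchors An [anchor_config()]; its scales should match the image
#'   scale being processed (the full-scale defaults for real video, smaller
#'   scales for desk-scale synthetic scenes).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `sleepose_net`.
#' @export
sleepose_net <- function(cfg = net_config(), anchors = anchor_config(),
                         seed = 1L) {
  structure(list(params = init_net_params(cfg, seed), cfg = cfg,
                 anchor_cfg = anchors,
                 classes = list(region = REGION_CLASSES, pose = POSE_CLASSES)),
            class = "sleepose_net")
}

#' @export
print.sleepose_net <- function(x, ...) {
  np <- sum(vapply(x$params, function(l) length(l$W) + length(l$b), numeric(1)))
  cat("<sleepose_net>", x$cfg$backbone, "backbone, stride", x$cfg$stride,
      "-", format(np, big.mark = ","), "parameters\n")
  invisible(x)
}

#' Rescale an image for the detector
#'
#' Preserves aspect ratio; the shortest side is scaled to `target_short`
#' (default 600 px) unless that would push the longest side past
#' `max_long` (default 1000 px), in which case the longest side is set to
#' `max_long`. Desk-scale synthetic images bypass the rule with
#' `test_mode = TRUE`.
#'
#' @param image Intensity matrix.
#' @param target_short,max_long Size rule in pixels.
#' @param test_mode If `TRUE` the image is returned unscaled.
#' @return List with `image` and `scale` (multiply boxes on the resized
#'   image by `1/scale` to map back).
#' @export
resize_for_network <- function(image, target_short = 600, max_long = 1000,
                               test_mode = FALSE) {
  image <- luminance(image)
  if (length(image) == 0 || any(dim(image) == 0)) {
    stop("zero-area image", call. = FALSE)
  }
  if (test_mode) return(list(image = image, scale = 1))
  H <- nrow(image); W <- ncol(image)
  s <- target_short / min(H, W)
  if (s * max(H, W) > max_long) s <- max_long / max(H, W)
  if (abs(s - 1) < 1e-12) return(list(image = image, scale = 1))
  list(image = resample_image(image, round(H * s), round(W * s)), scale = s)
}

# bilinear resampling to (H2, W2); pixel centres at (x + 0.5, y + 0.5)
resample_image <- function(img, H2, W2) {
  H <- nrow(img); W <- ncol(img)
  xs <- ((seq_len(W2) - 0.5) * W / W2) - 0.5
  ys <- ((seq_len(H2) - 0.5) * H / H2) - 0.5
  bilinear_grid(img, matrix(rep(xs, each = H2), H2, W2),
                matrix(rep(ys, times = W2), H2, W2))
}

bilinear_grid <- function(img, X, Y, fill = NULL) {
  H <- nrow(img); W <- ncol(img)
  fill <- fill %||% stats::median(img)
  x0 <- floor(X); y0 <- floor(Y)
  fx <- X - x0; fy <- Y - y0
  px <- function(yy, xx) {
    inside <- xx >= 0 & xx <= W - 1 & yy >= 0 & yy <= H - 1
    v <- matrix(fill, nrow(X), ncol(X))
    v[inside] <- img[cbind(yy[inside] + 1, xx[inside] + 1)]
    v
  }
  v00 <- px(y0, x0); v01 <- px(y0, x0 + 1)
  v10 <- px(y0 + 1, x0); v11 <- px(y0 + 1, x0 + 1)
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  matrix(out, nrow(X), ncol(X))
}

#' Extract backbone features
#'
#' Runs the convolutional backbone; the image is zero-padded on the
#' bottom/right to a multiple of the stride, so the feature map has spatial
#' size `ceiling(input / stride)`.
#'
#' @param image Intensity matrix (0--255).
#' @param net A [sleepose_net()].
#' @return Feature array dim `c(fh, fw, C)` with attribute `image_size`.
#' @export
extract_features <- function(image, net) {
  image <- luminance(image)
  if (min(dim(image)) < net$cfg$stride) {
    stop("image smaller than the network stride (", net$cfg$stride, " px)",
         call. = FALSE)
  }
  x <- pad_to_stride(as_cube(image / 255), net$cfg$stride)
  f <- backbone_forward(x, net$params)$feat
  attr(f, "image_size") <- dim(image)
  f
}

# decode + clip + filter + NMS the proposal stage outputs
propose_boxes <- function(unpacked, anchors, image_size, pre_nms_top_k,
                          post_nms_top_k, nms_threshold, min_size) {
  ord <- order(-unpacked$p_fg)
  take <- ord[seq_len(min(pre_nms_top_k, length(ord)))]
  boxes <- decode_box_deltas(unpacked$deltas[take, , drop = FALSE],
                             anchors[take, , drop = FALSE])
  boxes <- clip_boxes(boxes, image_size[1], image_size[2])
  scores <- unpacked$p_fg[take]
  ok <- (boxes[, 3] - boxes[, 1]) >= min_size &
    (boxes[, 4] - boxes[, 2]) >= min_size
  boxes <- boxes[ok, , drop = FALSE]; scores <- scores[ok]
  if (nrow(boxes) == 0) return(list(boxes = boxes, scores = scores))
  keep <- nms(boxes, scores, nms_threshold)
  keep <- keep[seq_len(min(post_nms_top_k, length(keep)))]
  list(boxes = boxes[keep, , drop = FALSE], scores = scores[keep])
}

#' Propose candidate regions
#'
#' Scores every anchor for objectness, decodes its box offsets, clips to the
#' image, keeps the top-k by score and prunes overlaps with NMS.
#'
#' @param features Output of [extract_features()].
#' @param net A [sleepose_net()].
#' @param image_size `c(height, width)`; defaults to the feature attribute.
#' @param pre_nms_top_k,post_nms_top_k Truncation before/after NMS.
#' @param nms_threshold Proposal NMS overlap threshold.
#' @param min_size Minimum proposal side in pixels.
#' @return List with `boxes` (matrix, descending score) and `scores`.
#' @export
rpn_propose <- function(features, net, image_size = NULL,
                        pre_nms_top_k = 96, post_nms_top_k = 16,
                        nms_threshold = 0.7, min_size = 2) {
  image_size <- image_size %||% attr(features, "image_size")
  out <- rpn_forward(features, net$params)
  un <- rpn_unpack(out$cls, out$box, net$cfg$n_anchor_shapes)
  anchors <- generate_anchors(dim(features)[1], dim(features)[2],
                              net$anchor_cfg)
  propose_boxes(un, anchors, image_size, pre_nms_top_k, post_nms_top_k,
                nms_threshold, min_size)
}

#' Extract fixed-size region features
#'
#' Max-pools each box's feature-map window to an `output_size` grid, passes
#' it through the final residual block and global average pooling.
#'
#' @param features Output of [extract_features()].
#' @param boxes Box matrix in image coordinates.
#' @param net A [sleepose_net()].
#' @param output_size Pooled grid side; defaults to the network's RoI size.
#' @return Numeric matrix, one pooled feature vector per box.
#' @export
roi_extract <- function(features, boxes, net, output_size = NULL) {
  cfg <- net$cfg
  if (!is.null(output_size)) cfg$roi_size <- as.integer(output_size)
  fw <- roi_head_forward(features, boxes, net$params, cfg)
  fw$F
}

#' Region classification and box refinement head
#'
#' @param region_features Matrix from [roi_extract()].
#' @param net A [sleepose_net()].
#' @return List: `scores` (n x 3 softmax over head/upper_body/background)
#'   and `deltas` (n x 8; four refinement coordinates per non-background
#'   class, head then upper body).
#' @export
detect <- function(region_features, net) {
  p <- net$params
  logits <- sweep(region_features %*% p$fc_det$W, 2, p$fc_det$b, "+")
  deltas <- sweep(region_features %*% p$fc_box$W, 2, p$fc_box$b, "+")
  scores <- softmax_rows(logits)
  colnames(scores) <- REGION_CLASSES
  list(scores = scores, deltas = deltas)
}

#' Pose classification heads
#'
#' Two independent sibling heads over the four posture classes, one for the
#' head region and one for the upper body.
#'
#' @inheritParams detect
#' @return List of two n x 4 softmax score matrices, `head` and `body`.
#' @export
classify_poses <- function(region_features, net) {
  p <- net$params
  h <- softmax_rows(sweep(region_features %*% p$fc_head$W, 2,
                          p$fc_head$b, "+"))
  b <- softmax_rows(sweep(region_features %*% p$fc_body$W, 2,
                          p$fc_body$b, "+"))
  colnames(h) <- POSE_CLASSES; colnames(b) <- POSE_CLASSES
  list(head = h, body = b)
}

#' Detect head and upper body and classify their poses in one frame
#'
#' Full forward pass: backbone features, region proposals, region head.
#' Background detections are discarded, the surviving boxes are refined with
#' their class's regression output, per-class NMS is applied, and each
#' detection reads its pose from the pose head matching its region class.
#'
#' @param image Intensity matrix.
#' @param net A trained [sleepose_net()] (or a fitted `sleepose_model`).
#' @param score_threshold Minimum region score.
#' @param nms_threshold Final per-class NMS threshold.
#' @param max_per_class Keep at most this many detections per region class.
#' @return Data frame of detections: `region_class`, `pose_class`,
#'   `region_score`, `pose_score`, `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
predict_frame <- function(image, net, score_threshold = 0.5,
                          nms_threshold = 0.3, max_per_class = 1) {
  if (inherits(net, "sleepose_model")) net <- net$net
  image <- luminance(image)
  feat <- extract_features(image, net)
  props <- rpn_propose(feat, net, image_size = dim(image))
  empty <- data.frame(region_class = character(), pose_class = character(),
                      region_score = numeric(), pose_score = numeric(),
                      x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric())
  if (nrow(props$boxes) == 0) return(empty)
  fw <- roi_head_forward(feat, props$boxes, net$params, net$cfg)
  scores <- softmax_rows(fw$det_logits)
  poses <- list(head = softmax_rows(fw$head_logits),
                body = softmax_rows(fw$body_logits))
  cls <- max.col(scores, ties.method = "first")
  out <- empty
  for (ci in 1:2) {   # head, upper_body
    sel <- which(cls == ci & scores[, ci] >= score_threshold)
    if (length(sel) == 0) next
    refined <- decode_box_deltas(
      fw$box_out[sel, 4 * (ci - 1) + 1:4, drop = FALSE],
      props$boxes[sel, , drop = FALSE])
    refined <- clip_boxes(refined, nrow(image), ncol(image))
    ok <- refined[, 3] > refined[, 1] & refined[, 4] > refined[, 2]
    sel <- sel[ok]; refined <- refined[ok, , drop = FALSE]
    if (length(sel) == 0) next
    keep <- nms(refined, scores[sel, ci], nms_threshold)
    keep <- keep[seq_len(min(max_per_class, length(keep)))]
    pm <- if (ci == 1) poses$head else poses$body
    pj <- max.col(pm[sel[keep], , drop = FALSE], ties.method = "first")
    out <- rbind(out, data.frame(
      region_class = REGION_CLASSES[ci],
      pose_class = POSE_CLASSES[pj],
      region_score = scores[sel[keep], ci],
      pose_score = pm[cbind(keep, pj)],
      x_min = refined[keep, 1], y_min = refined[keep, 2],
      x_max = refined[keep, 3], y_max = refined[keep, 4]))
  }
  rownames(out) <- NULL
  out
}

#' Augment an annotated sample
#'
#' Rotates the image by an angle drawn uniformly from \[0, `max_angle`\]
#' degrees about the image centre and jitters contrast and brightness.
#' Bounding boxes become the axis-aligned box of their rotated corners,
#' clipped to the frame; pose and region labels are unchanged.
#'
#' @param sample A `scene_sample` (or any list with `image` and
#'   `annotations`).
#' @param seed Integer seed.
#' @param max_angle Maximum rotation in degrees.
#' @param contrast_range,brightness_range Jitter ranges (multiplicative
#'   about intensity 128; additive).
#' @return An augmented sample, or `NULL` (with a warning) when a box
#'   rotates fully out of the frame.
#' @export
augment_sample <- function(sample, seed = 1L, max_angle = 15,
                           contrast_range = c(0.9, 1.1),
                           brightness_range = c(-10, 10)) {
  img <- sample$image; ann <- sample$annotations
  H <- nrow(img); W <- ncol(img)
  with_seed(seed, {
    ang <- runif(1, 0, max_angle) * pi / 180
    ctr <- runif(1, contrast_range[1], contrast_range[2])
    brt <- runif(1, brightness_range[1], brightness_range[2])
    if (ang != 0) {
      cx <- W / 2; cy <- H / 2
      co <- cos(ang); si <- sin(ang)
      # inverse map for resampling
      xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cx
      ys <- matrix(rep(seq_len(H) - 0.5, times = W), H, W) - cy
      Xs <- co * xs + si * ys + cx - 0.5
      Ys <- -si * xs + co * ys + cy - 0.5
      img <- bilinear_grid(img, Xs, Ys)
      # forward-rotate box corners
      for (i in seq_len(nrow(ann))) {
        px <- c(ann$x_min[i], ann$x_max[i], ann$x_min[i], ann$x_max[i]) - cx
        py <- c(ann$y_min[i], ann$y_min[i], ann$y_max[i], ann$y_max[i]) - cy
        qx <- co * px - si * py + cx
        qy <- si * px + co * py + cy
        b <- clip_boxes(c(min(qx), min(qy), max(qx), max(qy)), H, W)
        if (b[1, 3] <= b[1, 1] || b[1, 4] <= b[1, 2]) {
          warning("augmented box fully outside the frame; sample rejected")
          return(NULL)
        }
        ann[i, c("x_min", "y_min", "x_max", "y_max")] <- b
      }
    }
    img <- clamp((img - 128) * ctr + 128 + brt, 0, 255)
    out <- sample
    out$image <- img; out$annotations <- ann
    out
  })
}

#' Save / load a detector checkpoint
#'
#' A checkpoint is self-describing: parameters, architecture and anchor
#' configuration, class-name ordering, and (for fitted models) the training
#' history and configuration.
#'
#' @param model A `sleepose_net` or fitted `sleepose_model`.
#' @param path File path.
#' @return `path` (save) / the restored object (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "sleepose_checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  x <- readRDS(path)
  stop_if_not(identical(x$format, "sleepose_checkpoint"),
              "not a sleepose checkpoint")
  x$model
}
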