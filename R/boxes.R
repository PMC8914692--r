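# Box arithmetic for the two-stage detector. All boxes are numeric
# (x_min, y_min, x_max, y_max) in 0-based, half-open pixel coordinates, so
# width = x_max - x_min. Matrices hold one box per row.

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = TRUE)
  b <- as.matrix(b)
  stopifnot(ncol(b) == 4)
  b
}

check_boxes <- function(b) {
  b <- as_box_matrix(b)
  if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2])) {
    stop("malformed box: need x_min < x_max and y_min < y_max", call. = FALSE)
  }
  b
}

#' Intersection over union of two boxes
#'
#' @param boxA,boxB Length-4 vectors `(x_min, y_min, x_max, y_max)`,
#'   half-open pixel coordinates.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(boxA, boxB) {
  iou_matrix(matrix(boxA, 1), matrix(boxB, 1))[1, 1]
}

#' Pairwise IoU matrix
#'
#' @param A,B Box matrices (rows are boxes).
#' @return `nrow(A)` x `nrow(B)` matrix of IoU values.
#' @export
iou_matrix <- function(A, B) {
  A <- check_boxes(A); B <- check_boxes(B)
  ix <- pmax(0, outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax))
  iy <- pmax(0, outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax))
  inter <- ix * iy
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (outer(areaA, areaB, "+") - inter)
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-scored remaining box and discards boxes whose
#' IoU with it reaches `iou_threshold`. Ties are broken by input order.
#'
#' @param boxes Box matrix.
#' @param scores Numeric vector, one score per box.
#' @param iou_threshold Overlap threshold.
#' @return Integer indices of kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.3) {
  boxes <- check_boxes(boxes)
  stopifnot(length(scores) == nrow(boxes))
  ord <- order(-scores)        # stable: ties keep input order
  keep <- integer(0)
  while (length(ord) > 0) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord) > 0) {
      ious <- iou_matrix(boxes[i, , drop = FALSE],
                         boxes[ord, , drop = FALSE])[1, ]
      ord <- ord[ious < iou_threshold]
    }
  }
  keep
}

#' Encode / decode parameterized box offsets
#'
#' The standard center-offset / log-size parameterization: for a box with
#' centre `(cx, cy)` and size `(w, h)` against a reference with
#' `(cxr, cyr, wr, hr)`,
#' `t = ((cx-cxr)/wr, (cy-cyr)/hr, log(w/wr), log(h/hr))`.
#' `decode_box_deltas()` inverts it exactly.
#'
#' @param box,reference_box Box matrices (or length-4 vectors).
#' @param delta Delta matrix `(tx, ty, tw, th)`.
#' @return Delta matrix (encode) or box matrix (decode).
#' @export
encode_box_deltas <- function(box, reference_box) {
  b <- check_boxes(box); r <- as_box_matrix(reference_box)
  wr <- r[, 3] - r[, 1]; hr <- r[, 4] - r[, 2]
  if (any(wr <= 0) || any(hr <= 0)) {
    stop("reference box has zero width or height", call. = FALSE)
  }
  w <- b[, 3] - b[, 1]; h <- b[, 4] - b[, 2]
  cbind(tx = ((b[, 1] + b[, 3]) / 2 - (r[, 1] + r[, 3]) / 2) / wr,
        ty = ((b[, 2] + b[, 4]) / 2 - (r[, 2] + r[, 4]) / 2) / hr,
        tw = log(w / wr), th = log(h / hr))
}

#' @rdname encode_box_deltas
#' @export
decode_box_deltas <- function(delta, reference_box) {
  d <- as_box_matrix(delta); r <- as_box_matrix(reference_box)
  wr <- r[, 3] - r[, 1]; hr <- r[, 4] - r[, 2]
  if (any(wr <= 0) || any(hr <= 0)) {
    stop("reference box has zero width or height", call. = FALSE)
  }
  cx <- (r[, 1] + r[, 3]) / 2 + d[, 1] * wr
  cy <- (r[, 2] + r[, 4]) / 2 + d[, 2] * hr
  w <- wr * exp(d[, 3]); h <- hr * exp(d[, 4])
  cbind(x_min = cx - w / 2, y_min = cy - h / 2,
        x_max = cx + w / 2, y_max = cy + h / 2)
}

#' Anchor configuration
#'
#' Defaults follow the full-scale detector: three areas (128^2, 256^2, 512^2
#' pixels) times three aspect ratios (1:1, 1:2, 2:1) give nine anchors per
#' feature-map location at stride 16. Desk-scale configurations override
#' `scales` to match the synthetic scene sizes.
#'
#' @param scales Anchor areas in pixels^2.
#' @param aspect_ratios Width:height ratios.
#' @param stride Pixels between feature-map locations.
#' @return Object of class `anchor_config`.
#' @export
anchor_config <- function(scales = c(128, 256, 512)^2,
                          aspect_ratios = c(1, 0.5, 2), stride = 16) {
  stop_if_not(all(scales > 0) && all(aspect_ratios > 0) && stride > 0,
              "anchor scales, ratios and stride must be positive")
  structure(list(scales = scales, aspect_ratios = aspect_ratios,
                 stride = stride,
                 n_anchors = length(scales) * length(aspect_ratios)),
            class = "anchor_config")
}

#' Generate anchors for a feature map
#'
#' Tiles `length(scales) * length(aspect_ratios)` reference boxes at every
#' feature-map location, centred at `(col + 0.5, row + 0.5) * stride` in
#' image coordinates. An anchor of area `s^2` and ratio `r` has width
#' `s * sqrt(r)` and height `s / sqrt(r)`, preserving the area.
#'
#' Row order: anchor shape varies slowest, location (column-major: row
#' fastest) varies fastest, matching the channel layout of the proposal
#' network outputs.
#'
#' @param feature_map_height,feature_map_width Feature-map size in cells.
#' @param cfg An [anchor_config()].
#' @return Box matrix with `fh * fw * n_anchors` rows.
#' @export
generate_anchors <- function(feature_map_height, feature_map_width,
                             cfg = anchor_config()) {
  stop_if_not(feature_map_height >= 1 && feature_map_width >= 1,
              "feature map dimensions must be positive")
  fh <- feature_map_height; fw <- feature_map_width
  cx <- (rep(seq_len(fw) - 0.5, each = fh)) * cfg$stride
  cy <- (rep(seq_len(fh) - 0.5, times = fw)) * cfg$stride
  shapes <- do.call(rbind, lapply(cfg$scales, function(a) {
    t(vapply(cfg$aspect_ratios, function(r) {
      s <- sqrt(a)
      c(w = s * sqrt(r), h = s / sqrt(r))
    }, numeric(2)))
  }))
  do.call(rbind, lapply(seq_len(nrow(shapes)), function(i) {
    w <- shapes[i, 1]; h <- shapes[i, 2]
    cbind(x_min = cx - w / 2, y_min = cy - h / 2,
          x_max = cx + w / 2, y_max = cy + h / 2)
  }))
}

#' Clip boxes to image bounds
#'
#' @param boxes Box matrix.
#' @param height,width Image size in pixels.
#' @return Clipped box matrix.
#' @export
clip_boxes <- function(boxes, height, width) {
  b <- as_box_matrix(boxes)
  b[, c(1, 3)] <- clamp(b[, c(1, 3)], 0, width)
  b[, c(2, 4)] <- clamp(b[, c(2, 4)], 0, height)
  b
}

#' Assign detection targets to anchors or proposals
#'
#' Boxes with IoU at least `iou_positive` against a ground-truth box take
#' that box's region class, pose label and encoded delta target; boxes with
#' IoU at most `iou_negative` become background; the rest are ignored
#' (`NA`). Every ground-truth box additionally claims its single best-IoU
#' box even below threshold, so no annotation goes unmatched.
#'
#' @param boxes Box matrix (anchors or proposals).
#' @param annotations Data frame with `region_class`, `pose_class`,
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @param iou_positive,iou_negative Assignment thresholds.
#' @return List: `region_label` (character; `"background"` or a region
#'   class, `NA` = ignore), `pose_label` (character or `NA`), `deltas`
#'   (n x 4 encoded targets, `NA` rows for non-foreground), `matched_gt`
#'   (index into `annotations` or `NA`), `max_iou`.
#' @export
assign_targets <- function(boxes, annotations, iou_positive = 0.7,
                           iou_negative = 0.3) {
  boxes <- check_boxes(boxes)
  gt <- as.matrix(annotations[, c("x_min", "y_min", "x_max", "y_max")])
  n <- nrow(boxes); m <- nrow(gt)
  M <- iou_matrix(boxes, gt)
  best_gt <- max.col(M, ties.method = "first")
  max_iou <- M[cbind(seq_len(n), best_gt)]

  region <- rep(NA_character_, n)
  region[max_iou <= iou_negative] <- "background"
  pos <- max_iou >= iou_positive
  # each ground-truth box claims its best box even below threshold, among
  # boxes that overlap it and do not match another ground-truth box better
  for (g in seq_len(m)) {
    eligible <- which(M[, g] > 0 & M[, g] >= max_iou - 1e-12)
    if (length(eligible) > 0) {
      i <- eligible[which.max(M[eligible, g])]
      pos[i] <- TRUE
      best_gt[i] <- g
    }
  }
  region[pos] <- annotations$region_class[best_gt[pos]]

  pose <- rep(NA_character_, n)
  pose[pos] <- annotations$pose_class[best_gt[pos]]
  deltas <- matrix(NA_real_, n, 4,
                   dimnames = list(NULL, c("tx", "ty", "tw", "th")))
  if (any(pos)) {
    deltas[pos, ] <- encode_box_deltas(gt[best_gt[pos], , drop = FALSE],
                                       boxes[pos, , drop = FALSE])
  }
  matched <- ifelse(pos, best_gt, NA_integer_)
  list(region_label = region, pose_label = pose, deltas = deltas,
       matched_gt = matched, max_iou = max_iou)
}
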