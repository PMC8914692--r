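# Detection and classification metrics: greedy detection matching, average
# precision with all-point precision-envelope integration, pose accuracy and
# confusion matrices.

#' Match detections against ground truth
#'
#' Greedy protocol: walking detections in descending score order, each
#' detection matches the highest-IoU not-yet-matched ground-truth box of its
#' region class, provided IoU reaches `iou_threshold`. Each ground-truth box
#' is matched at most once; further detections of it are false positives.
#'
#' @param detections Data frame from [predict_frame()] (must contain
#'   `region_class`, `region_score` and box columns).
#' @param ground_truth Annotation data frame (`region_class`, box columns).
#' @param iou_threshold Match threshold.
#' @return List of class `match_result`: `tp` (logical per detection),
#'   `matched_gt` (index or `NA`), `gt_matched` (logical per ground-truth
#'   box), `iou_threshold`.
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  nd <- nrow(detections); ng <- nrow(ground_truth)
  tp <- logical(nd); matched <- rep(NA_integer_, nd)
  gt_used <- logical(ng)
  if (nd > 0) {
    ord <- order(-detections$region_score)
    gtb <- as.matrix(ground_truth[, c("x_min", "y_min", "x_max", "y_max")])
    dtb <- as.matrix(detections[, c("x_min", "y_min", "x_max", "y_max")])
    for (i in ord) {
      cand <- which(ground_truth$region_class == detections$region_class[i] &
                      !gt_used)
      if (length(cand) == 0) next
      ious <- iou_matrix(dtb[i, , drop = FALSE],
                         gtb[cand, , drop = FALSE])[1, ]
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        tp[i] <- TRUE
        matched[i] <- cand[j]
        gt_used[cand[j]] <- TRUE
      }
    }
  }
  structure(list(tp = tp, matched_gt = matched, gt_matched = gt_used,
                 iou_threshold = iou_threshold), class = "match_result")
}

# all-point average precision from score-sorted TP flags
average_precision <- function(scores, tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(scores) == 0) return(0)
  ord <- order(-scores)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / n_gt
  # precision envelope (monotone non-increasing from the right)
  penv <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * penv)
}

#' Mean average precision over the two region classes
#'
#' Per-class AP integrates the precision--recall curve with the all-point
#' precision envelope; mAP is the mean over `head` and `upper_body`.
#' A class with no ground truth is excluded (with a message).
#'
#' @param detections Data frame of detections pooled over images, with an
#'   `image` column identifying the frame.
#' @param ground_truth Data frame of annotations with an `image` column.
#' @param iou_threshold IoU threshold for matching.
#' @param classes Region classes to evaluate.
#' @return List of class `map_result`: `mAP` and per-class `ap`.
#' @export
mean_average_precision <- function(detections, ground_truth,
                                   iou_threshold = 0.5,
                                   classes = c("head", "upper_body")) {
  if (is.null(detections$image)) {
    detections$image <- rep(1L, nrow(detections))
  }
  if (is.null(ground_truth$image)) {
    ground_truth$image <- rep(1L, nrow(ground_truth))
  }
  aps <- setNames(numeric(0), character(0))
  for (cl in classes) {
    gt_cl <- ground_truth[ground_truth$region_class == cl, , drop = FALSE]
    n_gt <- nrow(gt_cl)
    if (n_gt == 0) {
      message("class '", cl, "' has no ground truth; excluded from mAP")
      next
    }
    det_cl <- detections[detections$region_class == cl, , drop = FALSE]
    tps <- logical(nrow(det_cl)); scs <- det_cl$region_score
    for (im in unique(ground_truth$image)) {
      di <- which(det_cl$image == im)
      if (length(di) == 0) next
      mr <- match_detections(det_cl[di, , drop = FALSE],
                             gt_cl[gt_cl$image == im, , drop = FALSE],
                             iou_threshold)
      tps[di] <- mr$tp
    }
    aps[cl] <- average_precision(scs, tps, n_gt)
  }
  structure(list(mAP = mean(aps), ap = aps,
                 iou_threshold = iou_threshold), class = "map_result")
}

#' Pose classification accuracy
#'
#' @param true,predicted Equal-length pose label vectors.
#' @return Percentage (0--100) of correct labels.
#' @export
classification_accuracy <- function(true, predicted) {
  stop_if_not(length(true) == length(predicted) && length(true) > 0,
              "need equal-length, nonempty label vectors")
  100 * mean(true == predicted)
}

#' Pose confusion matrix
#'
#' @param true,predicted Pose label vectors (rows = truth,
#'   columns = prediction).
#' @param normalize Return row-normalized proportions instead of counts.
#' @return 4 x 4 matrix over the posture classes.
#' @export
confusion_matrix <- function(true, predicted, normalize = FALSE) {
  bad <- setdiff(unique(c(true, predicted)), POSE_CLASSES)
  if (length(bad) > 0) {
    stop("unknown pose label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- table(factor(true, POSE_CLASSES), factor(predicted, POSE_CLASSES))
  m <- unclass(m)
  dimnames(m) <- list(truth = POSE_CLASSES, prediction = POSE_CLASSES)
  if (normalize) {
    rs <- rowSums(m)
    m <- sweep(m, 1, pmax(rs, 1), "/")
  }
  m
}

#' Write a confusion matrix as CSV
#'
#' @param m A [confusion_matrix()].
#' @param path Output file.
#' @export
write_confusion_csv <- function(m, path) {
  write.csv(as.data.frame(m), path)
  invisible(path)
}
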