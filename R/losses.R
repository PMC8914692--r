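# The masked multi-task loss of the detector: categorical cross-entropy for
# region classification and for each pose head (each pose loss masked to
# regions of the matching class), smooth-L1 for box regression, combined as
# the weighted sum
#   L = lambda_class * L_class + lambda_head * L_head +
#       lambda_body * L_body + lambda_box * L_box.

one_hot <- function(labels, classes) {
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}

# mean cross-entropy of softmax scores against labels; scores clamped away
# from zero at machine epsilon
cross_entropy <- function(labels, scores, classes) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- one_hot(as.character(labels), classes)
  }
  scores <- pmax(as.matrix(scores), .Machine$double.eps)
  mean(-rowSums(labels * log(scores)))
}

#' Loss weights of the multi-task objective
#'
#' @param lambda_class,lambda_head,lambda_body,lambda_box Nonnegative
#'   weights of the region-classification, head-pose, body-pose and
#'   box-regression losses.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_class = 1, lambda_head = 1,
                         lambda_body = 1, lambda_box = 1) {
  w <- c(lambda_class = lambda_class, lambda_head = lambda_head,
         lambda_body = lambda_body, lambda_box = lambda_box)
  if (any(w < 0)) stop("loss weights must be nonnegative", call. = FALSE)
  structure(as.list(w), class = "loss_weights")
}

#' Region-classification loss
#'
#' Mean categorical cross-entropy over sampled regions for the three-way
#' head / upper-body / background classification.
#'
#' @param y True labels: character vector over
#'   `c("head", "upper_body", "background")` or a one-hot matrix.
#' @param y_hat Softmax score matrix (n x 3).
#' @return Nonnegative scalar.
#' @export
loss_detection_class <- function(y, y_hat) {
  cross_entropy(y, y_hat, REGION_CLASSES)
}

#' Pose-classification losses
#'
#' Cross-entropy over the four posture classes, averaged only over regions
#' whose region label matches the head (`loss_head_pose`) or upper body
#' (`loss_body_pose`); zero when no region of that class is present.
#'
#' @param region_labels Character vector of region labels.
#' @param pose_labels Character vector of true pose labels (may be `NA` for
#'   non-matching regions).
#' @param pose_scores Softmax score matrix (n x 4).
#' @return Nonnegative scalar.
#' @export
loss_head_pose <- function(region_labels, pose_labels, pose_scores) {
  masked_pose_loss(region_labels, pose_labels, pose_scores, "head")
}

#' @rdname loss_head_pose
#' @export
loss_body_pose <- function(region_labels, pose_labels, pose_scores) {
  masked_pose_loss(region_labels, pose_labels, pose_scores, "upper_body")
}

masked_pose_loss <- function(region_labels, pose_labels, pose_scores, what) {
  sel <- which(!is.na(region_labels) & region_labels == what)
  if (length(sel) == 0) return(0)
  cross_entropy(pose_labels[sel],
                as.matrix(pose_scores)[sel, , drop = FALSE], POSE_CLASSES)
}

#' Smooth-L1 box-regression loss
#'
#' For matched foreground regions only: sum over the four parameterized
#' coordinates of `smoothL1(t - t_hat)` with `smoothL1(d) = 0.5 d^2` for
#' `|d| < 1` and `|d| - 0.5` otherwise, averaged over regions.
#'
#' @param t Predicted delta matrix (n x 4).
#' @param t_hat Target delta matrix (n x 4).
#' @return Nonnegative scalar.
#' @export
loss_box_regression <- function(t, t_hat) {
  t <- as_box_matrix(t); t_hat <- as_box_matrix(t_hat)
  if (nrow(t) == 0) return(0)
  d <- t - t_hat
  sl1 <- ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)
  mean(rowSums(sl1))
}

# derivative of smooth-L1 wrt d
smooth_l1_grad <- function(d) ifelse(abs(d) < 1, d, sign(d))

#' Total multi-task loss
#'
#' The weighted sum of the four task losses.
#'
#' @param L_class,L_head,L_body,L_box Nonnegative component losses.
#' @param weights A [loss_weights()].
#' @return Object of class `loss_breakdown`: the four components, the
#'   weights, and `L_total`.
#' @export
total_loss <- function(L_class, L_head, L_body, L_box,
                       weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  comp <- c(L_class = L_class, L_head = L_head, L_body = L_body,
            L_box = L_box)
  # non-finite components pass through so training can report divergence
  if (any(comp < 0, na.rm = TRUE)) {
    stop("loss components must be nonnegative", call. = FALSE)
  }
  total <- weights$lambda_class * L_class + weights$lambda_head * L_head +
    weights$lambda_body * L_body + weights$lambda_box * L_box
  structure(list(L_class = L_class, L_head = L_head, L_body = L_body,
                 L_box = L_box, L_total = total, weights = weights),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss: total %.4f (class %.4f, head %.4f, body %.4f, box %.4f)\n",
    x$L_total, x$L_class, x$L_head, x$L_body, x$L_box))
  invisible(x)
}
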