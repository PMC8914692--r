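# End-to-end training of the multi-task detector: joint Adam optimization of
# the weighted multi-task loss (region class + head pose + body pose + box
# regression) together with the proposal stage's objectness/regression loss,
# with validation-based early stopping.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (the full-scale default is 1e-5;
#'   desk-scale runs on the tiny backbone use larger rates).
#' @param max_epochs Maximum number of passes over the training set.
#' @param patience Early stopping: stop after this many epochs without
#'   validation improvement.
#' @param batch_size Images per optimization step (image-centric training;
#'   currently 1).
#' @param seed Integer seed controlling initialization and sampling.
#' @param backbone Backbone name, see [net_config()].
#' @param augment Apply [augment_sample()] to each training image per epoch.
#' @param rpn_batch,roi_batch Anchors / regions sampled per image for the
#'   loss (at most half foreground).
#' @param rpn_iou_positive,rpn_iou_negative Anchor assignment thresholds.
#' @param roi_iou_positive Second-stage foreground threshold.
#' @param pre_nms_top_k,post_nms_top_k Proposal truncation during training.
#' @param n_jitter Jittered copies of each ground-truth box added to the
#'   region pool.
#' @param lr_decay_factor,lr_decay_after Step decay: after epoch
#'   `lr_decay_after` (default two thirds of `max_epochs`) the learning rate
#'   is multiplied by `lr_decay_factor`; this settles box regression once
#'   classification has converged. Set the factor to 1 for a constant rate.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, max_epochs = 20, patience = 5,
                         batch_size = 1, seed = 1L,
                         backbone = "tiny_test", augment = FALSE,
                         rpn_batch = 16, roi_batch = 16,
                         rpn_iou_positive = 0.7, rpn_iou_negative = 0.3,
                         roi_iou_positive = 0.5,
                         pre_nms_top_k = 48, post_nms_top_k = 12,
                         n_jitter = 2, lr_decay_factor = 0.2,
                         lr_decay_after = NULL) {
  stopifnot(learning_rate > 0, max_epochs >= 1, patience >= 1,
            batch_size >= 1, lr_decay_factor > 0)
  lr_decay_after <- lr_decay_after %||% max(1, floor(2 * max_epochs / 3))
  structure(list(learning_rate = learning_rate, optimizer = "adam",
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 backbone = backbone, augment = isTRUE(augment),
                 rpn_batch = rpn_batch, roi_batch = roi_batch,
                 rpn_iou_positive = rpn_iou_positive,
                 rpn_iou_negative = rpn_iou_negative,
                 roi_iou_positive = roi_iou_positive,
                 pre_nms_top_k = pre_nms_top_k,
                 post_nms_top_k = post_nms_top_k, n_jitter = n_jitter,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_after = as.integer(lr_decay_after)),
            class = "train_config")
}

sample_n_of <- function(x, n) {
  n <- min(n, length(x))
  if (n <= 0) return(integer(0))
  if (length(x) == 1) return(x)
  x[sample.int(length(x), n)]
}

jitter_boxes <- function(gtb, k, H, W) {
  if (k <= 0) return(NULL)
  out <- do.call(rbind, lapply(seq_len(k), function(j) {
    w <- gtb[, 3] - gtb[, 1]; h <- gtb[, 4] - gtb[, 2]
    cx <- (gtb[, 1] + gtb[, 3]) / 2 + runif(nrow(gtb), -0.1, 0.1) * w
    cy <- (gtb[, 2] + gtb[, 4]) / 2 + runif(nrow(gtb), -0.1, 0.1) * h
    w2 <- w * exp(runif(nrow(gtb), -0.15, 0.15))
    h2 <- h * exp(runif(nrow(gtb), -0.15, 0.15))
    cbind(cx - w2 / 2, cy - h2 / 2, cx + w2 / 2, cy + h2 / 2)
  }))
  out <- clip_boxes(out, H, W)
  out[out[, 3] - out[, 1] >= 2 & out[, 4] - out[, 2] >= 2, , drop = FALSE]
}

# One image's losses and (optionally) parameter gradients.
compute_step <- function(net, sample, weights, tc, with_grads = TRUE) {
  p <- net$params; cfg <- net$cfg; A <- cfg$n_anchor_shapes
  img <- luminance(sample$image)
  H <- nrow(img); W <- ncol(img)
  x <- pad_to_stride(as_cube(img / 255), cfg$stride)
  bb <- backbone_forward(x, p)
  feat <- bb$feat
  fh <- dim(feat)[1]; fw <- dim(feat)[2]
  rpn <- rpn_forward(feat, p)
  un <- rpn_unpack(rpn$cls, rpn$box, A)
  anchors <- generate_anchors(fh, fw, net$anchor_cfg)
  ann <- sample$annotations

  # --- proposal stage loss over sampled anchors ----------------------------
  at <- assign_targets(anchors, ann, tc$rpn_iou_positive, tc$rpn_iou_negative)
  fg_a <- which(!is.na(at$region_label) & at$region_label != "background")
  bg_a <- which(!is.na(at$region_label) & at$region_label == "background")
  sel_fg <- sample_n_of(fg_a, ceiling(tc$rpn_batch / 2))
  sel_bg <- sample_n_of(bg_a, tc$rpn_batch - length(sel_fg))
  sel <- c(sel_fg, sel_bg)
  y <- c(rep(1, length(sel_fg)), rep(0, length(sel_bg)))
  pfg <- clamp(un$p_fg[sel], .Machine$double.eps, 1 - 1e-15)
  L_rpn_cls <- mean(-(y * log(pfg) + (1 - y) * log(1 - pfg)))
  t_pred <- un$deltas[sel_fg, , drop = FALSE]
  t_tgt <- at$deltas[sel_fg, , drop = FALSE]
  L_rpn_box <- loss_box_regression(t_pred, t_tgt)

  # --- second-stage regions: proposals + ground truth + jittered copies ----
  props <- propose_boxes(un, anchors, c(H, W), tc$pre_nms_top_k,
                         tc$post_nms_top_k, 0.7, 2)$boxes
  gtb <- as.matrix(ann[, c("x_min", "y_min", "x_max", "y_max")])
  rois <- rbind(props, gtb, jitter_boxes(gtb, tc$n_jitter, H, W))
  st <- assign_targets(rois, ann, tc$roi_iou_positive, tc$roi_iou_positive)
  fg_r <- which(!is.na(st$region_label) & st$region_label != "background")
  bg_r <- which(!is.na(st$region_label) & st$region_label == "background")
  # stratify foreground regions by class so the small head region is not
  # swamped by body proposals
  nf_half <- ceiling(ceiling(tc$roi_batch / 2) / 2)
  sfg <- c(sample_n_of(fg_r[st$region_label[fg_r] == "head"], nf_half),
           sample_n_of(fg_r[st$region_label[fg_r] == "upper_body"], nf_half))
  sbg <- sample_n_of(bg_r, tc$roi_batch - length(sfg))
  sel2 <- c(sfg, sbg)
  boxes_s <- rois[sel2, , drop = FALSE]
  labs <- st$region_label[sel2]
  pose_labs <- st$pose_label[sel2]
  tgt_d <- st$deltas[sel2, , drop = FALSE]

  fw_ <- roi_head_forward(feat, boxes_s, p, cfg)
  P <- softmax_rows(fw_$det_logits)
  Ph <- softmax_rows(fw_$head_logits)
  Pb <- softmax_rows(fw_$body_logits)
  L_class <- loss_detection_class(labs, P)
  L_head <- loss_head_pose(labs, pose_labs, Ph)
  L_body <- loss_body_pose(labs, pose_labs, Pb)
  cslot <- match(labs, REGION_CLASSES)
  fgi <- which(labs != "background")
  L_box <- if (length(fgi) > 0) {
    tp <- t(vapply(fgi, function(i) {
      fw_$box_out[i, 4 * (cslot[i] - 1) + 1:4]
    }, numeric(4)))
    loss_box_regression(tp, tgt_d[fgi, , drop = FALSE])
  } else 0
  lb <- total_loss(L_class, L_head, L_body, L_box, weights)
  L_rpn <- L_rpn_cls + L_rpn_box

  out <- list(breakdown = lb, L_rpn = L_rpn,
              total = lb$L_total + L_rpn)
  if (!with_grads) return(out)

  # --- gradients -----------------------------------------------------------
  n2 <- length(labs)
  d_det <- weights$lambda_class * (P - one_hot(labs, REGION_CLASSES)) / n2
  d_head <- matrix(0, n2, 4); d_body <- matrix(0, n2, 4)
  hrows <- which(labs == "head"); brows <- which(labs == "upper_body")
  if (length(hrows) > 0) {
    d_head[hrows, ] <- weights$lambda_head *
      (Ph[hrows, , drop = FALSE] -
         one_hot(pose_labs[hrows], POSE_CLASSES)) / length(hrows)
  }
  if (length(brows) > 0) {
    d_body[brows, ] <- weights$lambda_body *
      (Pb[brows, , drop = FALSE] -
         one_hot(pose_labs[brows], POSE_CLASSES)) / length(brows)
  }
  d_box <- matrix(0, n2, 8)
  if (length(fgi) > 0) {
    for (i in fgi) {
      sl <- 4 * (cslot[i] - 1) + 1:4
      d_box[i, sl] <- weights$lambda_box *
        smooth_l1_grad(fw_$box_out[i, sl] - tgt_d[i, ]) / length(fgi)
    }
  }
  bwd <- roi_head_backward(fw_, d_det, d_box, d_head, d_body, feat, p)

  dclsm <- matrix(0, un$n_loc, 2 * A)
  g <- (un$p_fg[sel] - y) / length(sel)
  l_i <- (sel - 1) %% un$n_loc + 1
  a_i <- (sel - 1) %/% un$n_loc + 1
  dclsm[cbind(l_i, 2 * a_i)] <- g
  dclsm[cbind(l_i, 2 * a_i - 1)] <- -g
  dboxm <- matrix(0, un$n_loc, 4 * A)
  if (length(sel_fg) > 0) {
    gd <- smooth_l1_grad(t_pred - t_tgt) / length(sel_fg)
    lf <- (sel_fg - 1) %% un$n_loc + 1
    af <- (sel_fg - 1) %/% un$n_loc + 1
    for (j in 1:4) dboxm[cbind(lf, 4 * (af - 1) + j)] <- gd[, j]
  }
  rb <- rpn_backward(array(dclsm, c(fh, fw, 2 * A)),
                     array(dboxm, c(fh, fw, 4 * A)), rpn$cache, p)
  dfeat <- bwd$dfeat + rb$dfeat
  out$grads <- c(backbone_backward(dfeat, bb$cache, p), rb$grads, bwd$grads)
  out
}

#' Fit the multi-task sleep-posture detector
#'
#' Trains all tasks end to end with Adam on the weighted multi-task loss,
#' using validation-based early stopping; the parameters of the best
#' validation epoch are returned.
#'
#' @param train List of annotated samples (e.g. a [generate_dataset()]
#'   `$train` split) or a `scene_dataset` (its `train`/`val` splits are
#'   used).
#' @param val List of validation samples; if `NULL`, the training loss
#'   drives early stopping.
#' @param config A [train_config()].
#' @param weights A [loss_weights()].
#' @param anchors An [anchor_config()] sized for the input images.
#' @param net Optional pre-built [sleepose_net()] (overrides `config`'s
#'   backbone).
#' @return Object of class `sleepose_model`: the fitted `net`, per-epoch
#'   loss `history`, `config`, `weights`, and `best_epoch`.
#' @export
sleepose_fit <- function(train, val = NULL, config = train_config(),
                         weights = loss_weights(),
                         anchors = anchor_config(), net = NULL) {
  if (inherits(train, "scene_dataset")) {
    if (is.null(val)) val <- train$val
    train <- train$train
  }
  stop_if_not(length(train) > 0, "empty training set")
  tc <- config
  if (is.null(net)) {
    net <- sleepose_net(net_config(backbone = tc$backbone), anchors,
                        seed = tc$seed)
  }
  state <- adam_init(net$params)
  best <- list(val = Inf, params = net$params, epoch = 0L)
  hist <- NULL
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      lr <- tc$learning_rate *
        if (epoch > tc$lr_decay_after) tc$lr_decay_factor else 1
      ord <- sample.int(length(train))
      tr_tot <- comp <- c(L_class = 0, L_head = 0, L_body = 0, L_box = 0,
                          L_rpn = 0)
      tr_total <- 0
      for (i in ord) {
        smp <- train[[i]]
        if (tc$augment) {
          aug <- augment_sample(smp, seed = sample.int(.Machine$integer.max, 1))
          if (!is.null(aug)) smp <- aug
        }
        stp <- compute_step(net, smp, weights, tc, with_grads = TRUE)
        if (!is.finite(stp$total)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        }
        upd <- adam_step(net$params, stp$grads, state, lr)
        net$params <- upd$params; state <- upd$state
        tr_total <- tr_total + stp$total
        comp <- comp + c(stp$breakdown$L_class, stp$breakdown$L_head,
                         stp$breakdown$L_body, stp$breakdown$L_box, stp$L_rpn)
      }
      tr_total <- tr_total / length(train)
      comp <- comp / length(train)
      val_total <- if (is.null(val)) tr_total else {
        with_seed(tc$seed + 86243L, {
          mean(vapply(val, function(s) {
            compute_step(net, s, weights, tc, with_grads = FALSE)$total
          }, numeric(1)))
        })
      }
      hist <- rbind(hist, data.frame(
        epoch = epoch, train_total = tr_total, val_total = val_total,
        L_class = comp[1], L_head = comp[2], L_body = comp[3],
        L_box = comp[4], L_rpn = comp[5]))
      sp_log("epoch %d  train %.4f  val %.4f", epoch, tr_total, val_total)
      if (val_total < best$val - 1e-6) {
        best <- list(val = val_total, params = net$params, epoch = epoch)
      } else if (epoch - best$epoch >= tc$patience) {
        sp_log("early stopping at epoch %d (best epoch %d)", epoch,
               best$epoch)
        break
      }
    }
  })
  net$params <- best$params
  rownames(hist) <- NULL
  structure(list(net = net, history = hist, config = tc, weights = weights,
                 best_epoch = best$epoch, call = sys.call()),
            class = "sleepose_model")
}

#' @export
print.sleepose_model <- function(x, ...) {
  cat("Multi-task sleep-posture detector (", x$net$cfg$backbone,
      " backbone)\n", sep = "")
  cat("  epochs run:", nrow(x$history), " best validation epoch:",
      x$best_epoch, "\n")
  cat(sprintf("  best validation loss: %.4f\n", min(x$history$val_total)))
  invisible(x)
}

#' @export
summary.sleepose_model <- function(object, ...) {
  x <- object
  cat("Multi-task sleep-posture detector\n")
  cat("  backbone:", x$net$cfg$backbone, " stride:", x$net$cfg$stride, "\n")
  cat("  optimizer: adam, lr", format(x$config$learning_rate),
      " max epochs:", x$config$max_epochs,
      " patience:", x$config$patience, "\n")
  w <- x$weights
  cat(sprintf("  loss weights: class %.2g head %.2g body %.2g box %.2g\n",
              w$lambda_class, w$lambda_head, w$lambda_body, w$lambda_box))
  cat("  loss history (last 5 epochs):\n")
  print(tail(x$history, 5), row.names = FALSE)
  invisible(x$history)
}

#' Predict detections for new images
#'
#' @param object A fitted `sleepose_model`.
#' @param newdata A single image matrix, a `scene_sample`, or a list of
#'   either.
#' @param ... Passed to [predict_frame()].
#' @return A detections data frame (single image) or a list of them.
#' @export
predict.sleepose_model <- function(object, newdata, ...) {
  one <- function(s) {
    img <- if (is.list(s)) s$image else s
    predict_frame(img, object$net, ...)
  }
  if (is.matrix(newdata) || inherits(newdata, "scene_sample")) {
    return(one(newdata))
  }
  lapply(newdata, one)
}

#' Plot training and validation loss curves
#'
#' @param x A fitted `sleepose_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sleepose_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_total, h$val_total), type = "b",
                    pch = c(1, 19), lty = 1, xlab = "epoch",
                    ylab = "total loss", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 19),
                   lty = 1, col = 1:2, bty = "n")
  invisible(x)
}

#' @export
coef.sleepose_model <- function(object, ...) object$net$params

#' Desk-scale reference configuration
#'
#' The package's reference setup for training and validating the detector on
#' synthetic scenes without GPUs or human data: 96 x 96 px scenes (head
#' 18--24 px, body 32--44 px, thin-sheet-like occlusion of the lower body,
#' mild noise and brightness jitter), anchors scaled to those blob sizes,
#' and a short Adam schedule with early stopping. Used by the package's own
#' validation runs; every element can be overridden for larger studies.
#'
#' @param seed Integer seed.
#' @return List with `spec` ([scene_spec()]), `anchors`
#'   ([anchor_config()]) and `train` ([train_config()]).
#' @export
desk_config <- function(seed = 1L) {
  list(spec = scene_spec(96, 96, head_size_range = c(18, 24),
                         body_size_range = c(32, 44), seed = seed),
       anchors = anchor_config(scales = c(20, 34, 48)^2),
       train = train_config(learning_rate = 2e-3, max_epochs = 9,
                            patience = 4, roi_batch = 8, rpn_batch = 16,
                            lr_decay_after = 6, seed = seed))
}
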