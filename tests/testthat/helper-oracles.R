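# Brute-force reference implementations, deliberately independent of the
# package's vectorized/compiled code paths: plain loops and set arithmetic.

# pixel-set IoU for integer-coordinate half-open boxes
oracle_iou_pixels <- function(a, b) {
  pix <- function(bx) {
    as.vector(outer(bx[1]:(bx[3] - 1), bx[2]:(bx[4] - 1),
                    function(x, y) paste(x, y)))
  }
  ia <- pix(a); ib <- pix(b)
  length(intersect(ia, ib)) / length(union(ia, ib))
}

# greedy NMS with explicit loops
oracle_nms <- function(boxes, scores, thr) {
  alive <- rep(TRUE, nrow(boxes))
  keep <- integer(0)
  repeat {
    cand <- which(alive)
    if (length(cand) == 0) break
    i <- cand[order(-scores[cand])][1]
    keep <- c(keep, i)
    alive[i] <- FALSE
    for (j in which(alive)) {
      if (iou(boxes[i, ], boxes[j, ]) >= thr) alive[j] <- FALSE
    }
  }
  keep
}

# per-pixel ViBe classification straight from the match-count rule
oracle_vibe_classify <- function(frame, samples, R, min_matches) {
  H <- nrow(frame); W <- ncol(frame)
  mask <- matrix(0L, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      cnt <- 0L
      for (n in seq_len(dim(samples)[3])) {
        if (abs(frame[y, x] - samples[y, x, n]) < R) cnt <- cnt + 1L
      }
      if (cnt < min_matches) mask[y, x] <- 1L
    }
  }
  mask
}

# set-based binary morphology with a square kernel
oracle_erode <- function(m, k) {
  half <- (k - 1) / 2
  out <- matrix(0L, nrow(m), ncol(m))
  for (y in seq_len(nrow(m))) {
    for (x in seq_len(ncol(m))) {
      ys <- max(1, y - half):min(nrow(m), y + half)
      xs <- max(1, x - half):min(ncol(m), x + half)
      # border-clamped neighborhood: all in-bounds covered cells must be set
      out[y, x] <- as.integer(all(m[ys, xs] == 1))
    }
  }
  out
}

oracle_dilate <- function(m, k) {
  half <- (k - 1) / 2
  out <- matrix(0L, nrow(m), ncol(m))
  for (y in seq_len(nrow(m))) {
    for (x in seq_len(ncol(m))) {
      ys <- max(1, y - half):min(nrow(m), y + half)
      xs <- max(1, x - half):min(ncol(m), x + half)
      out[y, x] <- as.integer(any(m[ys, xs] == 1))
    }
  }
  out
}

# 4-connected component labels via BFS
oracle_label <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (sy in seq_len(nrow(m))) for (sx in seq_len(ncol(m))) {
    if (m[sy, sx] == 1 && lab[sy, sx] == 0) {
      cur <- cur + 1L
      queue <- list(c(sy, sx)); lab[sy, sx] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
              m[q[1], q[2]] == 1 && lab[q[1], q[2]] == 0) {
            lab[q[1], q[2]] <- cur
            queue <- c(queue, list(q))
          }
        }
      }
    }
  }
  lab
}

# fill interior holes: background components not reachable from the border
oracle_fill_holes <- function(m) {
  inv <- 1L - m
  lab <- oracle_label(inv)
  border <- unique(c(lab[1, ], lab[nrow(m), ], lab[, 1], lab[, ncol(m)]))
  hole <- lab > 0 & !(lab %in% border)
  m[hole] <- 1L
  m
}

oracle_clean_mask <- function(m, k, min_area) {
  m <- oracle_dilate(oracle_erode(m, k), k)
  lab <- oracle_label(m)
  if (max(lab) > 0) {
    for (comp in seq_len(max(lab))) {
      if (sum(lab == comp) < min_area) m[lab == comp] <- 0L
    }
  }
  oracle_fill_holes(m)
}

# RoI max pooling with explicit loops (same floor/ceil binning contract)
oracle_roipool <- function(X, box, S) {
  C <- dim(X)[3]
  out <- array(0, c(S, S, C))
  for (c in seq_len(C)) for (bx in 1:S) for (by in 1:S) {
    x0 <- floor(box[1] + (bx - 1) * (box[3] - box[1]) / S)
    x1 <- ceiling(box[1] + bx * (box[3] - box[1]) / S)
    y0 <- floor(box[2] + (by - 1) * (box[4] - box[2]) / S)
    y1 <- ceiling(box[2] + by * (box[4] - box[2]) / S)
    x0 <- max(0, min(x0, dim(X)[2] - 1)); x1 <- max(x0 + 1, min(x1, dim(X)[2]))
    y0 <- max(0, min(y0, dim(X)[1] - 1)); y1 <- max(y0 + 1, min(y1, dim(X)[1]))
    out[by, bx, c] <- max(X[(y0 + 1):y1, (x0 + 1):x1, c])
  }
  out
}

# target assignment straight from the written rule
oracle_assign <- function(boxes, ann, pos, neg) {
  gt <- as.matrix(ann[, c("x_min", "y_min", "x_max", "y_max")])
  n <- nrow(boxes); m <- nrow(gt)
  lab <- rep(NA_character_, n)
  M <- matrix(0, n, m)
  for (i in seq_len(n)) for (g in seq_len(m)) {
    M[i, g] <- iou(boxes[i, ], gt[g, ])
  }
  best <- integer(n)
  maxiou <- numeric(n)
  for (i in seq_len(n)) {
    best[i] <- which.max(M[i, ])
    maxiou[i] <- M[i, best[i]]
    if (maxiou[i] >= pos) lab[i] <- ann$region_class[best[i]]
    else if (maxiou[i] <= neg) lab[i] <- "background"
  }
  # forced claim: best positively-overlapping box for which this gt is also
  # (one of) the box's best matches
  for (g in seq_len(m)) {
    cand <- which(M[, g] > 0 & M[, g] >= maxiou - 1e-12)
    if (length(cand) > 0) {
      i <- cand[which.max(M[cand, g])]
      lab[i] <- ann$region_class[g]
    }
  }
  lab
}

# all-point average precision by enumerating precision-recall points
oracle_ap <- function(scores, tp, n_gt) {
  ord <- order(-scores)
  tp <- tp[ord]
  ap <- 0; prev_rec <- 0
  for (i in seq_along(tp)) {
    rec <- sum(tp[1:i]) / n_gt
    if (tp[i]) {
      # envelope precision at this recall: max precision at any k >= i
      penv <- max(sapply(i:length(tp), function(k) sum(tp[1:k]) / k))
      ap <- ap + (rec - prev_rec) * penv
      prev_rec <- rec
    }
  }
  ap
}
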