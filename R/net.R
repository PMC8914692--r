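# Internal neural-network machinery for the two-stage detector.
#
# Every layer's parameters are a list(W, b) where W is a matrix
# ((k*k*Cin) x Cout for convolutions, (Cin x Cout) for fully connected
# layers) and b a numeric vector, so one Adam implementation serves all
# layers. Convolution/pooling kernels live in src/convnet.cpp; feature maps
# are arrays dim c(H, W, C).

BB_LAYERS <- c("conv1", "conv2", "conv3", "conv4")

#' Network architecture configuration
#'
#' The detector backbone is a swappable contract: any convolutional stack
#' producing a stride-16 feature map. `tiny_test` is a four-stage stack
#' (3x3 conv + ReLU + 2x2 max-pool, four times) sized for desk-scale
#' synthetic scenes. `paper_resnet50` names the full-scale configuration
#' (ResNet-50 cut at its fourth stage); it requires externally pretrained
#' weights and cannot be instantiated here.
#'
#' @param backbone `"tiny_test"` or `"paper_resnet50"`.
#' @param channels Output channels of the four backbone stages.
#' @param rpn_channels Channels of the proposal network's 3x3 conv.
#' @param roi_size Side of the pooled RoI grid fed to the residual block.
#' @return Object of class `net_config`.
#' @export
net_config <- function(backbone = c("tiny_test", "paper_resnet50"),
                       channels = c(8, 16, 32, 32), rpn_channels = 32,
                       roi_size = 6) {
  backbone <- match.arg(backbone)
  stopifnot(length(channels) == 4, all(channels > 0), rpn_channels > 0,
            roi_size >= 1)
  structure(list(backbone = backbone, channels = as.integer(channels),
                 rpn_channels = as.integer(rpn_channels),
                 roi_size = as.integer(roi_size), stride = 16L,
                 n_anchor_shapes = 9L),
            class = "net_config")
}

he_init <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

init_net_params <- function(cfg, seed = 1L) {
  if (cfg$backbone == "paper_resnet50") {
    stop("the 'paper_resnet50' backbone contract requires pretrained ",
         "ResNet-50 weights and cannot be instantiated in this build; ",
         "use backbone = 'tiny_test'", call. = FALSE)
  }
  ch <- cfg$channels; A <- cfg$n_anchor_shapes
  with_seed(seed, {
    p <- list()
    cin <- 1L
    for (i in seq_along(BB_LAYERS)) {
      p[[BB_LAYERS[i]]] <- list(W = he_init(9 * cin, ch[i]),
                                b = numeric(ch[i]))
      cin <- ch[i]
    }
    C <- ch[4]; R <- cfg$rpn_channels
    p$rpn_conv <- list(W = he_init(9 * C, R), b = numeric(R))
    p$rpn_cls <- list(W = 0.01 * he_init(R, 2 * A), b = numeric(2 * A))
    p$rpn_box <- list(W = 0.01 * he_init(R, 4 * A), b = numeric(4 * A))
    p$resA <- list(W = he_init(9 * C, C), b = numeric(C))
    p$resB <- list(W = 0.1 * he_init(9 * C, C), b = numeric(C))
    p$fc_det <- list(W = 0.01 * he_init(C, 3), b = numeric(3))
    p$fc_box <- list(W = 0.01 * he_init(C, 8), b = numeric(8))
    p$fc_head <- list(W = 0.01 * he_init(C, 4), b = numeric(4))
    p$fc_body <- list(W = 0.01 * he_init(C, 4), b = numeric(4))
    p
  })
}

softmax_rows <- function(z) {
  z <- as.matrix(z)
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

as_cube <- function(img) {
  if (is.matrix(img)) array(img, dim = c(dim(img), 1L)) else img
}

# pad bottom/right with zeros so both sides are multiples of the stride
pad_to_stride <- function(x, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]
  H2 <- ceiling(H / stride) * stride; W2 <- ceiling(W / stride) * stride
  if (H2 == H && W2 == W) return(x)
  out <- array(0, c(H2, W2, dim(x)[3]))
  out[seq_len(H), seq_len(W), ] <- x
  out
}

backbone_forward <- function(x, p) {
  cache <- vector("list", length(BB_LAYERS))
  names(cache) <- BB_LAYERS
  a <- x
  for (ln in BB_LAYERS) {
    z <- cn_conv_fwd(a, p[[ln]]$W, p[[ln]]$b, 3L, 1L)
    r <- pmax(z, 0)
    pl <- cn_maxpool2_fwd(r)
    cache[[ln]] <- list(input = a, pre = z, idx = pl$idx, dims = dim(r))
    a <- pl$out
  }
  list(feat = a, cache = cache)
}

backbone_backward <- function(d, cache, p) {
  grads <- list()
  for (ln in rev(BB_LAYERS)) {
    cc <- cache[[ln]]
    dr <- cn_maxpool2_bwd(d, cc$idx, cc$dims[1], cc$dims[2], cc$dims[3])
    dz <- dr * (cc$pre > 0)
    g <- cn_conv_bwd(cc$input, p[[ln]]$W, dz, 3L, 1L)
    grads[[ln]] <- list(W = g$dK, b = as.numeric(g$db))
    d <- g$dX
  }
  grads
}

rpn_forward <- function(feat, p) {
  z <- cn_conv_fwd(feat, p$rpn_conv$W, p$rpn_conv$b, 3L, 1L)
  r <- pmax(z, 0)
  cls <- cn_conv_fwd(r, p$rpn_cls$W, p$rpn_cls$b, 1L, 0L)
  box <- cn_conv_fwd(r, p$rpn_box$W, p$rpn_box$b, 1L, 0L)
  list(cls = cls, box = box, cache = list(feat = feat, z = z, r = r))
}

rpn_backward <- function(dcls, dbox, cache, p) {
  g1 <- cn_conv_bwd(cache$r, p$rpn_cls$W, dcls, 1L, 0L)
  g2 <- cn_conv_bwd(cache$r, p$rpn_box$W, dbox, 1L, 0L)
  dz <- (g1$dX + g2$dX) * (cache$z > 0)
  g0 <- cn_conv_bwd(cache$feat, p$rpn_conv$W, dz, 3L, 1L)
  list(grads = list(rpn_cls = list(W = g1$dK, b = as.numeric(g1$db)),
                    rpn_box = list(W = g2$dK, b = as.numeric(g2$db)),
                    rpn_conv = list(W = g0$dK, b = as.numeric(g0$db))),
       dfeat = g0$dX)
}

# Flatten RPN output cubes into per-anchor foreground probabilities and
# deltas. Global anchor index = (shape - 1) * n_locations + location, with
# locations in column-major (row-fastest) order -- the same order
# generate_anchors() emits.
rpn_unpack <- function(cls, box, A) {
  L <- dim(cls)[1] * dim(cls)[2]
  clsm <- matrix(cls, L, 2 * A)
  dl <- clsm[, 2 * seq_len(A), drop = FALSE] -
    clsm[, 2 * seq_len(A) - 1, drop = FALSE]
  p_fg <- as.vector(1 / (1 + exp(-dl)))
  boxm <- matrix(box, L, 4 * A)
  deltas <- do.call(rbind, lapply(seq_len(A), function(a) {
    boxm[, 4 * (a - 1) + 1:4, drop = FALSE]
  }))
  list(p_fg = p_fg, deltas = deltas, n_loc = L)
}

roi_head_forward <- function(feat, boxes_img, p, cfg) {
  S <- cfg$roi_size; C <- dim(feat)[3]
  fb <- as_box_matrix(boxes_img) / cfg$stride
  rp <- cn_roipool_fwd(feat, fb, S)
  n <- nrow(fb)
  Fm <- matrix(0, n, C)
  rcache <- vector("list", n)
  pooled <- array(rp$out, c(S, S, C, n))
  for (i in seq_len(n)) {
    x <- array(pooled[, , , i], c(S, S, C))
    za <- cn_conv_fwd(x, p$resA$W, p$resA$b, 3L, 1L)
    a <- pmax(za, 0)
    zb <- cn_conv_fwd(a, p$resB$W, p$resB$b, 3L, 1L)
    ypre <- x + zb
    y <- pmax(ypre, 0)
    Fm[i, ] <- apply(y, 3, mean)
    rcache[[i]] <- list(x = x, za = za, a = a, ypre = ypre)
  }
  det_logits <- sweep(Fm %*% p$fc_det$W, 2, p$fc_det$b, "+")
  box_out <- sweep(Fm %*% p$fc_box$W, 2, p$fc_box$b, "+")
  head_logits <- sweep(Fm %*% p$fc_head$W, 2, p$fc_head$b, "+")
  body_logits <- sweep(Fm %*% p$fc_body$W, 2, p$fc_body$b, "+")
  list(F = Fm, det_logits = det_logits, box_out = box_out,
       head_logits = head_logits, body_logits = body_logits,
       rcache = rcache, roi_idx = rp$idx, S = S, C = C, n = n)
}

roi_head_backward <- function(fw, d_det, d_box, d_head, d_body, feat, p) {
  Fm <- fw$F; S <- fw$S; C <- fw$C; n <- fw$n
  grads <- list(
    fc_det = list(W = t(Fm) %*% d_det, b = colSums(d_det)),
    fc_box = list(W = t(Fm) %*% d_box, b = colSums(d_box)),
    fc_head = list(W = t(Fm) %*% d_head, b = colSums(d_head)),
    fc_body = list(W = t(Fm) %*% d_body, b = colSums(d_body))
  )
  dF <- d_det %*% t(p$fc_det$W) + d_box %*% t(p$fc_box$W) +
    d_head %*% t(p$fc_head$W) + d_body %*% t(p$fc_body$W)
  dKa <- 0 * p$resA$W; dba <- numeric(C)
  dKb <- 0 * p$resB$W; dbb <- numeric(C)
  droi <- array(0, c(S, S, C, n))
  for (i in seq_len(n)) {
    rc <- fw$rcache[[i]]
    dY <- array(rep(dF[i, ] / (S * S), each = S * S), c(S, S, C))
    dypre <- dY * (rc$ypre > 0)
    gB <- cn_conv_bwd(rc$a, p$resB$W, dypre, 3L, 1L)
    dKb <- dKb + gB$dK; dbb <- dbb + as.numeric(gB$db)
    da <- gB$dX * (rc$za > 0)
    gA <- cn_conv_bwd(rc$x, p$resA$W, da, 3L, 1L)
    dKa <- dKa + gA$dK; dba <- dba + as.numeric(gA$db)
    droi[, , , i] <- dypre + gA$dX
  }
  grads$resA <- list(W = dKa, b = dba)
  grads$resB <- list(W = dKb, b = dbb)
  dfeat <- cn_roipool_bwd(as.vector(droi), fw$roi_idx,
                          dim(feat)[1], dim(feat)[2], C)
  list(grads = grads, dfeat = dfeat)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(l) lapply(l, function(x) x * 0))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (ln in names(grads)) {
    for (pn in names(grads[[ln]])) {
      g <- grads[[ln]][[pn]]
      m <- beta1 * state$m[[ln]][[pn]] + (1 - beta1) * g
      v <- beta2 * state$v[[ln]][[pn]] + (1 - beta2) * g^2
      state$m[[ln]][[pn]] <- m
      state$v[[ln]][[pn]] <- v
      params[[ln]][[pn]] <- params[[ln]][[pn]] -
        lr * (m / c1) / (sqrt(v / c2) + eps)
    }
  }
  list(params = params, state = state)
}

# elementwise sum of two nested grad lists
grads_add <- function(a, b) {
  for (ln in names(b)) {
    if (is.null(a[[ln]])) a[[ln]] <- b[[ln]]
    else for (pn in names(b[[ln]])) {
      a[[ln]][[pn]] <- a[[ln]][[pn]] + b[[ln]][[pn]]
    }
  }
  a
}
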