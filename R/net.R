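## Keypoint-regression network: encoder of four bottleneck residual blocks
## (32, 64, 128, 256 channels, stride-2 spatial reduction per block), global
## average pooling, and a decoder of three fully connected layers (288, 144,
## 72 units). Batch normalization precedes every convolutional and fully
## connected layer and leaky rectifier activations (slope 0.01) follow them;
## the 72-vector output passes through a sigmoid scaled to [0, 141] and is
## reshaped to three 2 x 12 keypoint matrices (10 backbone + 2 eye points
## per camera view).
##
## Implemented natively: feature tensors are arrays (C, H, W, N) and
## convolutions are evaluated as sums of 9 shifted matrix products, with
## hand-written backward passes and an Adam optimizer.

#' Network architecture specification
#'
#' @param input_size input image side, px. Images rendered at 141 px may be
#'   downscaled (mean pooling) before entering the network; keypoint outputs
#'   always live on the [0, 141] scale.
#' @param channels output channels of the four bottleneck blocks.
#' @param fc sizes of the three fully connected decoder layers; the last must
#'   be 72 = 3 views x 12 keypoints x 2 coordinates.
#' @param expansion bottleneck expansion factor (internal channels =
#'   channels / expansion).
#' @param slope negative slope of the leaky rectifier.
#' @param out_scale sigmoid output scale (141: the crop side).
#' @return an object of class \code{pose_net_spec}.
#' @export
pose_net_spec <- function(input_size = 141L, channels = c(32L, 64L, 128L, 256L),
                          fc = c(288L, 144L, 72L), expansion = 4L,
                          slope = 0.01, out_scale = 141) {
  stopifnot(length(channels) == 4L, length(fc) == 3L,
            fc[3L] == 72L, all(channels %% expansion == 0))
  structure(list(input_size = as.integer(input_size), channels = channels,
                 fc = fc, expansion = expansion, slope = slope,
                 out_scale = out_scale),
            class = "pose_net_spec")
}

conv_out_size <- function(h) (h - 1L) %/% 2L + 1L

he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

new_bn <- function(c_) {
  list(gamma = rep(1, c_), beta = rep(0, c_),
       run_mean = rep(0, c_), run_var = rep(1, c_))
}

#' Initialize network weights
#'
#' He-normal initialization, seeded for reproducibility.
#'
#' @param spec a \code{pose_net_spec}.
#' @param seed RNG seed.
#' @return an object of class \code{pose_net}: weights plus the spec.
#' @export
pose_net_init <- function(spec = pose_net_spec(), seed = 1L) {
  set.seed(seed)
  c_in <- 3L
  blocks <- vector("list", 4L)
  for (b in 1:4) {
    c_out <- spec$channels[b]
    c_mid <- c_out %/% spec$expansion
    blocks[[b]] <- list(
      bn1 = new_bn(c_in),
      w1 = he_init(c_in, c(c_mid, c_in)), b1 = rep(0, c_mid),
      bn2 = new_bn(c_mid),
      w2 = he_init(c_mid * 9L, c(c_mid, c_mid, 3L, 3L)), b2 = rep(0, c_mid),
      bn3 = new_bn(c_mid),
      w3 = he_init(c_mid, c(c_out, c_mid)), b3 = rep(0, c_out),
      ws = he_init(c_in, c(c_out, c_in)), bs = rep(0, c_out))
    c_in <- c_out
  }
  fcs <- vector("list", 3L)
  f_in <- spec$channels[4L]
  for (i in 1:3) {
    fcs[[i]] <- list(bn = new_bn(f_in),
                     w = he_init(f_in, c(spec$fc[i], f_in)),
                     b = rep(0, spec$fc[i]))
    f_in <- spec$fc[i]
  }
  structure(list(spec = spec, blocks = blocks, fcs = fcs, trained = FALSE),
            class = "pose_net")
}

#' @export
print.pose_net <- function(x, ...) {
  cat(sprintf("<pose_net> input %dx%dx3, blocks %s, fc %s%s\n",
              x$spec$input_size, x$spec$input_size,
              paste(x$spec$channels, collapse = "-"),
              paste(x$spec$fc, collapse = "-"),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

## ---- layer primitives -----------------------------------------------------
## x: array (C, H, W, N); matrices are (C, M) with M = H*W*N.

bn_forward <- function(bn, x_mat, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(x_mat)
    xc <- x_mat - mu
    v <- rowMeans(xc * xc)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
    xc <- x_mat - mu
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = xhat * bn$gamma + bn$beta, xhat = xhat, inv = inv, bn = bn)
}

bn_backward <- function(cache, dy) {
  m <- ncol(dy)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$bn$gamma
  dx <- cache$inv * (dxhat - rowSums(dxhat) / m -
                       cache$xhat * rowSums(dxhat * cache$xhat) / m)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

lrelu_forward <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, neg = neg)
}

lrelu_backward <- function(cache, dy, slope) {
  dy[cache$neg] <- dy[cache$neg] * slope
  dy
}

## 3x3 stride-2 pad-1 convolution as 9 shifted matrix products.
conv3_forward <- function(x, w, b) {
  d <- dim(x); C <- d[1L]; H <- d[2L]; W_ <- d[3L]; N <- d[4L]
  Ho <- conv_out_size(H); Wo <- conv_out_size(W_)
  Cout <- dim(w)[1L]
  xp <- array(0, c(C, H + 2L, W_ + 2L, N))
  xp[, 2:(H + 1L), 2:(W_ + 1L), ] <- x
  y <- matrix(0, Cout, Ho * Wo * N)
  slices <- vector("list", 9L)
  for (di in 1:3) for (dj in 1:3) {
    ri <- seq.int(di, by = 2L, length.out = Ho)
    ci <- seq.int(dj, by = 2L, length.out = Wo)
    xs <- matrix(xp[, ri, ci, , drop = FALSE], C)
    slices[[(di - 1L) * 3L + dj]] <- xs
    y <- y + w[, , di, dj] %*% xs
  }
  y <- y + b
  dim(y) <- c(Cout, Ho, Wo, N)
  list(y = y, slices = slices, in_dim = d)
}

conv3_backward <- function(cache, w, dy) {
  d <- cache$in_dim; C <- d[1L]; H <- d[2L]; W_ <- d[3L]; N <- d[4L]
  Ho <- conv_out_size(H); Wo <- conv_out_size(W_)
  Cout <- dim(w)[1L]
  dy_mat <- matrix(dy, Cout)
  dw <- array(0, dim(w))
  dxp <- array(0, c(C, H + 2L, W_ + 2L, N))
  for (di in 1:3) for (dj in 1:3) {
    xs <- cache$slices[[(di - 1L) * 3L + dj]]
    dw[, , di, dj] <- tcrossprod(dy_mat, xs)
    dxs <- crossprod(w[, , di, dj], dy_mat)
    dim(dxs) <- c(C, Ho, Wo, N)
    ri <- seq.int(di, by = 2L, length.out = Ho)
    ci <- seq.int(dj, by = 2L, length.out = Wo)
    dxp[, ri, ci, ] <- dxp[, ri, ci, , drop = FALSE] + dxs
  }
  list(dx = dxp[, 2:(H + 1L), 2:(W_ + 1L), , drop = FALSE],
       dw = dw, db = rowSums(dy_mat))
}

## 1x1 convolution, optional stride-2 subsampling.
conv1_forward <- function(x, w, b, stride = 1L) {
  d <- dim(x)
  if (stride == 2L) {
    ri <- seq.int(1L, d[2L], by = 2L)
    ci <- seq.int(1L, d[3L], by = 2L)
    x <- x[, ri, ci, , drop = FALSE]
    d <- dim(x)
  }
  xm <- matrix(x, d[1L])
  y <- w %*% xm + b
  dim(y) <- c(nrow(w), d[2L], d[3L], d[4L])
  list(y = y, xm = xm, dim_in = d)
}

conv1_backward <- function(cache, w, dy, full_dim = NULL) {
  dy_mat <- matrix(dy, nrow(w))
  dw <- tcrossprod(dy_mat, cache$xm)
  dx <- crossprod(w, dy_mat)
  dim(dx) <- cache$dim_in
  if (!is.null(full_dim)) {                 # scatter back through the stride
    dx_full <- array(0, full_dim)
    ri <- seq.int(1L, full_dim[2L], by = 2L)
    ci <- seq.int(1L, full_dim[3L], by = 2L)
    dx_full[, ri, ci, ] <- dx
    dx <- dx_full
  }
  list(dx = dx, dw = dw, db = rowSums(dy_mat))
}

gap_forward <- function(x) {
  d <- dim(x)
  hw <- d[2L] * d[3L]
  y <- colMeans(matrix(aperm(x, c(2L, 3L, 1L, 4L)), hw))
  dim(y) <- c(d[1L], d[4L])
  list(y = y, in_dim = d)
}

gap_backward <- function(cache, dy) {
  d <- cache$in_dim
  hw <- d[2L] * d[3L]
  ## broadcast dy (C, N) / HW over the spatial dimensions
  aperm(array(t(matrix(dy / hw, d[1L], d[4L])),
              c(d[4L], d[1L], d[2L], d[3L])), c(2L, 3L, 4L, 1L))
}

## ---- forward / backward through the whole network -------------------------

block_forward <- function(blk, x, slope, training) {
  d <- dim(x)
  xm <- matrix(x, d[1L])
  c1 <- bn_forward(blk$bn1, xm, training); blk$bn1 <- c1$bn
  a1 <- lrelu_forward(c1$y, slope)
  h1 <- a1$y; dim(h1) <- d
  r1 <- conv1_forward(h1, blk$w1, blk$b1)
  d2 <- dim(r1$y)
  c2 <- bn_forward(blk$bn2, matrix(r1$y, d2[1L]), training); blk$bn2 <- c2$bn
  a2 <- lrelu_forward(c2$y, slope)
  h2 <- a2$y; dim(h2) <- d2
  r2 <- conv3_forward(h2, blk$w2, blk$b2)
  d3 <- dim(r2$y)
  c3 <- bn_forward(blk$bn3, matrix(r2$y, d3[1L]), training); blk$bn3 <- c3$bn
  a3 <- lrelu_forward(c3$y, slope)
  h3 <- a3$y; dim(h3) <- d3
  r3 <- conv1_forward(h3, blk$w3, blk$b3)
  rs <- conv1_forward(h1, blk$ws, blk$bs, stride = 2L)
  y <- r3$y + rs$y
  list(y = y, blk = blk,
       cache = list(d = d, c1 = c1, a1 = a1, r1 = r1, d2 = d2, c2 = c2,
                    a2 = a2, r2 = r2, d3 = d3, c3 = c3, a3 = a3, r3 = r3,
                    rs = rs))
}

block_backward <- function(blk, cache, dy, slope) {
  g <- list()
  b3 <- conv1_backward(cache$r3, blk$w3, dy)
  g$w3 <- b3$dw; g$b3 <- b3$db
  bs <- conv1_backward(cache$rs, blk$ws, dy, full_dim = cache$d)
  g$ws <- bs$dw; g$bs <- bs$db
  da3 <- lrelu_backward(cache$a3, matrix(b3$dx, cache$d3[1L]), slope)
  bb3 <- bn_backward(cache$c3, da3)
  g$bn3_gamma <- bb3$dgamma; g$bn3_beta <- bb3$dbeta
  dr2 <- bb3$dx; dim(dr2) <- cache$d3
  b2 <- conv3_backward(cache$r2, blk$w2, dr2)
  g$w2 <- b2$dw; g$b2 <- b2$db
  da2 <- lrelu_backward(cache$a2, matrix(b2$dx, cache$d2[1L]), slope)
  bb2 <- bn_backward(cache$c2, da2)
  g$bn2_gamma <- bb2$dgamma; g$bn2_beta <- bb2$dbeta
  dr1 <- bb2$dx; dim(dr1) <- cache$d2
  b1 <- conv1_backward(cache$r1, blk$w1, dr1)
  g$w1 <- b1$dw; g$b1 <- b1$db
  dh1 <- b1$dx + bs$dx
  da1 <- lrelu_backward(cache$a1, matrix(dh1, cache$d[1L]), slope)
  bb1 <- bn_backward(cache$c1, da1)
  g$bn1_gamma <- bb1$dgamma; g$bn1_beta <- bb1$dbeta
  dx <- bb1$dx; dim(dx) <- cache$d
  list(dx = dx, grads = g)
}

net_forward <- function(net, x, training = FALSE) {
  slope <- net$spec$slope
  caches <- vector("list", 4L)
  for (b in 1:4) {
    bf <- block_forward(net$blocks[[b]], x, slope, training)
    x <- bf$y
    net$blocks[[b]] <- bf$blk
    caches[[b]] <- bf$cache
  }
  gp <- gap_forward(x)
  z <- gp$y
  fcc <- vector("list", 3L)
  for (i in 1:3) {
    fc <- net$fcs[[i]]
    cb <- bn_forward(fc$bn, z, training); net$fcs[[i]]$bn <- cb$bn
    al <- lrelu_forward(cb$y, slope)
    zz <- fc$w %*% al$y + fc$b
    fcc[[i]] <- list(cb = cb, al = al, zin = al$y)
    z <- zz
  }
  sg <- 1 / (1 + exp(-z))
  out <- net$spec$out_scale * sg
  list(out = out, net = net,
       cache = list(blocks = caches, gap = gp, fcs = fcc, sg = sg))
}

net_backward <- function(net, cache, dout) {
  slope <- net$spec$slope
  dz <- dout * net$spec$out_scale * cache$sg * (1 - cache$sg)
  grads <- list(fcs = vector("list", 3L), blocks = vector("list", 4L))
  for (i in 3:1) {
    fc <- net$fcs[[i]]
    cc <- cache$fcs[[i]]
    dw <- tcrossprod(dz, cc$zin)
    db <- rowSums(dz)
    dal <- crossprod(fc$w, dz)
    da <- lrelu_backward(cc$al, dal, slope)
    bb <- bn_backward(cc$cb, da)
    grads$fcs[[i]] <- list(w = dw, b = db, bn_gamma = bb$dgamma,
                           bn_beta = bb$dbeta)
    dz <- bb$dx
  }
  dx <- gap_backward(cache$gap, dz)
  for (b in 4:1) {
    bk <- block_backward(net$blocks[[b]], cache$blocks[[b]], dx, slope)
    grads$blocks[[b]] <- bk$grads
    dx <- bk$dx
  }
  grads
}

## ---- loss -----------------------------------------------------------------

## reshape a (72, N) output into an array (2, 12, 3, N): per view, columns
## 1..10 backbone, 11..12 eyes
reshape_keypoints <- function(out) {
  n <- ncol(out)
  array(out, c(2L, 12L, 3L, n))
}

#' Backbone loss: RMSE over the 10 backbone keypoints of all three views
#'
#' @param pred,truth arrays (2, 12, 3) or (2, 12, 3, N) of keypoints, px.
#' @return scalar: RMSE over the 60 backbone coordinates (mean over the
#'   batch when 4-D).
#' @export
backbone_loss <- function(pred, truth) {
  if (length(dim(pred)) == 3L) { dim(pred) <- c(dim(pred), 1L)
                                 dim(truth) <- dim(pred) }
  e <- pred[, 1:10, , , drop = FALSE] - truth[, 1:10, , , drop = FALSE]
  n <- dim(e)[4L]
  mean(sqrt(colMeans(matrix(e^2, 60L))))
}

#' Eye loss: per-camera minimum over the two eye assignments
#'
#' For each camera view, the RMSE between the predicted eye pair and the
#' ground-truth pair is evaluated under both labelings (identity and
#' swapped) and the smaller value is kept; the per-camera minima are summed.
#' This makes the loss symmetric under eye relabeling.
#'
#' @param pred,truth arrays (2, 12, 3) or (2, 12, 3, N).
#' @return scalar (mean over the batch when 4-D).
#' @export
eye_loss <- function(pred, truth) {
  if (length(dim(pred)) == 3L) { dim(pred) <- c(dim(pred), 1L)
                                 dim(truth) <- dim(pred) }
  p <- pred[, 11:12, , , drop = FALSE]
  g <- truth[, 11:12, , , drop = FALSE]
  gs <- g[, c(2L, 1L), , , drop = FALSE]
  n <- dim(p)[4L]
  per_cam <- function(err) sqrt(colMeans(matrix(err^2, 4L)))  # (3*N)
  r_id <- matrix(per_cam(p - g), 3L, n)
  r_sw <- matrix(per_cam(p - gs), 3L, n)
  mean(colSums(pmin(r_id, r_sw)))
}

#' Total training loss
#'
#' backbone_loss + lambda * eye_loss.
#'
#' @param pred,truth keypoint arrays as in [backbone_loss()].
#' @param lambda eye-loss weight (default 5).
#' @return scalar.
#' @export
total_loss <- function(pred, truth, lambda = 5) {
  stopifnot(lambda >= 0)
  backbone_loss(pred, truth) + lambda * eye_loss(pred, truth)
}

## loss and gradient wrt pred, arrays (2, 12, 3, N); mean over batch
loss_grad <- function(pred, truth, lambda) {
  dm <- dim(pred)
  n <- dm[4L]
  e <- pred - truth
  eb <- e; eb[, 11:12, , ] <- 0
  rb <- sqrt(colMeans(matrix(eb[, 1:10, , , drop = FALSE]^2, 60L)))  # per ex
  g <- array(0, dm)
  rb_safe <- pmax(rb, 1e-9)
  g[, 1:10, , ] <- eb[, 1:10, , , drop = FALSE] /
    rep(60 * rb_safe, each = 60L)
  p <- pred[, 11:12, , , drop = FALSE]
  gt <- truth[, 11:12, , , drop = FALSE]
  gs <- gt[, c(2L, 1L), , , drop = FALSE]
  r_id <- matrix(sqrt(colMeans(matrix((p - gt)^2, 4L))), 3L, n)
  r_sw <- matrix(sqrt(colMeans(matrix((p - gs)^2, 4L))), 3L, n)
  use_sw <- r_sw < r_id
  r_min <- pmin(r_id, r_sw)
  ge <- array(0, dim(p))
  for (cam in 1:3) for (ex in seq_len(n)) {
    err <- if (use_sw[cam, ex]) p[, , cam, ex] - gs[, , cam, ex]
           else p[, , cam, ex] - gt[, , cam, ex]
    ge[, , cam, ex] <- err / (4 * max(r_min[cam, ex], 1e-9))
  }
  g[, 11:12, , ] <- lambda * ge
  loss <- mean(rb) + lambda * mean(colSums(r_min))
  list(loss = loss, grad = g / n)
}

## ---- Adam -----------------------------------------------------------------

adam_state <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  keys <- names(params)
  for (key in keys) {
    gr <- grads[[key]]
    if (is.null(gr)) next
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- gr * 0
      state$v[[key]] <- gr * 0
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * gr
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * gr^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    params[[key]] <- params[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## flatten network parameters (excluding BN running stats) to a named list
net_params <- function(net) {
  out <- list()
  for (b in 1:4) {
    blk <- net$blocks[[b]]
    for (nm in c("w1", "b1", "w2", "b2", "w3", "b3", "ws", "bs"))
      out[[sprintf("blk%d_%s", b, nm)]] <- blk[[nm]]
    for (bn in c("bn1", "bn2", "bn3")) {
      out[[sprintf("blk%d_%s_gamma", b, bn)]] <- blk[[bn]]$gamma
      out[[sprintf("blk%d_%s_beta", b, bn)]] <- blk[[bn]]$beta
    }
  }
  for (i in 1:3) {
    out[[sprintf("fc%d_w", i)]] <- net$fcs[[i]]$w
    out[[sprintf("fc%d_b", i)]] <- net$fcs[[i]]$b
    out[[sprintf("fc%d_bn_gamma", i)]] <- net$fcs[[i]]$bn$gamma
    out[[sprintf("fc%d_bn_beta", i)]] <- net$fcs[[i]]$bn$beta
  }
  out
}

net_set_params <- function(net, params) {
  for (b in 1:4) {
    for (nm in c("w1", "b1", "w2", "b2", "w3", "b3", "ws", "bs"))
      net$blocks[[b]][[nm]] <- params[[sprintf("blk%d_%s", b, nm)]]
    for (bn in c("bn1", "bn2", "bn3")) {
      net$blocks[[b]][[bn]]$gamma <- params[[sprintf("blk%d_%s_gamma", b, bn)]]
      net$blocks[[b]][[bn]]$beta <- params[[sprintf("blk%d_%s_beta", b, bn)]]
    }
  }
  for (i in 1:3) {
    net$fcs[[i]]$w <- params[[sprintf("fc%d_w", i)]]
    net$fcs[[i]]$b <- params[[sprintf("fc%d_b", i)]]
    net$fcs[[i]]$bn$gamma <- params[[sprintf("fc%d_bn_gamma", i)]]
    net$fcs[[i]]$bn$beta <- params[[sprintf("fc%d_bn_beta", i)]]
  }
  net
}

grads_flat <- function(grads) {
  out <- list()
  for (b in 1:4) {
    g <- grads$blocks[[b]]
    for (nm in c("w1", "b1", "w2", "b2", "w3", "b3", "ws", "bs"))
      out[[sprintf("blk%d_%s", b, nm)]] <- g[[nm]]
    for (bn in c("bn1", "bn2", "bn3")) {
      out[[sprintf("blk%d_%s_gamma", b, bn)]] <- g[[sprintf("%s_gamma", bn)]]
      out[[sprintf("blk%d_%s_beta", b, bn)]] <- g[[sprintf("%s_beta", bn)]]
    }
  }
  for (i in 1:3) {
    out[[sprintf("fc%d_w", i)]] <- grads$fcs[[i]]$w
    out[[sprintf("fc%d_b", i)]] <- grads$fcs[[i]]$b
    out[[sprintf("fc%d_bn_gamma", i)]] <- grads$fcs[[i]]$bn_gamma
    out[[sprintf("fc%d_bn_beta", i)]] <- grads$fcs[[i]]$bn_beta
  }
  out
}

## ---- data plumbing --------------------------------------------------------

## mean-pool an image matrix by an integer factor (after trimming to a
## multiple of the factor)
downscale_image <- function(img, factor) {
  if (factor == 1L) return(img)
  n <- (nrow(img) %/% factor) * factor
  m <- (ncol(img) %/% factor) * factor
  img <- img[seq_len(n), seq_len(m)]
  a <- array(img, c(factor, n %/% factor, factor, m %/% factor))
  colMeans(aperm(a, c(1L, 3L, 2L, 4L)), dims = 2L)
}

#' Pack training examples into network tensors
#'
#' @param examples list of \code{training_example}.
#' @param downscale integer mean-pooling factor applied to the images (the
#'   network input size must match; keypoints stay on the 141 px scale).
#' @return list with \code{x} (3, H, W, N array, unit scale) and \code{y}
#'   (2, 12, 3, N keypoint array, px).
#' @export
pack_examples <- function(examples, downscale = 1L) {
  n <- length(examples)
  img1 <- downscale_image(examples[[1L]]$images[[1L]], downscale)
  h <- nrow(img1); w <- ncol(img1)
  x <- array(0, c(3L, h, w, n))
  y <- array(0, c(2L, 12L, 3L, n))
  for (i in seq_len(n)) {
    ex <- examples[[i]]
    for (k in 1:3) {
      x[k, , , i] <- downscale_image(ex$images[[k]], downscale) / 255
      y[, , k, i] <- t(ex$annotation[[k]])
    }
  }
  list(x = x, y = y)
}

#' Train the keypoint network
#'
#' Seeded minibatch training with Adam on the symmetric keypoint loss,
#' splitting the dataset 9:1 into training and validation parts. The
#' defaults follow the full-scale recipe (learning rate 0.001, batch 300,
#' 120 epochs, lambda = 5); desk-scale runs use fewer examples and epochs
#' and a spatial downscale of the input images.
#'
#' @param net a \code{pose_net} from [pose_net_init()].
#' @param data list with \code{x} and \code{y} from [pack_examples()].
#' @param epochs training epochs.
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param lambda eye-loss weight.
#' @param val_frac validation fraction (default 0.1).
#' @param seed RNG seed for the split and shuffling.
#' @param verbose print per-epoch losses.
#' @return the trained \code{pose_net} with a \code{history} data.frame
#'   (epoch, train_loss, val_loss) attached.
#' @export
pose_net_train <- function(net, data, epochs = 120L, batch = 300L,
                           lr = 0.001, lambda = 5, val_frac = 0.1,
                           seed = 1L, verbose = FALSE) {
  set.seed(seed)
  n <- dim(data$x)[4L]
  idx <- sample.int(n)
  n_val <- max(1L, round(val_frac * n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  state <- adam_state()
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  if (epochs == 0L) {
    net$history <- history
    return(net)
  }
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = batch)) {
      take <- ord[start:min(start + batch - 1L, length(ord))]
      xb <- data$x[, , , take, drop = FALSE]
      yb <- data$y[, , , take, drop = FALSE]
      fw <- net_forward(net, xb, training = TRUE)
      net <- fw$net
      pred <- reshape_keypoints(fw$out)
      lg <- loss_grad(pred, yb, lambda)
      if (!is.finite(lg$loss))
        stop("training diverged: non-finite loss; lower the learning rate")
      dout <- matrix(lg$grad, 72L)
      grads <- net_backward(net, fw$cache, dout)
      upd <- adam_step(net_params(net), grads_flat(grads), state, lr)
      net <- net_set_params(net, upd$params)
      state <- upd$state
      losses <- c(losses, lg$loss)
    }
    val_loss <- pose_net_loss(net, data, val_idx, lambda)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, mean(losses),
                      val_loss))
  }
  net$trained <- TRUE
  net$history <- history
  net
}

## evaluation-mode loss on a subset
pose_net_loss <- function(net, data, idx, lambda = 5, batch = 256L) {
  tot <- 0; m <- 0
  for (start in seq(1L, length(idx), by = batch)) {
    take <- idx[start:min(start + batch - 1L, length(idx))]
    fw <- net_forward(net, data$x[, , , take, drop = FALSE],
                      training = FALSE)
    pred <- reshape_keypoints(fw$out)
    lg <- loss_grad(pred, data$y[, , , take, drop = FALSE], lambda)
    tot <- tot + lg$loss * length(take)
    m <- m + length(take)
  }
  tot / m
}

#' Predict keypoints for view triplets
#'
#' @param net a \code{pose_net}.
#' @param x input: a \code{view_triplet}/\code{training_example}, or an
#'   array (3, H, W, N) on the unit intensity scale matching the network
#'   input size.
#' @param downscale mean-pooling factor applied when \code{x} carries
#'   141 px images and the network expects smaller inputs.
#' @return list of per-example keypoint sets: each a list of three 12 x 2
#'   matrices (crop px in [0, 141]).
#' @export
pose_net_predict <- function(net, x, downscale = 1L) {
  if (inherits(x, c("view_triplet", "training_example"))) {
    arr <- array(0, c(3L, net$spec$input_size, net$spec$input_size, 1L))
    for (k in 1:3)
      arr[k, , , 1L] <- downscale_image(x$images[[k]], downscale) / 255
    x <- arr
  }
  stopifnot(length(dim(x)) == 4L, dim(x)[1L] == 3L)
  fw <- net_forward(net, x, training = FALSE)
  kp <- reshape_keypoints(fw$out)
  lapply(seq_len(dim(kp)[4L]), function(i)
    lapply(1:3, function(k) t(kp[, , k, i])))
}
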