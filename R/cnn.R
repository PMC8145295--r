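## Small trainable convolutional network used by the deep saliency
## segmentation stage and the tiny-cnn feature backbone. Ten layers: input,
## conv1(3x3x3x64)+ReLU, conv2(3x3x64x64)+ReLU, maxpool(2x2/2),
## conv3(3x3x64x128)+ReLU, fully-connected, softmax, output. Implemented in
## base R: same-padding convolutions are im2col patch matrices multiplied by
## the weight matrix (BLAS), training is mini-batch SGD with classical
## momentum (v <- m*v - r*grad; w <- w + v).

#' Hyperparameter specification for the saliency network
#'
#' @param input_size square input side in pixels (divisible by 2; the
#'   desk-scale default is 64, the full-scale reference 224).
#' @param n_classes number of class labels for the softmax head.
#' @param learning_rate SGD learning rate `r` (default 0.001).
#' @param momentum classical momentum coefficient (default 0.9).
#' @param epochs training epochs.
#' @param batch_size mini-batch size (default 28).
#' @param seed seed for weight initialization and batch shuffling.
#' @return object of class `saliency_net_spec`.
#' @export
saliency_net_spec <- function(input_size = 64, n_classes = 2,
                              learning_rate = 0.001, momentum = 0.9,
                              epochs = 5, batch_size = 28, seed = 1) {
  if (input_size %% 2 != 0 || input_size < 8)
    stop("input_size must be even and at least 8")
  if (n_classes < 2) stop("need at least 2 classes")
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed),
            class = "saliency_net_spec")
}

## ---- im2col machinery ------------------------------------------------

## Index matrix mapping each output pixel of an H x W grid to the linear
## indices of its 3x3xC patch inside the zero-padded (H+2) x (W+2) x C
## array. Column order: di fastest, then dj, then channel — matching the
## row order of the (9C) x F weight matrices.
make_im2col_idx <- function(H, W, C) {
  hp <- H + 2L; wp <- W + 2L
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L * C)
  k <- 0L
  for (c in seq_len(C)) {
    ch_off <- (c - 1L) * hp * wp
    for (dj in 0:2) for (di in 0:2) {
      k <- k + 1L
      idx[, k] <- (ii + di) + (jj + dj - 1L) * hp + ch_off
    }
  }
  idx
}

pad_zero <- function(x, H, W, C) {
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  xp
}

conv_forward <- function(x, idx, W_mat, b, H, W, C) {
  xp <- pad_zero(x, H, W, C)
  X2 <- matrix(xp[idx], nrow = H * W)
  out <- X2 %*% W_mat
  out <- sweep(out, 2L, b, "+")
  list(out = out, X2 = X2)
}

## scatter-add the patch-matrix gradient back onto the (unpadded) input
conv_backward_input <- function(dX2, idx, H, W, C) {
  gp <- numeric((H + 2L) * (W + 2L) * C)
  for (k in seq_len(ncol(dX2))) {
    ik <- idx[, k]
    gp[ik] <- gp[ik] + dX2[, k]
  }
  array(gp, c(H + 2L, W + 2L, C))[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

## 2x2/2 max pooling on an (H*W) x F activation matrix; returns pooled
## matrix plus the winner masks needed for the backward pass
maxpool_forward <- function(x, H, W) {
  F_ <- ncol(x)
  a <- array(x, c(H, W, F_))
  o <- seq(1L, H, 2L); e <- seq(2L, H, 2L)
  oc <- seq(1L, W, 2L); ec <- seq(2L, W, 2L)
  m <- list(a[o, oc, , drop = FALSE], a[e, oc, , drop = FALSE],
            a[o, ec, , drop = FALSE], a[e, ec, , drop = FALSE])
  out <- pmax(m[[1]], m[[2]], m[[3]], m[[4]])
  # first-match winner masks (ties resolved in fixed quadrant order)
  taken <- array(FALSE, dim(out))
  win <- vector("list", 4L)
  for (q in 1:4) {
    w <- (m[[q]] == out) & !taken
    win[[q]] <- w
    taken <- taken | w
  }
  list(out = matrix(out, ncol = F_), win = win, H2 = H %/% 2L, W2 = W %/% 2L)
}

maxpool_backward <- function(dout, pool, H, W) {
  F_ <- ncol(dout)
  d <- array(dout, c(pool$H2, pool$W2, F_))
  g <- array(0, c(H, W, F_))
  o <- seq(1L, H, 2L); e <- seq(2L, H, 2L)
  oc <- seq(1L, W, 2L); ec <- seq(2L, W, 2L)
  g[o, oc, ] <- d * pool$win[[1]]
  g[e, oc, ] <- g[e, oc, ] + d * pool$win[[2]]
  g[o, ec, ] <- g[o, ec, ] + d * pool$win[[3]]
  g[e, ec, ] <- g[e, ec, ] + d * pool$win[[4]]
  matrix(g, ncol = F_)
}

#' Build the untrained ten-layer saliency network
#'
#' Weight shapes follow the fixed architecture: conv1 3x3x3x64 (1728
#' weights + 64 biases), conv2 3x3x64x64, maxpool 2x2 stride 2, conv3
#' 3x3x64x128, then a fully connected softmax head. He-normal
#' initialization seeded from the spec.
#'
#' @param spec a [saliency_net_spec()].
#' @return object of class `saliency_net`.
#' @export
build_saliency_net <- function(spec) {
  stopifnot(inherits(spec, "saliency_net_spec"))
  s <- spec$input_size
  s2 <- s %/% 2L
  d_flat <- s2 * s2 * 128L
  with_seed(spec$seed, {
    he <- function(fan_in, n) matrix(stats::rnorm(fan_in * n, 0, sqrt(2 / fan_in)),
                                     fan_in, n)
    net <- list(
      spec = spec,
      W1 = he(27L, 64L), b1 = numeric(64L),
      W2 = he(576L, 64L), b2 = numeric(64L),
      W3 = he(576L, 128L), b3 = numeric(128L),
      Wfc = he(d_flat, spec$n_classes) * 0.1, bfc = numeric(spec$n_classes),
      idx3 = make_im2col_idx(s, s, 3L),
      idx64 = make_im2col_idx(s, s, 64L),
      idx64p = make_im2col_idx(s2, s2, 64L),
      trained = FALSE, classes = NULL, loss_history = numeric(0))
    class(net) <- "saliency_net"
    net
  })
}

#' @export
print.saliency_net <- function(x, ...) {
  s <- x$spec$input_size
  cat("Ten-layer saliency network\n")
  cat(sprintf("  input %dx%dx3 | conv1 3x3x64 | conv2 3x3x64 | pool 2x2 | conv3 3x3x128 | fc %d | softmax\n",
              s, s, x$spec$n_classes))
  cat(sprintf("  trained: %s", if (x$trained) paste(x$classes, collapse = ", ") else "no"), "\n")
  invisible(x)
}

## preprocess an image to the net input: [0,1] scaling, per-image mean
## centering, bilinear resize to the spec size if needed
net_preprocess <- function(image, s) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (dim(image)[1] != s || dim(image)[2] != s) {
    img <- EBImage::Image(image / 255, colormode = "Color")
    image <- as.array(EBImage::resize(img, w = s, h = s)) * 255
  }
  x <- image / 255
  x - mean(x)
}

## forward pass; returns activations needed for backprop or saliency
net_forward <- function(net, x, upto = c("logits", "conv3")) {
  upto <- match.arg(upto)
  s <- net$spec$input_size; s2 <- s %/% 2L
  c1 <- conv_forward(x, net$idx3, net$W1, net$b1, s, s, 3L)
  a1 <- pmax(c1$out, 0)
  c2 <- conv_forward(array(a1, c(s, s, 64L)), net$idx64, net$W2, net$b2, s, s, 64L)
  a2 <- pmax(c2$out, 0)
  pool <- maxpool_forward(a2, s, s)
  c3 <- conv_forward(array(pool$out, c(s2, s2, 64L)), net$idx64p, net$W3,
                     net$b3, s2, s2, 64L)
  a3 <- pmax(c3$out, 0)
  if (upto == "conv3")
    return(list(a3 = a3, H3 = s2, W3 = s2))
  flat <- as.vector(a3)
  logits <- drop(crossprod(net$Wfc, flat)) + net$bfc
  list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, pool = pool, c3 = c3, a3 = a3,
       flat = flat, logits = logits)
}

## backward pass for one sample; returns per-parameter gradients
net_backward <- function(net, x, fwd, y_onehot) {
  s <- net$spec$input_size; s2 <- s %/% 2L
  p <- exp(fwd$logits - max(fwd$logits)); p <- p / sum(p)
  dlogits <- p - y_onehot
  gWfc <- tcrossprod(fwd$flat, dlogits)
  gbfc <- dlogits
  dflat <- drop(net$Wfc %*% dlogits)
  da3 <- matrix(dflat, nrow = s2 * s2)
  dz3 <- da3 * (fwd$c3$out > 0)
  gW3 <- crossprod(fwd$c3$X2, dz3)
  gb3 <- colSums(dz3)
  dX2_3 <- tcrossprod(dz3, net$W3)
  dpool_in <- conv_backward_input(dX2_3, net$idx64p, s2, s2, 64L)
  da2 <- maxpool_backward(matrix(dpool_in, ncol = 64L), fwd$pool, s, s)
  dz2 <- da2 * (fwd$c2$out > 0)
  gW2 <- crossprod(fwd$c2$X2, dz2)
  gb2 <- colSums(dz2)
  dX2_2 <- tcrossprod(dz2, net$W2)
  da1 <- conv_backward_input(dX2_2, net$idx64, s, s, 64L)
  dz1 <- matrix(da1, ncol = 64L) * (fwd$c1$out > 0)
  gW1 <- crossprod(fwd$c1$X2, dz1)
  gb1 <- colSums(dz1)
  loss <- -log(max(sum(p * y_onehot), 1e-12))
  list(gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2, gW3 = gW3, gb3 = gb3,
       gWfc = gWfc, gbfc = gbfc, loss = loss)
}

#' One SGD-with-momentum parameter update
#'
#' The classical update: `v <- momentum * v - rate * grad`,
#' `w <- w + v`. Exported so the optimizer arithmetic is directly testable
#' on toy objectives.
#' @param w parameter (numeric vector/matrix).
#' @param v velocity of the same shape.
#' @param grad gradient of the same shape.
#' @param rate learning rate.
#' @param momentum momentum coefficient.
#' @return list with updated `w` and `v`.
#' @export
sgd_momentum_step <- function(w, v, grad, rate, momentum) {
  v <- momentum * v - rate * grad
  list(w = w + v, v = v)
}

#' Train the saliency network with mini-batch SGD + momentum
#'
#' Images are scaled to \[0, 1\], mean-centered per image, and resized to
#' the spec input size when needed. The softmax head is trained on the
#' image-level class labels; the per-epoch mean cross-entropy loss is
#' recorded in `loss_history`.
#'
#' @param net a [build_saliency_net()] network.
#' @param images list of images (matrices or H x W x 3 arrays in \[0, 255\]).
#' @param class_labels factor/character vector of per-image labels
#'   (at least two distinct classes).
#' @param epochs,learning_rate,batch_size optional overrides of the spec.
#' @return the trained network (with `loss_history` and `classes` filled).
#' @export
train_saliency_net <- function(net, images, class_labels,
                               epochs = NULL, learning_rate = NULL,
                               batch_size = NULL) {
  stopifnot(inherits(net, "saliency_net"))
  labels <- factor(class_labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes to train")
  if (nlevels(labels) != net$spec$n_classes)
    stop("spec n_classes (", net$spec$n_classes, ") != observed classes (",
         nlevels(labels), ")")
  spec <- net$spec
  if (is.null(epochs)) epochs <- spec$epochs
  if (is.null(learning_rate)) learning_rate <- spec$learning_rate
  if (is.null(batch_size)) batch_size <- spec$batch_size
  s <- spec$input_size
  xs <- lapply(images, net_preprocess, s = s)
  y <- as.integer(labels)
  K <- nlevels(labels)
  par_names <- c("W1", "b1", "W2", "b2", "W3", "b3", "Wfc", "bfc")
  vel <- lapply(par_names, function(nm) net[[nm]] * 0)
  names(vel) <- par_names
  n <- length(xs)
  hist <- numeric(epochs)
  with_seed(spec$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        batch <- ord[start:min(start + batch_size - 1L, n)]
        grads <- NULL
        for (i in batch) {
          fwd <- net_forward(net, xs[[i]])
          oh <- numeric(K); oh[y[i]] <- 1
          g <- net_backward(net, xs[[i]], fwd, oh)
          ep_loss <- ep_loss + g$loss
          if (is.null(grads)) {
            grads <- g
          } else {
            for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + g[[nm]]
          }
        }
        bs <- length(batch)
        for (nm in par_names) {
          up <- sgd_momentum_step(net[[nm]], vel[[nm]],
                                  grads[[paste0("g", nm)]] / bs,
                                  learning_rate, spec$momentum)
          net[[nm]] <- up$w
          vel[[nm]] <- up$v
        }
      }
      hist[ep] <- ep_loss / n
    }
  })
  net$trained <- TRUE
  net$classes <- levels(labels)
  net$loss_history <- c(net$loss_history, hist)
  net
}

#' Predict class labels with the saliency network head
#' @param object trained `saliency_net`.
#' @param images list of images.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.saliency_net <- function(object, images, ...) {
  if (!object$trained) stop("network is untrained")
  s <- object$spec$input_size
  out <- vapply(images, function(im) {
    fwd <- net_forward(object, net_preprocess(im, s))
    which.max(fwd$logits)
  }, integer(1))
  factor(object$classes[out], levels = object$classes)
}

#' Compute the fused conv3 saliency map of an image
#'
#' Each of the 128 third-convolution channels is min-max normalized,
#' the channels are averaged into one map, bilinearly upsampled to the
#' network input size, and min-max normalized again. A constant map (e.g.
#' all-zero conv3 activations) normalizes to all zeros by convention.
#'
#' @param net trained `saliency_net`.
#' @param image matrix or RGB array in \[0, 255\].
#' @return H x W matrix in \[0, 1\] (H = W = spec input size).
#' @export
compute_saliency_map <- function(net, image) {
  stopifnot(inherits(net, "saliency_net"))
  if (!net$trained) stop("network is untrained; train_saliency_net() first")
  if (any(!is.finite(net$W3))) stop("network weights are not finite")
  s <- net$spec$input_size
  fwd <- net_forward(net, net_preprocess(image, s), upto = "conv3")
  a <- fwd$a3  # (s/2)^2 x 128
  normed <- apply(a, 2L, minmax01)
  fusedv <- rowMeans(normed)
  small <- matrix(fusedv, fwd$H3, fwd$W3)
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(small), w = s, h = s))
  minmax01(up)
}

#' Global-average-pooled conv3 embedding (tiny-cnn backbone)
#' @param net trained `saliency_net`.
#' @param image matrix or RGB array in \[0, 255\].
#' @return numeric vector of length 128.
#' @keywords internal
tiny_cnn_embedding <- function(net, image) {
  s <- net$spec$input_size
  fwd <- net_forward(net, net_preprocess(image, s), upto = "conv3")
  colMeans(fwd$a3)
}
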