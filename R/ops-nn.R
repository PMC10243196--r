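# Autograd wrappers around the compiled tensor kernels, plus the two
# normalization layers implemented vectorized in R. All tensors are
# (H, W, C, N) arrays.

ag_conv2d <- function(tape, x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- ag_val(x); wv <- ag_val(w)
  bv <- if (is.null(b)) numeric(0) else ag_val(b)
  out <- cpp_conv2d_fw(xv, wv, bv, as.integer(stride), as.integer(pad))
  ag_op(tape, list(x, w, b), out, function(g) {
    gr <- cpp_conv2d_bw(xv, wv, g, as.integer(stride), as.integer(pad))
    list(gr$gx, gr$gw, if (is.null(b)) NULL else gr$gb)
  })
}

ag_dwconv <- function(tape, x, w, b = NULL, pad = 1L) {
  xv <- ag_val(x); wv <- ag_val(w)
  bv <- if (is.null(b)) numeric(0) else ag_val(b)
  out <- cpp_dwconv_fw(xv, wv, bv, as.integer(pad))
  ag_op(tape, list(x, w, b), out, function(g) {
    gr <- cpp_dwconv_bw(xv, wv, g, as.integer(pad))
    list(gr$gx, gr$gw, if (is.null(b)) NULL else gr$gb)
  })
}

ag_deform_conv <- function(tape, x, off, mask, w, b = NULL) {
  xv <- ag_val(x); ov <- ag_val(off); mv <- ag_val(mask); wv <- ag_val(w)
  bv <- if (is.null(b)) numeric(0) else ag_val(b)
  out <- cpp_deform_fw(xv, ov, mv, wv, bv)
  ag_op(tape, list(x, off, mask, w, b), out, function(g) {
    gr <- cpp_deform_bw(xv, ov, mv, wv, g)
    list(gr$gx, gr$goff, gr$gmask, gr$gw, if (is.null(b)) NULL else gr$gb)
  })
}

ag_maxpool2 <- function(tape, x) {
  xv <- ag_val(x)
  fw <- cpp_maxpool2_fw(xv)
  ag_op(tape, list(x), fw$out, function(g) {
    list(cpp_maxpool2_bw(g, fw$idx, dim(xv)))
  })
}

ag_up2 <- function(tape, x) {
  xv <- ag_val(x)
  ag_op(tape, list(x), cpp_up2_fw(xv), function(g) list(cpp_up2_bw(g)))
}

#' Fixed-kernel separable-free 2-D filtering (same zero padding), used by the
#' windowed SSIM; `kern` is a constant K x K matrix, applied per channel.
#' The adjoint is filtering with the flipped kernel.
#' @keywords internal
ag_filter_fixed <- function(tape, x, kern) {
  xv <- ag_val(x)
  d <- dim(xv)
  K <- nrow(kern)
  pad <- (K - 1L) %/% 2L
  wrep <- array(kern, dim = c(K, K, d[3]))
  out <- cpp_dwconv_fw(xv, wrep, numeric(0), pad)
  kflip <- kern[K:1, K:1, drop = FALSE]
  wflip <- array(kflip, dim = c(K, K, d[3]))
  ag_op(tape, list(x), out, function(g) {
    list(cpp_dwconv_fw(g, wflip, numeric(0), pad))
  })
}

# -- normalization ------------------------------------------------------------

#' Instance normalization with affine parameters
#'
#' Standardizes each (sample, channel) plane by its own spatial mean and
#' variance; no running statistics are tracked (small-batch setting).
#' @keywords internal
ag_instance_norm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- ag_val(x); gv <- ag_val(gamma); bv <- ag_val(beta)
  d <- dim(xv)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- xv; dim(xm) <- c(HW, C * N)
  mu <- colMeans(xm)
  va <- colMeans(xm * xm) - mu * mu
  inv <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = HW)) * rep(inv, each = HW)
  gcol <- rep(gv, times = N); bcol <- rep(bv, times = N)
  out <- xhat * rep(gcol, each = HW) + rep(bcol, each = HW)
  dim(out) <- d
  ag_op(tape, list(x, gamma, beta), out, function(g) {
    gm <- g; dim(gm) <- c(HW, C * N)
    dgam <- rowSums(matrix(colSums(gm * xhat), C, N))
    dbet <- rowSums(matrix(colSums(gm), C, N))
    dxh <- gm * rep(gcol, each = HW)
    s1 <- colSums(dxh) / HW
    s2 <- colSums(dxh * xhat) / HW
    dx <- rep(inv, each = HW) *
      (dxh - rep(s1, each = HW) - xhat * rep(s2, each = HW))
    dim(dx) <- d
    list(dx, dgam, dbet)
  })
}

#' Batch normalization with affine parameters and running statistics
#'
#' Statistics are taken over (H, W, N) per channel in training mode; the
#' exponential running averages kept in `state` are used in eval mode.
#' @keywords internal
ag_batch_norm <- function(tape, x, gamma, beta, state, training = TRUE,
                          eps = 1e-5, momentum = 0.1) {
  xv <- ag_val(x); gv <- ag_val(gamma); bv <- ag_val(beta)
  d <- dim(xv)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  cnt <- HW * N
  xm <- xv; dim(xm) <- c(HW, C * N)
  if (training) {
    mu <- rowSums(matrix(colSums(xm), C, N)) / cnt
    va <- rowSums(matrix(colSums(xm * xm), C, N)) / cnt - mu * mu
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * va
  } else {
    mu <- state$rm
    va <- state$rv
  }
  inv <- 1 / sqrt(va + eps)
  mu_col <- rep(mu, times = N); inv_col <- rep(inv, times = N)
  xhat <- (xm - rep(mu_col, each = HW)) * rep(inv_col, each = HW)
  gcol <- rep(gv, times = N); bcol <- rep(bv, times = N)
  out <- xhat * rep(gcol, each = HW) + rep(bcol, each = HW)
  dim(out) <- d
  ag_op(tape, list(x, gamma, beta), out, function(g) {
    gm <- g; dim(gm) <- c(HW, C * N)
    dgam <- rowSums(matrix(colSums(gm * xhat), C, N))
    dbet <- rowSums(matrix(colSums(gm), C, N))
    dxh <- gm * rep(gcol, each = HW)
    if (training) {
      s1 <- rep(rowSums(matrix(colSums(dxh), C, N)) / cnt, times = N)
      s2 <- rep(rowSums(matrix(colSums(dxh * xhat), C, N)) / cnt, times = N)
      dx <- rep(inv_col, each = HW) *
        (dxh - rep(s1, each = HW) - xhat * rep(s2, each = HW))
    } else {
      dx <- dxh * rep(inv_col, each = HW)
    }
    dim(dx) <- d
    list(dx, dgam, dbet)
  })
}
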