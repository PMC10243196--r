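#' U-Net semantic segmentation model (background / crop / weed)
#'
#' Canonical 4-stage U-Net: double 3x3 conv + batch norm + ReLU blocks, 2x2 max-pool
#' downsampling with width doubling from `base` channels, bilinear x2
#' upsampling followed by a 3x3 conv and skip concatenation on the way up,
#' and a final 1x1 convolution to `cls` channels with a per-pixel softmax.
#'
#' @param base first-stage width (64 in the classic design; small values are
#'   convenient for desk-scale experiments)
#' @param cls number of classes (3: background, crop, weed)
#' @param seed optional seed for weight initialization
#' @return object of class `unet_model`
#' @export
unet <- function(base = 64L, cls = 3L, seed = NULL) {
  if (base < 1) stop("base width must be positive")
  build <- function() {
    dbl <- function(cin, cout) list(
      c1 = nn_conv(3, 3, cin, cout, bias = TRUE),
      n1 = nn_norm(cout, "batch"),
      c2 = nn_conv(3, 3, cout, cout, bias = TRUE),
      n2 = nn_norm(cout, "batch"))
    w <- base * c(1L, 2L, 4L, 8L, 16L)
    list(
      enc = list(dbl(3, w[1]), dbl(w[1], w[2]), dbl(w[2], w[3]), dbl(w[3], w[4])),
      bott = dbl(w[4], w[5]),
      upconv = list(nn_conv(3, 3, w[5], w[4], bias = TRUE),
                    nn_conv(3, 3, w[4], w[3], bias = TRUE),
                    nn_conv(3, 3, w[3], w[2], bias = TRUE),
                    nn_conv(3, 3, w[2], w[1], bias = TRUE)),
      updbl = list(dbl(2L * w[4], w[4]), dbl(2L * w[3], w[3]),
                   dbl(2L * w[2], w[2]), dbl(2L * w[1], w[1])),
      # zero-init classifier head: training starts from uniform class
      # probabilities, which keeps the class-balanced Dice gradients alive
      head = nn_conv(1, 1, w[1], cls, bias = TRUE, zero = TRUE))
  }
  net <- if (is.null(seed)) build() else with_seed(seed, build())
  model <- c(net, list(descriptor = list(arch = "unet", base = as.integer(base),
                                         cls = as.integer(cls))))
  class(model) <- "unet_model"
  model
}

#' @export
print.unet_model <- function(x, ...) {
  d <- x$descriptor
  cat(sprintf("U-Net segmenter: base width %d, %d classes, %s parameters\n",
              d$base, d$cls, format(count_params(x), big.mark = ",")))
  invisible(x)
}

unet_dbl_forward <- function(blk, x, tape = NULL, training = FALSE) {
  h <- ag_conv2d(tape, x, blk$c1$w, blk$c1$b, pad = 1L)
  h <- ag_relu(tape, apply_norm(tape, h, blk$n1, training))
  h <- ag_conv2d(tape, h, blk$c2$w, blk$c2$b, pad = 1L)
  ag_relu(tape, apply_norm(tape, h, blk$n2, training))
}

#' Forward pass of the segmenter
#'
#' @param model a [unet()] model
#' @param img (H, W, 3) or (H, W, 3, N) array in the model domain `[-1, 1]`,
#'   H and W divisible by 16
#' @param tape optional gradient tape
#' @return probability map node/`(H, W, cls[, N])` array; per-pixel class
#'   probabilities sum to 1
#' @export
unet_forward <- function(model, img, tape = NULL, training = !is.null(tape)) {
  x <- img
  single <- !is_node(x) && length(dim(x)) == 3L
  if (single) x <- as_batch(x)
  d <- dim(ag_val(x))
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("U-Net input dims must be divisible by 16, got ", d[1], "x", d[2])
  skips <- vector("list", 4)
  h <- x
  for (i in 1:4) {
    h <- unet_dbl_forward(model$enc[[i]], h, tape, training)
    skips[[i]] <- h
    h <- ag_maxpool2(tape, h)
  }
  h <- unet_dbl_forward(model$bott, h, tape, training)
  for (i in 1:4) {
    h <- ag_up2(tape, h)
    h <- ag_conv2d(tape, h, model$upconv[[i]]$w, model$upconv[[i]]$b, pad = 1L)
    h <- ag_concat_ch(tape, list(skips[[5 - i]], h))
    h <- unet_dbl_forward(model$updbl[[i]], h, tape, training)
  }
  logits <- ag_conv2d(tape, h, model$head$w, model$head$b)
  p <- ag_softmax_ch(tape, logits)
  if (is.null(tape) && !is_node(img)) {
    pv <- ag_val(p)
    return(if (single) drop_batch(pv) else pv)
  }
  p
}

#' Per-pixel argmax labels from a probability map
#'
#' Ties break toward the lowest class index, so a uniform map is all
#' background.
#'
#' @param p (H, W, cls) or (H, W, cls, N) probability array
#' @return integer label matrix (H, W) or array (H, W, N), values 0..cls-1
#' @export
predict_labels <- function(p) {
  p <- ag_val(p)
  d <- dim(p)
  if (length(d) == 3L) dim(p) <- c(d, 1L)
  d4 <- dim(p)
  out <- array(0L, dim = c(d4[1], d4[2], d4[4]))
  for (n in seq_len(d4[4])) {
    m <- matrix(aperm(p[, , , n, drop = FALSE], c(3, 1, 2, 4)), nrow = d4[3])
    out[, , n] <- matrix(max.col(t(m), ties.method = "first") - 1L, nrow = d4[1])
  }
  if (length(d) == 3L) out <- matrix(out, nrow = d[1]) else out
}
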