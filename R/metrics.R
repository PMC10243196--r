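#' @title Restoration and segmentation losses and metrics
#' @description SSIM (global and windowed), the composite SSIM + L1
#'   restoration loss, Dice loss, PSNR and the confusion-matrix segmentation
#'   metrics (per-class IOU, mIOU, macro recall/precision, F1).
#' @name losses_metrics
NULL

#' 2-D Gaussian window, normalized to sum 1
#' @param size odd window side (default 11)
#' @param sigma standard deviation in pixels (default 1.5)
#' @keywords internal
gaussian_window <- function(size = 11L, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

as_hwcn <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

# Differentiable windowed SSIM on (H, W, C, N) nodes/arrays. Gaussian window
# statistics are renormalized by the window coverage at the borders, so a
# constant image has exactly uniform statistics and the windowed value matches
# the sigma = 0 closed form.
ag_ssim_windowed <- function(tape, x, y, m = 2.55, n = 7.5,
                             window = gaussian_window()) {
  d <- dim(ag_val(x))
  cov <- cpp_dwconv_fw(array(1, dim = d), array(window, dim = c(dim(window), d[3])),
                       numeric(0), (nrow(window) - 1L) %/% 2L)
  inv_cov <- 1 / cov
  filt <- function(z) ag_mul(tape, ag_filter_fixed(tape, z, window), inv_cov)
  mux <- filt(x); muy <- filt(y)
  x2 <- filt(ag_mul(tape, x, x)); y2 <- filt(ag_mul(tape, y, y))
  xy <- filt(ag_mul(tape, x, y))
  vx <- ag_sub(tape, x2, ag_mul(tape, mux, mux))
  vy <- ag_sub(tape, y2, ag_mul(tape, muy, muy))
  vxy <- ag_sub(tape, xy, ag_mul(tape, mux, muy))
  m2 <- m^2; n2 <- n^2
  num <- ag_mul(tape,
                ag_affine(tape, ag_mul(tape, mux, muy), 2, m2),
                ag_affine(tape, vxy, 2, n2))
  den <- ag_mul(tape,
                ag_affine(tape, ag_add(tape, ag_mul(tape, mux, mux),
                                       ag_mul(tape, muy, muy)), 1, m2),
                ag_affine(tape, ag_add(tape, vx, vy), 1, n2))
  ag_mean(tape, ag_div(tape, num, den))
}

#' Structural similarity index (SSIM)
#'
#' Luminance/contrast/structure similarity with stabilizers \eqn{m^2} and
#' \eqn{n^2}; equals 1 iff the images are identical. Defaults `m = 2.55`,
#' `n = 7.5` assume the 0-255 intensity scale. `mode = "global"` uses
#' whole-image statistics (the sigma = 0 closed form on constant images);
#' `mode = "windowed"` averages an 11x11 Gaussian-weighted local SSIM map
#' (sigma 1.5), with border-renormalized windows.
#'
#' @param x,y same-shape numeric arrays on a common intensity scale
#' @param m,n stabilizing constants (> 0)
#' @param mode `"windowed"` (default) or `"global"`
#' @return SSIM value (symmetric in x and y, at most 1)
#' @export
ssim <- function(x, y, m = 2.55, n = 7.5, mode = c("windowed", "global")) {
  mode <- match.arg(mode)
  if (!identical(dim(x), dim(y))) stop("ssim: shape mismatch")
  if (m <= 0 || n <= 0) stop("ssim: stabilizers must be positive")
  if (mode == "global") {
    mux <- mean(x); muy <- mean(y)
    vx <- mean(x^2) - mux^2; vy <- mean(y^2) - muy^2
    vxy <- mean(x * y) - mux * muy
    ((2 * mux * muy + m^2) * (2 * vxy + n^2)) /
      ((mux^2 + muy^2 + m^2) * (vx + vy + n^2))
  } else {
    ag_val(ag_ssim_windowed(NULL, as_hwcn(x), as_hwcn(y), m = m, n = n))
  }
}

#' Composite restoration loss: weighted (1 - SSIM) plus L1
#'
#' \eqn{\lambda_1 (1 - SSIM) + (1 - \lambda_1) \, \|restored - target\|_1}.
#' Inputs are expected in the model domain \eqn{[-1, 1]}; the SSIM term is
#' evaluated after rescaling to the 0-255 intensity scale (where the default
#' stabilizers are calibrated) and the L1 term is the mean absolute
#' difference in the model domain.
#'
#' @param restored,target same-shape arrays in the model domain
#' @param lambda1 mixing weight in `[0, 1]` (default 0.84)
#' @return nonnegative scalar loss
#' @export
restoration_loss <- function(restored, target, lambda1 = 0.84) {
  ag_val(ag_restoration_loss(NULL, as_hwcn(ag_val(restored)),
                             as_hwcn(ag_val(target)), lambda1))
}

# node-aware version used by the trainer
ag_restoration_loss <- function(tape, restored, target, lambda1 = 0.84) {
  if (lambda1 < 0 || lambda1 > 1) stop("lambda1 must be in [0, 1]")
  if (!identical(dim(ag_val(restored)), dim(ag_val(target))))
    stop("restoration_loss: shape mismatch")
  s <- ag_ssim_windowed(tape, ag_affine(tape, restored, 127.5, 127.5),
                        ag_affine(tape, target, 127.5, 127.5))
  ssim_term <- ag_affine(tape, s, -1, 1)              # 1 - SSIM
  l1 <- ag_mean(tape, ag_abs(tape, ag_sub(tape, restored, target)))
  ag_add(tape, ag_affine(tape, ssim_term, lambda1, 0),
         ag_affine(tape, l1, 1 - lambda1, 0))
}

#' Dice loss for 3-class probability maps
#'
#' One minus the class-averaged Dice overlap between predicted probabilities
#' and a one-hot label map, with a small smoothing term for empty classes.
#'
#' @param P probability array (H, W, cls) or (H, W, cls, N)
#' @param L one-hot label array, same shape
#' @param eps smoothing added to numerator and denominator (default 1e-6)
#' @return loss in `[0, 1]`
#' @export
dice_loss <- function(P, L, eps = 1e-6) {
  ag_val(ag_dice_loss(NULL, as_hwcn(ag_val(P)), as_hwcn(ag_val(L)), eps))
}

ag_dice_loss <- function(tape, P, L, eps = 1e-6) {
  Lv <- ag_val(L); Pv <- ag_val(P)
  if (!identical(dim(Pv), dim(Lv))) stop("dice_loss: shape mismatch")
  d <- dim(Pv)
  cls <- d[3]
  csum <- function(z)  # per-class sums pooled over pixels and batch
    colSums(matrix(aperm(z, c(1, 2, 4, 3)), ncol = cls))
  inter <- csum(Pv * Lv)
  tot <- csum(Pv + Lv)
  terms <- (2 * inter + eps) / (tot + eps)
  val <- 1 - mean(terms)
  ag_op(tape, list(P), val, function(g) {
    gP <- array(0, dim = d)
    for (c in seq_len(cls)) {
      # d term_c / dP_ci = (2 L_ci (tot_c + eps) - (2 inter_c + eps)) / (tot_c + eps)^2
      gP[, , c, ] <- -(g / cls) *
        (2 * Lv[, , c, , drop = FALSE] * (tot[c] + eps) - (2 * inter[c] + eps)) /
        (tot[c] + eps)^2
    }
    list(gP)
  })
}

#' Peak signal-to-noise ratio in dB
#'
#' MSE is averaged over all pixels and channels; `Max` is the dynamic range.
#' Identical images give `Inf`.
#'
#' @param restored,target same-shape arrays on the 0-255 scale
#' @param max_val dynamic range (default 255)
#' @return PSNR in dB
#' @export
psnr <- function(restored, target, max_val = 255) {
  if (!identical(dim(restored), dim(target))) stop("psnr: shape mismatch")
  mse <- mean((restored - target)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' One-vs-rest confusion counts per class
#'
#' @param pred,gt integer label matrices with values in `0..cls-1`
#' @param cls number of classes (default 3)
#' @return list with vectors `tp`, `fp`, `fn`, `tn` of length `cls`
#' @export
confusion <- function(pred, gt, cls = 3L) {
  if (!identical(dim(pred), dim(gt))) stop("confusion: shape mismatch")
  if (any(pred < 0 | pred >= cls) || any(gt < 0 | gt >= cls))
    stop("confusion: labels out of range 0..", cls - 1)
  tot <- length(pred)
  cm <- table(factor(pred, levels = 0:(cls - 1)), factor(gt, levels = 0:(cls - 1)))
  tp <- diag(cm)
  fp <- rowSums(cm) - tp
  fn <- colSums(cm) - tp
  list(tp = as.numeric(tp), fp = as.numeric(fp), fn = as.numeric(fn),
       tn = tot - as.numeric(tp) - as.numeric(fp) - as.numeric(fn))
}

#' Segmentation metrics: per-class IOU, mIOU, macro recall/precision, F1
#'
#' IOU\eqn{_c} = TP/(TP+FN+FP); mIOU is the unweighted mean over all classes
#' (background included). Recall and precision are computed per class and
#' macro-averaged; F1 is the harmonic mean of the macro averages. A class
#' with an empty denominator (absent from both maps for IOU; absent from the
#' ground truth for recall; never predicted for precision) contributes 1 by
#' the vacuous-truth convention; such classes are listed in the
#' `vacuous_classes` field.
#'
#' @inheritParams confusion
#' @return list with `per_class_iou`, `miou`, `recall`, `precision`, `f1`,
#'   `vacuous_classes`
#' @export
seg_metrics <- function(pred, gt, cls = 3L) {
  cf <- confusion(pred, gt, cls)
  safe <- function(num, den) ifelse(den == 0, 1, num / den)
  iou <- safe(cf$tp, cf$tp + cf$fn + cf$fp)
  rec <- safe(cf$tp, cf$tp + cf$fn)
  prec <- safe(cf$tp, cf$tp + cf$fp)
  vac <- which(cf$tp + cf$fn + cf$fp == 0) - 1L
  mr <- mean(rec); mp <- mean(prec)
  f1 <- if (mr + mp == 0) 0 else 2 * mp * mr / (mp + mr)
  structure(list(per_class_iou = iou, miou = mean(iou), recall = mr,
                 precision = mp, f1 = f1, vacuous_classes = vac),
            class = "wranet_seg_metrics")
}

#' @export
print.wranet_seg_metrics <- function(x, ...) {
  cat(sprintf("mIOU %.4f | IOU per class [%s] | recall %.4f | precision %.4f | F1 %.4f\n",
              x$miou, paste(sprintf("%.4f", x$per_class_iou), collapse = ", "),
              x$recall, x$precision, x$f1))
  invisible(x)
}
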