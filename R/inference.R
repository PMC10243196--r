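#' @title Patch-based restoration and the restore-then-segment pipeline
#' @description Large images are restored tile by tile: the input is
#'   reflect-padded so an overlapping patch grid covers it exactly, each tile
#'   is restored by the network, and overlaps are blended by uniform
#'   averaging, which suppresses seam artifacts.
#' @name inference
NULL

#' Compute the tile grid covering an image
#'
#' @param h,w image dims
#' @param patch square tile size
#' @param stride step between tile origins, `1 <= stride <= patch`
#' @return list: `patch`, `stride`, `origins` (matrix of 0-based (row, col)
#'   tile origins), `pad_h`, `pad_w`, padded dims `ph`, `pw`
#' @keywords internal
tile_grid <- function(h, w, patch, stride) {
  if (stride < 1 || stride > patch) stop("need 1 <= stride <= patch")
  nt <- function(L) if (L <= patch) 1L else as.integer(ceiling((L - patch) / stride) + 1)
  nh <- nt(h); nw <- nt(w)
  ph <- (nh - 1L) * stride + patch
  pw <- (nw - 1L) * stride + patch
  og <- as.matrix(expand.grid(row = (seq_len(nh) - 1L) * stride,
                              col = (seq_len(nw) - 1L) * stride))
  list(patch = as.integer(patch), stride = as.integer(stride), origins = og,
       pad_h = ph - h, pad_w = pw - w, ph = ph, pw = pw, h = h, w = w)
}

#' Cut an image into overlapping tiles
#'
#' The image is reflect-padded (bottom/right) to the grid's canvas so every
#' pixel is covered by at least one tile.
#'
#' @param img (H, W, C) array
#' @param patch tile size
#' @param stride tile stride
#' @return list with `tiles` (list of (patch, patch, C) arrays, in grid
#'   order) and `grid` (the [tile_grid()])
#' @export
tile_image <- function(img, patch = 256L, stride = 128L) {
  d <- dim(img)
  g <- tile_grid(d[1], d[2], patch, stride)
  padded <- pad_reflect(img, 0L, g$pad_h, 0L, g$pad_w)
  tiles <- lapply(seq_len(nrow(g$origins)), function(i) {
    oy <- g$origins[i, 1]; ox <- g$origins[i, 2]
    padded[(oy + 1):(oy + patch), (ox + 1):(ox + patch), , drop = FALSE]
  })
  list(tiles = tiles, grid = g)
}

#' Recompose tiles into a full image
#'
#' Overlapping regions are averaged with uniform weights (the per-pixel
#' denominator is the tile coverage count); the padding introduced by
#' [tile_image()] is cropped off.
#'
#' @param tiles list of (patch, patch, C) arrays in grid order
#' @param grid the accompanying grid
#' @return (H, W, C) array of the original size
#' @export
stitch_tiles <- function(tiles, grid) {
  if (length(tiles) != nrow(grid$origins))
    stop("tile count does not match the grid")
  C <- dim(tiles[[1]])[3]
  acc <- array(0, dim = c(grid$ph, grid$pw, C))
  cnt <- matrix(0, grid$ph, grid$pw)
  p <- grid$patch
  for (i in seq_along(tiles)) {
    if (!identical(dim(tiles[[i]]), c(p, p, C)))
      stop("tile ", i, " has inconsistent shape")
    oy <- grid$origins[i, 1]; ox <- grid$origins[i, 2]
    ys <- (oy + 1):(oy + p); xs <- (ox + 1):(ox + p)
    acc[ys, xs, ] <- acc[ys, xs, , drop = FALSE] + tiles[[i]]
    cnt[ys, xs] <- cnt[ys, xs] + 1
  }
  for (c in seq_len(C)) acc[, , c] <- acc[, , c] / cnt
  acc[seq_len(grid$h), seq_len(grid$w), , drop = FALSE]
}

#' Patch-based restoration of an arbitrarily sized image
#'
#' Tiles the input, restores each tile with the network and stitches the
#' results with overlap averaging. Memory use is bounded by the tile size
#' regardless of the image size.
#'
#' @param img (H, W, 3) array in the model domain `[-1, 1]`
#' @param model a trained [wranet()] model
#' @param patch tile size; must be divisible by `2^(levels-1)`
#' @param stride tile stride (default `patch / 2`)
#' @return restored (H, W, 3) array, values in (-1, 1), same size as input
#' @export
restore_full <- function(img, model, patch = 256L, stride = 128L) {
  div <- 2^(model$descriptor$levels - 1)
  if (patch %% div != 0)
    stop("patch must be divisible by 2^(levels-1) = ", div)
  tl <- tile_image(img, patch, stride)
  restored <- lapply(tl$tiles, function(t) restore(model, t))
  stitch_tiles(restored, tl$grid)
}

#' Error-class visualization of a predicted label map
#'
#' Correct pixels keep the class palette (black background, red crop, blue
#' weed); misclassified pixels are colored by their ground-truth class:
#' missed crop yellow, missed weed orange, mislabelled background gray.
#'
#' @param pred,gt integer (H, W) label matrices
#' @return (H, W, 3) RGB array in `[0, 1]`
#' @export
error_visualization <- function(pred, gt) {
  out <- labels_to_rgb(pred)
  err <- pred != gt
  col <- rbind(c(0.5, 0.5, 0.5),  # gt background, wrongly labelled
               c(1.0, 1.0, 0.0),  # gt crop missed -> yellow
               c(1.0, 0.5, 0.0))  # gt weed missed -> orange
  for (k in 1:3) {
    ch <- out[, , k]
    ch[err] <- col[gt[err] + 1L, k]
    out[, , k] <- ch
  }
  out
}

#' End-to-end restore-then-segment pipeline
#'
#' Restores a blurred image patch-wise, pads it to U-Net divisibility,
#' segments it and returns per-pixel labels; when ground truth is supplied,
#' segmentation metrics and an error visualization are included.
#'
#' @param img (H, W, 3) blurred image in the model domain `[-1, 1]`
#' @param restorer trained [wranet()] model
#' @param segmenter trained [unet()] model
#' @param gt optional integer (H, W) ground-truth label map
#' @param patch,stride tiling parameters for restoration
#' @return list with `restored` ((H, W, 3), model domain), `labels`
#'   ((H, W) integer), and when `gt` is given `metrics` ([seg_metrics()])
#'   and `error_map` ((H, W, 3) RGB)
#' @export
run_pipeline <- function(img, restorer, segmenter, gt = NULL,
                         patch = 256L, stride = 128L) {
  d <- dim(img)
  restored <- restore_full(img, restorer, patch, stride)
  ph <- (16 - d[1] %% 16) %% 16
  pw <- (16 - d[2] %% 16) %% 16
  seg_in <- if (ph > 0 || pw > 0) pad_reflect(restored, 0L, ph, 0L, pw) else restored
  p <- unet_forward(segmenter, seg_in)
  lab <- predict_labels(p)[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  out <- list(restored = restored, labels = lab)
  if (!is.null(gt)) {
    out$metrics <- seg_metrics(lab, gt)
    out$error_map <- error_visualization(lab, gt)
  }
  out
}
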