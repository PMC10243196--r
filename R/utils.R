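# Shared helpers: seeded evaluation, reflective padding, image domains, IO.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls do not perturb the
#' caller's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Symmetric (edge-inclusive) reflection index
#'
#' Maps any integer coordinate onto 1..n by mirroring at the borders with the
#' edge pixel included (… 2 1 | 1 2 3 … n | n n-1 …). Well defined for
#' padding wider than the image.
#' @keywords internal
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1L) %% (2L * n)
  m <- ifelse(m < 0L, m + 2L * n, m)
  ifelse(m < n, m + 1L, 2L * n - m)
}

#' Pad a `(H, W, C[, N])` array by symmetric reflection
#' @param x array
#' @param top,bottom,left,right pad widths in pixels
#' @keywords internal
pad_reflect <- function(x, top, bottom = top, left = top, right = left) {
  d <- dim(x)
  ri <- mirror_index(seq.int(1L - top, d[1] + bottom), d[1])
  ci <- mirror_index(seq.int(1L - left, d[2] + right), d[2])
  if (length(d) == 2L) x[ri, ci, drop = FALSE]
  else if (length(d) == 3L) x[ri, ci, , drop = FALSE]
  else x[ri, ci, , , drop = FALSE]
}

# -- value domains ------------------------------------------------------------
# storage domain: 8-bit [0, 255]; file domain (png): [0, 1];
# model domain: [-1, 1].

#' Convert a `[0,1]` image array to the model domain `[-1, 1]`
#' @param x numeric array in `[0, 1]`
#' @export
to_model_domain <- function(x) 2 * x - 1

#' Convert a model-domain image to `[0,1]`, clipping to range
#' @param x numeric array in `[-1, 1]`
#' @export
from_model_domain <- function(x) pmin(pmax((x + 1) / 2, 0), 1)

#' Rescale model-domain values to the 0-255 metric scale
#' @param x numeric array in `[-1, 1]`
#' @export
to_metric_scale <- function(x) (x + 1) * 127.5

#' Ensure a batch dimension: (H,W,C) -> (H,W,C,1)
#' @keywords internal
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

drop_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 4L && d[4] == 1L) dim(x) <- d[1:3]
  x
}

# -- image / label IO ---------------------------------------------------------

#' Read an RGB PNG as a `[0,1]` `(H, W, 3)` array
#' @param path PNG file
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  x
}

#' Write a `[0,1]` `(H, W, 3)` array as an 8-bit PNG
#' @param x image array in `[0, 1]`
#' @param path output file
#' @export
write_image <- function(x, path) {
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}

#' Read a single-channel label PNG holding class indices {0, 1, 2}
#' @param path PNG file
#' @return integer (H, W) matrix
#' @export
read_labels <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow = nrow(x))
}

#' Write an integer label map as a single-channel PNG
#' @param lab integer (H, W) matrix of class indices
#' @param path output file
#' @export
write_labels <- function(lab, path) {
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' RGB visualization palette for label maps
#'
#' background = black, crop = red, weed = blue.
#' @param lab integer (H, W) label matrix
#' @return `(H, W, 3)` array in `[0, 1]`
#' @export
labels_to_rgb <- function(lab) {
  pal <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  out <- array(0, dim = c(nrow(lab), ncol(lab), 3))
  for (k in 1:3) out[, , k] <- pal[lab + 1L, k]
  out
}

#' One-hot encode a label map
#' @param lab integer (H, W) matrix with values in 0..(cls-1)
#' @param cls number of classes
#' @return (H, W, cls) array of 0/1
#' @export
one_hot <- function(lab, cls = 3L) {
  out <- array(0, dim = c(nrow(lab), ncol(lab), cls))
  for (c in seq_len(cls)) out[, , c] <- (lab == c - 1L) * 1
  out
}
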