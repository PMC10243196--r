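# Shared fixtures and independent oracles used across the suite.

# brute-force standard convolution (zero padding), independent of the
# compiled im2col/GEMM path
brute_conv <- function(x, w, b, stride = 1L, pad = 0L) {
  d <- dim(x); wd <- dim(w)
  Ho <- (d[1] + 2 * pad - wd[1]) %/% stride + 1
  Wo <- (d[2] + 2 * pad - wd[2]) %/% stride + 1
  out <- array(0, c(Ho, Wo, wd[4], d[4]))
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  for (n in seq_len(d[4])) for (o in seq_len(wd[4]))
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      patch <- xp[(i - 1) * stride + seq_len(wd[1]),
                  (j - 1) * stride + seq_len(wd[2]), , n]
      out[i, j, o, n] <- sum(patch * w[, , , o]) + b[o]
    }
  out
}

# central-difference numerical gradient of a scalar function
num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  if (is.null(dim(x))) as.vector(g) else g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand4 <- function(h, w, c, n, seed = 1, sd = 1) {
  set.seed(seed)
  array(rnorm(h * w * c * n, sd = sd), c(h, w, c, n))
}

# small shared study-condition fixtures for scaled-down experiments
tiny_scene <- function() scene_spec(64, 64, n_crops = 3, n_weeds = 5, seed = 0)
tiny_blur <- function() blur_params(kernel_size = 13L)
tiny_cfg <- function(seed = 3) {
  train_config(lr0 = 1e-3, lr_min = 1e-6, batch = 2, patch = 64,
               seed = seed, seg_lr = 1e-3, val_frac = 0)
}

# set every parameter of a module to |value| (makes impulse responses
# strictly positive so ReLU keeps the full footprint)
make_params_positive <- function(module) {
  for (p in collect_params(module)) p$v <- abs(p$v) + 0.01
  invisible(module)
}

wr <- asNamespace("wranet")
acceptance_cache <- new.env(parent = emptyenv())
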