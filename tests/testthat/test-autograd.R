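# Correctness of the autodiff engine: every layer's analytic gradient is
# checked against central differences on small tensors, and the compiled
# convolution against a brute-force oracle.

test_that("compiled convolution matches brute force over strides and paddings", {
  x <- rand4(7, 6, 3, 2, seed = 11)
  set.seed(12)
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  for (st in 1:2) for (pd in 0:1) {
    expect_equal(wr$cpp_conv2d_fw(x, w, b, st, pd), brute_conv(x, w, b, st, pd),
                 tolerance = 1e-12)
  }
})

grad_of <- function(build, x) {
  tape <- wr$ag_tape()
  xn <- wr$ag_node(x)
  loss <- build(tape, xn)
  wr$ag_backward(tape, loss)
  xn$g
}

test_that("convolution, depthwise and strided gradients match finite differences", {
  x <- rand4(5, 5, 2, 2, seed = 21)
  set.seed(22)
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3)); b <- rnorm(3)
  dw <- array(rnorm(3 * 3 * 2), c(3, 3, 2)); db <- rnorm(2)

  f <- function(z) {
    t2 <- wr$ag_tape()
    wr$ag_val(wr$ag_mean(t2, wr$ag_square(t2, wr$ag_conv2d(t2, z, w, b, 1L, 1L))))
  }
  g <- grad_of(function(tape, xn)
    wr$ag_mean(tape, wr$ag_square(tape, wr$ag_conv2d(tape, xn, w, b, 1L, 1L))), x)
  expect_equal(g, num_grad(f, x, 1e-5), tolerance = 1e-6)

  fd <- function(z) {
    t2 <- wr$ag_tape()
    wr$ag_val(wr$ag_mean(t2, wr$ag_square(t2, wr$ag_dwconv(t2, z, dw, db, 1L))))
  }
  gd <- grad_of(function(tape, xn)
    wr$ag_mean(tape, wr$ag_square(tape, wr$ag_dwconv(tape, xn, dw, db, 1L))), x)
  expect_equal(gd, num_grad(fd, x, 1e-5), tolerance = 1e-6)

  # weight gradient through a parameter node
  tape <- wr$ag_tape()
  wn <- wr$ag_param(w)
  loss <- wr$ag_mean(tape, wr$ag_square(tape, wr$ag_conv2d(tape, x, wn, b, 1L, 1L)))
  wr$ag_backward(tape, loss)
  fw <- function(z) {
    t2 <- wr$ag_tape()
    wr$ag_val(wr$ag_mean(t2, wr$ag_square(t2, wr$ag_conv2d(t2, x, z, b, 1L, 1L))))
  }
  expect_equal(wn$g, num_grad(fw, w, 1e-5), tolerance = 1e-6)
})

test_that("deformable convolution gradients (input, offsets, modulation, weights) are exact", {
  x <- rand4(5, 5, 2, 2, seed = 31)
  set.seed(32)
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  off <- array(rnorm(5 * 5 * 18 * 2, sd = 0.3), c(5, 5, 18, 2))
  msk <- array(runif(5 * 5 * 9 * 2, 0.5, 1), c(5, 5, 9, 2))
  run <- function(xv, ov, mv, wv) {
    tape <- wr$ag_tape()
    xn <- wr$ag_node(xv); on_ <- wr$ag_node(ov)
    mn <- wr$ag_node(mv); wn <- wr$ag_node(wv)
    l <- wr$ag_mean(tape, wr$ag_square(tape,
      wr$ag_deform_conv(tape, xn, on_, mn, wn, NULL)))
    list(l = l, tape = tape, xn = xn, on_ = on_, mn = mn, wn = wn)
  }
  r <- run(x, off, msk, w)
  wr$ag_backward(r$tape, r$l)
  expect_equal(r$xn$g, num_grad(function(z) wr$ag_val(run(z, off, msk, w)$l), x, 1e-5),
               tolerance = 1e-5)
  expect_equal(r$on_$g, num_grad(function(z) wr$ag_val(run(x, z, msk, w)$l), off, 1e-5),
               tolerance = 1e-5)
  expect_equal(r$mn$g, num_grad(function(z) wr$ag_val(run(x, off, z, w)$l), msk, 1e-5),
               tolerance = 1e-5)
  expect_equal(r$wn$g, num_grad(function(z) wr$ag_val(run(x, off, msk, z)$l), w, 1e-5),
               tolerance = 1e-5)
})

test_that("normalization layers backpropagate exactly", {
  x <- rand4(4, 4, 2, 2, seed = 41)
  cmul <- rand4(4, 4, 2, 2, seed = 42)
  set.seed(43)
  gam <- rnorm(2); bet <- rnorm(2)
  for (type in c("instance", "batch")) {
    run <- function(xv, gv) {
      tape <- wr$ag_tape()
      xn <- wr$ag_node(xv); gn <- wr$ag_node(gv); bn <- wr$ag_node(bet)
      st <- new.env(); st$rm <- numeric(2); st$rv <- rep(1, 2)
      h <- if (type == "instance") wr$ag_instance_norm(tape, xn, gn, bn)
           else wr$ag_batch_norm(tape, xn, gn, bn, st, training = TRUE)
      l <- wr$ag_mean(tape, wr$ag_square(tape, wr$ag_mul(tape, h, cmul)))
      list(l = l, tape = tape, xn = xn, gn = gn)
    }
    r <- run(x, gam)
    wr$ag_backward(r$tape, r$l)
    expect_equal(r$xn$g, num_grad(function(z) wr$ag_val(run(z, gam)$l), x), tolerance = 1e-5)
    expect_equal(r$gn$g, num_grad(function(z) wr$ag_val(run(x, z)$l), gam), tolerance = 1e-6)
  }
})

test_that("softmax + Dice, pooling, upsampling and SSIM-loss gradients are exact", {
  z <- rand4(4, 4, 3, 2, seed = 51)
  set.seed(52)
  lab <- matrix(sample(0:2, 16, TRUE), 4, 4)
  L <- array(0, c(4, 4, 3, 2))
  for (n in 1:2) L[, , , n] <- one_hot(lab)
  run1 <- function(zv) {
    tape <- wr$ag_tape()
    zn <- wr$ag_node(zv)
    l <- wr$ag_dice_loss(tape, wr$ag_softmax_ch(tape, zn), L)
    list(l = l, tape = tape, zn = zn)
  }
  r <- run1(z); wr$ag_backward(r$tape, r$l)
  expect_equal(r$zn$g, num_grad(function(v) wr$ag_val(run1(v)$l), z), tolerance = 1e-6)

  z2 <- rand4(4, 4, 2, 1, seed = 53)
  for (opname in c("up", "pool")) {
    run2 <- function(zv) {
      tape <- wr$ag_tape()
      zn <- wr$ag_node(zv)
      h <- if (opname == "up") wr$ag_up2(tape, zn) else wr$ag_maxpool2(tape, zn)
      l <- wr$ag_mean(tape, wr$ag_square(tape, h))
      list(l = l, tape = tape, zn = zn)
    }
    r <- run2(z2); wr$ag_backward(r$tape, r$l)
    expect_equal(r$zn$g, num_grad(function(v) wr$ag_val(run2(v)$l), z2), tolerance = 1e-6)
  }

  xa <- array(runif(8 * 8, -0.5, 0.5), c(8, 8, 1, 1))
  ya <- array(runif(8 * 8, -0.5, 0.5), c(8, 8, 1, 1))
  run3 <- function(zv) {
    tape <- wr$ag_tape()
    zn <- wr$ag_node(zv)
    l <- wr$ag_restoration_loss(tape, zn, ya, 0.84)
    list(l = l, tape = tape, zn = zn)
  }
  r <- run3(xa); wr$ag_backward(r$tape, r$l)
  expect_equal(r$zn$g, num_grad(function(v) wr$ag_val(run3(v)$l), xa, 1e-5),
               tolerance = 1e-5)
})

test_that("pixelshuffle is a bijection and channel concat splits gradients", {
  z <- rand4(3, 5, 8, 2, seed = 61)
  ps <- wr$ag_val(wr$ag_pixel_shuffle(NULL, z))
  expect_equal(dim(ps), c(6L, 10L, 2L, 2L))
  expect_identical(wr$ag_val(wr$ag_pixel_unshuffle(NULL, ps)), z)
  expect_equal(sum(ps^2), sum(z^2))  # permutation conserves energy

  a <- rand4(3, 3, 2, 1, seed = 62); b <- rand4(3, 3, 3, 1, seed = 63)
  tape <- wr$ag_tape()
  an <- wr$ag_node(a); bn <- wr$ag_node(b)
  l <- wr$ag_mean(tape, wr$ag_square(tape, wr$ag_concat_ch(tape, list(an, bn))))
  wr$ag_backward(tape, l)
  f <- function(z2) {
    t2 <- wr$ag_tape()
    wr$ag_val(wr$ag_mean(t2, wr$ag_square(t2, wr$ag_concat_ch(t2, list(z2, b)))))
  }
  expect_equal(an$g, num_grad(f, a), tolerance = 1e-6)
})
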