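# Architecture of the restoration network: block shapes, closed-form
# parameter counts, receptive fields, attention/skip identities, deformable
# convolution oracles and the tanh residual output.

test_that("Conv Block 1 and 2 produce ReLU-positive C-channel maps of the input size", {
  m <- wranet(C = 8, levels = 1, seed = 1)
  x <- rand4(10, 12, 3, 2, seed = 2)
  f <- wr$ag_val(wr$conv_block1_forward(m$cb1, x))
  expect_equal(dim(f), c(10L, 12L, 8L, 2L))
  expect_true(all(f >= 0))
  h <- wr$ag_val(wr$conv_block2_forward(m$cb2[[1]], f))
  expect_equal(dim(h), c(10L, 12L, 8L, 2L))
  expect_true(all(h >= 0))
  # closed-form parameter counts (weights + biases + norm affines)
  cb1_n <- sum(vapply(collect_params(m$cb1), function(p) length(p$v), numeric(1)))
  expect_equal(cb1_n, (27 * 8 + 8) + (9 * 64 + 8) + 2 * 16)
  cb2_n <- sum(vapply(collect_params(m$cb2[[1]]), function(p) length(p$v), numeric(1)))
  expect_equal(cb2_n, 9 * 64 + 8 + 16)
})

test_that("mDSCB factorizes into C^2 + 9C conv parameters and preserves shape", {
  C <- 8L
  m <- wranet(C = C, levels = 1, seed = 3)
  md <- m$wrarb[[1]]$groups[[1]][[1]]
  conv_n <- length(md$pw$w$v) + length(md$dw$w$v)
  expect_equal(conv_n, C^2 + 9 * C)       # vs 9 C^2 for a standard 3x3 conv
  x <- rand4(9, 9, C, 1, seed = 4)
  y <- wr$ag_val(wr$mdscb_forward(md, x))
  expect_equal(dim(y), dim(x))
})

test_that("mDSCB group n has a (1+2n)^2 impulse footprint with norms bypassed", {
  C <- 8L
  m <- wranet(C = C, levels = 1, groups = c(1L, 4L), seed = 5)
  make_params_positive(m$wrarb[[1]])
  impulse <- array(0, c(17, 17, C, 1))
  impulse[9, 9, , 1] <- 1
  for (gi in 1:2) {
    n <- c(1L, 4L)[gi]
    out <- wr$ag_val(wr$mdscb_group_forward(m$wrarb[[1]]$groups[[gi]], impulse,
                                            bypass_norm = TRUE))
    # subtract the bias-only response of a zero input to isolate the impulse
    base <- wr$ag_val(wr$mdscb_group_forward(m$wrarb[[1]]$groups[[gi]],
                                             array(0, dim(impulse)),
                                             bypass_norm = TRUE))
    resp <- apply(abs(out - base), c(1, 2), sum)
    nz <- which(resp > 1e-12, arr.ind = TRUE)
    side <- 1 + 2 * n
    expect_equal(max(nz[, 1]) - min(nz[, 1]) + 1, side)
    expect_equal(max(nz[, 2]) - min(nz[, 2]) + 1, side)
    expect_true(all(abs(nz[, 1] - 9) <= n & abs(nz[, 2] - 9) <= n))
  }
  expect_error(wranet(C = 8, groups = integer(0)), "positive")
})

test_that("the attention gate bounds features with weights strictly in (0,1)", {
  C <- 8L
  m <- wranet(C = C, levels = 1, seed = 6)
  wrb <- m$wrarb[[1]]
  zero <- array(0, c(6, 6, C, 1))
  expect_true(all(wr$ag_val(wr$attention_gate_forward(wrb, zero)) == 0))

  f_fe <- abs(rand4(6, 6, C, 2, seed = 7)) + 0.1
  out <- wr$ag_val(wr$attention_gate_forward(wrb, f_fe))
  expect_true(all(abs(out) < abs(f_fe)))  # sigmoid weights in (0,1)

  # zeroed second pointwise conv -> sigmoid(0) = 0.5 exactly
  wrb$attn2$w$v[] <- 0
  wrb$attn2$b$v[] <- 0
  out2 <- wr$ag_val(wr$attention_gate_forward(wrb, f_fe))
  expect_equal(out2, 0.5 * f_fe)
})

test_that("Lite WRARB: zero alpha yields the attention branch, unit alpha the skip", {
  C <- 8L
  m <- wranet(C = C, levels = 1, seed = 8)
  wrb <- m$wrarb[[1]]
  expect_true(all(wrb$alpha$v == 0))  # initialized to zero before training
  # fusion conv input width is (number of groups) * C
  expect_equal(dim(wrb$fusion$w$v), c(1L, 1L, 4L * C, C))

  x <- rand4(8, 8, C, 1, seed = 9)
  out <- wr$ag_val(wr$lite_wrarb_forward(wrb, x))
  feats <- lapply(wrb$groups, function(g) wr$mdscb_group_forward(g, x))
  h <- wr$ag_conv2d(NULL, wr$ag_concat_ch(NULL, feats), wrb$fusion$w, wrb$fusion$b)
  f_fe <- wr$ag_relu(NULL, wr$apply_norm(NULL, h, wrb$fusion_norm))
  f_att <- wr$ag_val(wr$attention_gate_forward(wrb, f_fe))
  expect_equal(out, f_att)  # alpha = 0: pure attention branch

  # alpha = 1 with all conv paths zeroed: pure skip
  for (p in collect_params(wrb)) p$v[] <- 0
  wrb$alpha$v[] <- 1
  expect_equal(wr$ag_val(wr$lite_wrarb_forward(wrb, x)), x)
})

test_that("strided 2x2 downsampling halves dims and reduces to average pooling", {
  C <- 4L
  m <- wranet(C = C, levels = 3, seed = 10)
  x <- rand4(16, 16, C, 1, seed = 11)
  y <- wr$ag_val(wr$downsample_forward(m$down[[1]], x))
  expect_equal(dim(y), c(8L, 8L, C, 1L))
  y2 <- wr$ag_val(wr$downsample_forward(m$down[[2]], y))
  expect_equal(dim(y2), c(4L, 4L, C, 1L))
  expect_error(wr$downsample_forward(m$down[[1]], rand4(5, 6, C, 1)), "even")

  dn <- m$down[[1]]
  dn$w$v[] <- 0
  for (c in seq_len(C)) dn$w$v[, , c, c] <- 1 / 4
  dn$b$v[] <- 0
  yp <- wr$ag_val(wr$downsample_forward(dn, x))
  pool <- array(0, c(8, 8, C, 1))
  for (i in 1:8) for (j in 1:8)
    pool[i, j, , 1] <- apply(x[2 * i - 1:0, 2 * j - 1:0, , 1], 3, mean)
  expect_equal(yp, pool, tolerance = 1e-12)
})

test_that("the encoder emits one skip per level at halving resolutions", {
  m1 <- wranet(C = 8, levels = 1, seed = 12)
  s1 <- wr$wranet_encode(m1, rand4(12, 12, 3, 1, seed = 13))
  expect_length(s1, 1)
  expect_equal(dim(wr$ag_val(s1[[1]]))[1:2], c(12L, 12L))

  m3 <- wranet(C = 8, levels = 3, seed = 14)
  s3 <- wr$wranet_encode(m3, rand4(64, 64, 3, 1, seed = 15))
  expect_equal(vapply(s3, function(s) dim(wr$ag_val(s))[1], integer(1)),
               c(64L, 32L, 16L))
  expect_error(wr$wranet_encode(m3, rand4(30, 30, 3, 1)), "divisible")
})

test_that("upsample-and-aggregation restores the skip's shape via pixelshuffle", {
  C <- 8L
  m <- wranet(C = C, levels = 2, seed = 16)
  skip <- rand4(10, 10, C, 2, seed = 17)
  prev <- rand4(5, 5, C, 2, seed = 18)
  out <- wr$ag_val(wr$upsample_aggregate_forward(m$dec[[1]], prev, skip))
  expect_equal(dim(out), dim(skip))
  expect_error(wr$upsample_aggregate_forward(m$dec[[1]], skip, skip), "half")
})

test_that("Deformable ResBlock equals a plain conv resblock at zero offsets", {
  C <- 8L
  m <- wranet(C = C, levels = 2, seed = 19)
  dec <- m$dec[[1]]
  expect_true(all(dec$off$w$v == 0) && all(dec$off$b$v == 0))  # init contract
  x <- rand4(8, 8, C, 2, seed = 20)
  got <- wr$ag_val(wr$deformable_resblock_forward(dec, x))
  plain <- brute_conv(pmax(brute_conv(x, dec$dconv$w$v, dec$dconv$b$v, 1, 1), 0),
                      dec$conv2$w$v, dec$conv2$b$v, 1, 1) + x
  expect_lt(max(abs(got - plain)), 1e-5)

  # residual identity when both conv weight sets are zeroed
  dec$dconv$w$v[] <- 0; dec$dconv$b$v[] <- 0
  dec$conv2$w$v[] <- 0; dec$conv2$b$v[] <- 0
  expect_equal(wr$ag_val(wr$deformable_resblock_forward(dec, x)), x)
})

test_that("uniform integer offsets shift the deformable sampling grid exactly", {
  C <- 4L
  set.seed(21)
  x <- rand4(10, 10, C, 1, seed = 21)
  w <- array(rnorm(9 * C * C), c(3, 3, C, C))
  off <- array(0, c(10, 10, 18, 1))
  off[, , 2 * (0:8) + 1, ] <- 1          # dy = +1 on every tap
  msk <- array(1, c(10, 10, 9, 1))
  got <- wr$cpp_deform_fw(x, off, msk, w, numeric(0))
  plain <- brute_conv(x, w, numeric(4), 1, 1)
  # sampling one pixel down equals the plain output shifted one row up
  expect_equal(got[2:8, 2:9, , , drop = FALSE],
               plain[3:9, 2:9, , , drop = FALSE], tolerance = 1e-10)
})

test_that("Conv Block 3 narrows C -> C/2 -> C/4 -> 3 and zeroing it silences the residual", {
  m <- wranet(C = 16, levels = 1, seed = 22)
  expect_equal(dim(m$cb3$conv1$w$v)[3:4], c(16L, 8L))
  expect_equal(dim(m$cb3$conv2$w$v)[3:4], c(8L, 4L))
  expect_equal(dim(m$cb3$conv3$w$v)[3:4], c(4L, 3L))
  expect_error(wranet(C = 6), "divisible by 4")

  x <- rand4(8, 8, 16, 1, seed = 23)
  fres <- wr$ag_val(wr$conv_block3_forward(m$cb3, x))
  expect_equal(dim(fres), c(8L, 8L, 3L, 1L))
  expect_true(all(fres == 0))  # default zero-initialized last layer
})

test_that("restore is a strict (-1,1) map of the input's shape; tanh at init", {
  m <- wranet(C = 8, levels = 3, seed = 24)
  img <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
  out <- restore(m, img)
  expect_equal(dim(out), dim(img))
  expect_true(all(out > -1 & out < 1))
  expect_equal(out, tanh(img))  # zero-initialized Conv Block 3
  expect_error(restore(m, img * 3), "model domain")

  # after perturbing the output layer the net is no longer a passthrough
  m$cb3$conv3$w$v[] <- 0.01
  expect_gt(max(abs(restore(m, img) - tanh(img))), 0)
})

test_that("normalization placement: instance norm in the encoder, batch norm in the decoder", {
  m <- wranet(C = 8, levels = 3, seed = 25)
  norm_types <- function(module) {
    out <- character(0)
    walk <- function(x) {
      if (is.list(x)) {
        if (!is.null(x$norm_type)) out <<- c(out, x$norm_type)
        for (el in x) if (!is.null(el) && is.list(el)) walk(el)
      }
    }
    walk(module)
    out
  }
  enc <- c(norm_types(m$cb1), norm_types(m$wrarb), norm_types(m$cb2))
  dec <- norm_types(m$dec)
  expect_true(length(enc) > 0 && all(enc == "instance"))
  expect_true(length(dec) > 0 && all(dec == "batch"))
})

test_that("counted parameters equal the closed form for any configuration", {
  cases <- list(list(C = 8L, levels = 1L, groups = c(1L, 2L, 3L, 4L)),
                list(C = 8L, levels = 2L, groups = c(1L, 2L, 3L, 4L)),
                list(C = 16L, levels = 3L, groups = c(1L, 3L)),
                list(C = 12L, levels = 2L, groups = c(2L)))
  for (cs in cases) {
    m <- wranet(C = cs$C, levels = cs$levels, groups = cs$groups, seed = 1)
    expect_equal(count_params(m),
                 wranet_param_formula(cs$C, cs$levels, cs$groups))
  }
})

test_that("checkpoints round-trip weights and reject mismatched architectures", {
  m <- wranet(C = 8, levels = 2, seed = 26)
  img <- array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3))
  m$cb3$conv3$w$v[] <- stats::rnorm(length(m$cb3$conv3$w$v), sd = 0.05)
  before <- restore(m, img)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  expect_true(file.exists(paste0(ck, ".json")))
  m2 <- load_checkpoint(wranet(C = 8, levels = 2, seed = 99), ck)
  expect_equal(restore(m2, img), before)
  expect_error(load_checkpoint(wranet(C = 12, levels = 2), ck), "mismatch")
  unlink(c(ck, paste0(ck, ".json")))
})
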