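# Synthetic blur kernels and field scenes.

test_that("trajectories follow the momentum random walk and are deterministic", {
  t1 <- generate_trajectory(n_steps = 1, seed = 0)
  expect_equal(t1$points, matrix(0, 1, 2))
  expect_error(generate_trajectory(n_steps = 0), "n_steps")

  a <- generate_trajectory(64, 0.7, 1.0, seed = 42)
  b <- generate_trajectory(64, 0.7, 1.0, seed = 42)
  expect_identical(a$points, b$points)
  expect_false(identical(a$points,
                         generate_trajectory(64, 0.7, 1.0, seed = 43)$points))

  # direct simulation of the update rule is the oracle for the path
  ref <- with(list(), {
    set.seed(42)
    v <- c(0, 0); p <- matrix(0, 64, 2)
    for (t in 2:64) {
      v <- 0.7 * v + rnorm(2, sd = 1)
      p[t, ] <- p[t - 1, ] + v
    }
    sweep(p, 2, colMeans(p))
  })
  expect_equal(a$points, ref)
  expect_equal(colMeans(a$points), c(0, 0))  # recentred
})

test_that("kernel rasterization splats bilinearly and conserves mass", {
  # single point at the exact center -> delta kernel
  k <- rasterize_kernel(generate_trajectory(1, seed = 0), K = 5)
  expect_equal(k[3, 3], 1)
  expect_equal(sum(k), 1)
  expect_equal(sum(k != 0), 1)

  # half-pixel offset -> two adjacent cells at 0.5 each (bilinear arithmetic)
  tr <- structure(list(points = matrix(c(0, 0.5), 1, 2), n_steps = 1L),
                  class = "wranet_trajectory")
  k2 <- rasterize_kernel(tr, K = 5)
  expect_equal(k2[3, 3], 0.5)
  expect_equal(k2[3, 4], 0.5)
  expect_equal(sum(k2), 1)

  expect_error(rasterize_kernel(generate_trajectory(4, seed = 1), K = 4), "odd")

  # mass conservation and canvas fit across seeds, including wild paths that
  # need auto-rescaling onto the default 33x33 canvas
  for (s in 1:20) {
    k3 <- rasterize_kernel(generate_trajectory(64, 0.7, 2.0, seed = s), K = 33)
    expect_lt(abs(sum(k3) - 1), 1e-9)
    expect_true(all(k3 >= 0))
  }
})

test_that("blurring preserves constants, means and never increases variance", {
  set.seed(5)
  img <- array(runif(20 * 18 * 3), c(20, 18, 3))
  kd <- rasterize_kernel(generate_trajectory(1, seed = 0), K = 3)  # delta
  expect_equal(apply_blur(img, kd), img)

  const <- array(0.37, c(16, 16, 3))
  kr <- rasterize_kernel(generate_trajectory(32, seed = 3), K = 9)
  expect_equal(apply_blur(const, kr), const)

  # interior pixel of a uniform 3x3 blur equals the 9-neighborhood mean
  ramp <- matrix(seq_len(16), 4, 4) / 16
  ku <- matrix(1 / 9, 3, 3)
  bl <- apply_blur(ramp, ku)
  expect_equal(bl[2, 2], mean(ramp[1:3, 1:3]))
  expect_equal(bl[3, 2], mean(ramp[2:4, 1:3]))

  expect_error(apply_blur(array(0, c(5, 5, 3)), matrix(1 / 49, 7, 7)), "larger")

  for (s in 1:5) {
    sp <- scene_spec(64, 64, seed = s)
    scn <- generate_field_scene(sp)
    kb <- rasterize_kernel(generate_trajectory(64, seed = s), K = 13)
    blr <- apply_blur(scn$image, kb)
    expect_lte(var(as.vector(blr)), var(as.vector(scn$image)) + 1e-6)
  }
})

test_that("field scenes render the requested objects with exact labels", {
  empty <- generate_field_scene(scene_spec(64, 64, n_crops = 0, n_weeds = 0, seed = 1))
  expect_true(all(empty$labels == 0L))

  sp <- scene_spec(96, 96, n_crops = 3, n_weeds = 5, seed = 9)
  a <- generate_field_scene(sp)
  b <- generate_field_scene(sp)
  expect_identical(a, b)  # bit-identical under a fixed seed
  expect_setequal(unique(as.vector(a$labels)), c(0L, 1L, 2L))

  skip_if_not_installed("EBImage")
  # connected-component oracle: exactly n_crops and n_weeds components
  n_cc <- function(mask) max(EBImage::bwlabel(mask * 1))
  expect_equal(n_cc(a$labels == 1L), 3)
  expect_equal(n_cc(a$labels == 2L), 5)
})

test_that("scene spec validates its invariants", {
  expect_error(scene_spec(32, 64), ">= 64")
  expect_error(scene_spec(64, 64, n_crops = -1), ">= 0")
})

test_that("paired datasets are written reproducibly with blur that costs PSNR", {
  d0 <- tempfile("ds0")
  p0 <- make_paired_dataset(0, tiny_scene(), tiny_blur(), d0, seed = 1)
  man0 <- jsonlite::read_json(p0)
  expect_length(man0$records, 0)
  expect_length(list.files(d0, pattern = "png$"), 0)

  d1 <- tempfile("ds1"); d2 <- tempfile("ds2")
  p1 <- make_paired_dataset(4, tiny_scene(), tiny_blur(), d1, seed = 7)
  p2 <- make_paired_dataset(4, tiny_scene(), tiny_blur(), d2, seed = 7)
  expect_length(list.files(d1, pattern = "png$"), 12)
  for (f in list.files(d1, pattern = "png$"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))

  ds <- load_dataset(p1)
  for (r in ds) {
    p <- psnr(r$blurred * 255, r$sharp * 255)
    expect_true(is.finite(p))       # strictly below the identical-image case
    expect_lt(p, psnr(r$sharp * 255, r$sharp * 255))
  }
  # labels survive the PNG round trip
  expect_true(all(ds[[1]]$labels %in% 0:2))
  unlink(c(d0, d1, d2), recursive = TRUE)
})
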