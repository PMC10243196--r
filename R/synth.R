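#' @title Synthetic motion blur and crop/weed field scenes
#' @description Generates (a) nonlinear camera-shake blur kernels as
#'   rasterized momentum-random-walk trajectories and (b) synthetic field
#'   scenes — soil-textured background with green crop clusters and smaller
#'   hue-shifted weed blobs — together with exact pixel labels, replacing
#'   external field datasets for building and testing the system.
#' @name synth_data
NULL

#' Random nonlinear camera-shake trajectory
#'
#' A momentum random walk: velocity `v[t+1] = inertia * v[t] + impulse`,
#' impulses iid Gaussian with scale `impulse_scale`; positions are the
#' cumulative sums, recentred on the origin. Deterministic given `seed`.
#'
#' @param n_steps number of trajectory points (>= 1)
#' @param inertia momentum coefficient in `[0, 1]` (default 0.7)
#' @param impulse_scale Gaussian impulse scale in pixels (default 1)
#' @param seed RNG seed
#' @return object of class `wranet_trajectory` with `points` (n x 2 matrix)
#'   and `n_steps`
#' @export
generate_trajectory <- function(n_steps = 64L, inertia = 0.7,
                                impulse_scale = 1.0, seed = 0L) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (inertia < 0 || inertia > 1) stop("inertia must be in [0, 1]")
  if (impulse_scale <= 0) stop("impulse_scale must be positive")
  pts <- with_seed(seed, {
    v <- c(0, 0)
    p <- matrix(0, nrow = n_steps, ncol = 2)
    for (t in seq_len(n_steps)[-1]) {
      v <- inertia * v + stats::rnorm(2, sd = impulse_scale)
      p[t, ] <- p[t - 1, ] + v
    }
    p
  })
  pts <- sweep(pts, 2, colMeans(pts))
  structure(list(points = pts, n_steps = as.integer(n_steps)),
            class = "wranet_trajectory")
}

#' Rasterize a trajectory into a normalized blur kernel (PSF)
#'
#' Trajectory points are auto-rescaled (never clipped, so no kernel mass is
#' lost) to fit the K x K canvas, then splatted with bilinear weights at
#' sub-pixel positions; the result is normalized to sum 1.
#'
#' @param traj a [generate_trajectory()] object
#' @param K odd canvas size (default 33)
#' @return K x K nonnegative matrix summing to 1
#' @export
rasterize_kernel <- function(traj, K = 33L) {
  if (K < 1 || K %% 2 == 0) stop("K must be an odd positive integer")
  pts <- traj$points
  r_max <- max(abs(pts))
  half <- (K - 1) / 2
  if (r_max > half && half > 0) pts <- pts * (half / r_max)
  if (half == 0) pts <- pts * 0
  ctr <- (K + 1) / 2
  k <- matrix(0, K, K)
  for (i in seq_len(nrow(pts))) {
    y <- ctr + pts[i, 1]; x <- ctr + pts[i, 2]
    y0 <- floor(y); x0 <- floor(x)
    ly <- y - y0; lx <- x - x0
    splat <- function(yy, xx, w) {
      if (w > 0 && yy >= 1 && yy <= K && xx >= 1 && xx <= K)
        k[yy, xx] <<- k[yy, xx] + w
    }
    splat(y0, x0, (1 - ly) * (1 - lx))
    splat(y0, x0 + 1, (1 - ly) * lx)
    splat(y0 + 1, x0, ly * (1 - lx))
    splat(y0 + 1, x0 + 1, ly * lx)
  }
  s <- sum(k)
  if (s <= 0) stop("internal error: empty kernel")  # cannot happen after rescale
  k / s
}

#' Convolve an image with a blur kernel under reflective borders
#'
#' Per-channel 2-D filtering with symmetric (edge-inclusive) reflection
#' padding; output has the input's size and value range. Constant images are
#' exactly unchanged (the kernel is a convex combination).
#'
#' @param img (H, W) or (H, W, C) numeric array
#' @param k normalized blur kernel from [rasterize_kernel()]
#' @return blurred array, same shape
#' @export
apply_blur <- function(img, k) {
  K <- nrow(k)
  d <- dim(img)
  two_d <- length(d) == 2L
  if (two_d) dim(img) <- c(d, 1L)
  d3 <- dim(img)
  if (K > d3[1] || K > d3[2]) stop("kernel larger than image")
  if (abs(sum(k) - 1) > 1e-6) stop("kernel must be normalized to sum 1")
  p <- (K - 1L) %/% 2L
  xp <- pad_reflect(img, p)
  dim(xp) <- c(dim(xp), 1L)
  out <- cpp_dwconv_fw(xp, array(k, dim = c(K, K, d3[3])), numeric(0), 0L)
  dim(out) <- d3
  if (two_d) dim(out) <- d
  out
}

#' Specification of a synthetic crop/weed field scene
#'
#' @param height,width canvas size in pixels (>= 64)
#' @param n_crops,n_weeds object counts (>= 0)
#' @param crop_radius,weed_radius min/max object radius in pixels; crops are
#'   larger leafy clusters, weeds smaller blobs
#' @param crop_hue,weed_hue HSV hue ranges; crops green, weeds shifted toward
#'   yellow-green
#' @param soil_base soil RGB base color
#' @param soil_noise amplitude of the low-frequency soil texture
#' @param seed RNG seed; scenes are bit-identical given the same spec
#' @return object of class `wranet_scene_spec`
#' @export
scene_spec <- function(height = 64L, width = 64L, n_crops = 3L, n_weeds = 5L,
                       crop_radius = c(7, 11), weed_radius = c(2.5, 4.5),
                       crop_hue = c(0.30, 0.38), weed_hue = c(0.14, 0.20),
                       soil_base = c(0.42, 0.30, 0.20), soil_noise = 0.08,
                       seed = 0L) {
  if (height < 64 || width < 64) stop("scene dimensions must be >= 64")
  if (n_crops < 0 || n_weeds < 0) stop("object counts must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_crops = as.integer(n_crops), n_weeds = as.integer(n_weeds),
                 crop_radius = crop_radius, weed_radius = weed_radius,
                 crop_hue = crop_hue, weed_hue = weed_hue,
                 soil_base = soil_base, soil_noise = soil_noise,
                 seed = as.integer(seed)),
            class = "wranet_scene_spec")
}

# rasterize one ellipse (center cy,cx; semi-axes a,b; angle th) into a mask
rast_ellipse <- function(mask, cy, cx, a, b, th) {
  H <- nrow(mask); W <- ncol(mask)
  r <- ceiling(max(a, b))
  ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- (dy * cos(th) + dx * sin(th)) / a
  v <- (-dy * sin(th) + dx * cos(th)) / b
  mask[ys, xs] <- mask[ys, xs] | (u * u + v * v <= 1)
  mask
}

# a connected leafy blob: central disk plus leaves through the center
rast_plant <- function(H, W, cy, cx, r, n_leaves) {
  m <- matrix(FALSE, H, W)
  m <- rast_ellipse(m, cy, cx, max(1.2, r / 3), max(1.2, r / 3), 0)
  if (n_leaves > 0) {
    for (i in seq_len(n_leaves)) {
      th <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.6, 1) * r
      wid <- max(0.9, stats::runif(1, 0.22, 0.4) * len)
      m <- rast_ellipse(m, cy + 0.5 * len * cos(th), cx + 0.5 * len * sin(th),
                        len / 2 + 0.6, wid, th)
    }
  }
  m
}

#' Render a synthetic field scene with exact pixel labels
#'
#' Soil-textured background (class 0) with `n_crops` larger green leafy
#' clusters (class 1) and `n_weeds` smaller hue-shifted blobs (class 2).
#' Objects are placed with a minimum separation so each remains a distinct
#' connected component; placement retries are bounded and failure to place
#' raises an error.
#'
#' @param spec a [scene_spec()]
#' @return list with `image` ((H, W, 3) array in `[0, 1]`) and `labels`
#'   (integer (H, W) matrix in {0, 1, 2})
#' @export
generate_field_scene <- function(spec) {
  stopifnot(inherits(spec, "wranet_scene_spec"))
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    # soil: base color + smoothed low-frequency texture + fine grain
    g <- gaussian_window(11L, 3)
    smooth_field <- function() {
      z <- matrix(stats::rnorm(H * W), H, W)
      zp <- pad_reflect(z, 5L)
      dim(zp) <- c(dim(zp), 1L, 1L)
      s <- cpp_dwconv_fw(zp, array(g, dim = c(11, 11, 1)), numeric(0), 0L)
      matrix(s, H, W)
    }
    tex <- smooth_field()
    tex <- tex / max(abs(tex), 1e-8)
    img <- array(0, dim = c(H, W, 3))
    for (c in 1:3)
      img[, , c] <- spec$soil_base[c] * (1 + spec$soil_noise * tex) +
        stats::rnorm(H * W, sd = 0.015)
    labels <- matrix(0L, H, W)
    # object placement with minimum separation
    placed <- matrix(numeric(0), ncol = 3)  # cy, cx, r
    place <- function(r) {
      for (attempt in 1:300) {
        cy <- stats::runif(1, r + 2, H - r - 1)
        cx <- stats::runif(1, r + 2, W - r - 1)
        ok <- TRUE
        if (nrow(placed) > 0) {
          dd <- sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2)
          ok <- all(dd >= placed[, 3] + r + 3)
        }
        if (ok) {
          placed <<- rbind(placed, c(cy, cx, r))
          return(c(cy, cx))
        }
      }
      stop("could not place object of radius ", r,
           " after bounded attempts; reduce counts or sizes")
    }
    paint <- function(mask, hue_range, cls) {
      hue <- stats::runif(1, hue_range[1], hue_range[2])
      sat <- stats::runif(1, 0.55, 0.8)
      val <- stats::runif(1, 0.45, 0.7)
      rgb <- as.numeric(grDevices::col2rgb(grDevices::hsv(hue, sat, val))) / 255
      shade <- 1 + 0.15 * tex[mask]
      for (c in 1:3) {
        ch <- img[, , c]
        ch[mask] <- rgb[c] * shade
        img[, , c] <<- ch
      }
      labels[mask] <<- cls
    }
    if (spec$n_crops > 0) for (i in seq_len(spec$n_crops)) {
      r <- stats::runif(1, spec$crop_radius[1], spec$crop_radius[2])
      ctr <- place(r)
      m <- rast_plant(H, W, ctr[1], ctr[2], r, sample(4:7, 1))
      paint(m, spec$crop_hue, 1L)
    }
    if (spec$n_weeds > 0) for (i in seq_len(spec$n_weeds)) {
      r <- stats::runif(1, spec$weed_radius[1], spec$weed_radius[2])
      ctr <- place(r)
      m <- rast_plant(H, W, ctr[1], ctr[2], r, sample(0:2, 1))
      paint(m, spec$weed_hue, 2L)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, labels = labels)
  })
}

#' Default nonlinear blur synthesis parameters
#' @param n_steps,inertia,impulse_scale trajectory parameters
#'   (see [generate_trajectory()])
#' @param kernel_size PSF canvas size (odd)
#' @export
blur_params <- function(n_steps = 64L, inertia = 0.7, impulse_scale = 1.0,
                        kernel_size = 33L) {
  list(n_steps = as.integer(n_steps), inertia = inertia,
       impulse_scale = impulse_scale, kernel_size = as.integer(kernel_size))
}

#' Generate an in-memory dataset of sharp/blurred/label triples
#'
#' Each record gets its own scene and a fresh random blur kernel; record
#' seeds are derived deterministically from `seed`.
#'
#' @param n number of triples
#' @param spec a [scene_spec()] (its `seed` field is overridden per record)
#' @param bp blur parameters from [blur_params()]
#' @param seed base seed
#' @return list of records with `sharp`, `blurred` ((H, W, 3), `[0, 1]`),
#'   `labels` ((H, W) integer), `scene_seed`, `kernel_seed`
#' @export
synth_dataset <- function(n, spec = scene_spec(), bp = blur_params(),
                          seed = 0L) {
  if (n < 0) stop("n must be >= 0")
  lapply(seq_len(n), function(i) {
    sc_seed <- (seed * 1000L + i) %% .Machine$integer.max
    k_seed <- (seed * 1000L + 500000L + i) %% .Machine$integer.max
    sp <- spec; sp$seed <- sc_seed
    scn <- generate_field_scene(sp)
    traj <- generate_trajectory(bp$n_steps, bp$inertia, bp$impulse_scale,
                                seed = k_seed)
    kern <- rasterize_kernel(traj, bp$kernel_size)
    list(sharp = scn$image, blurred = apply_blur(scn$image, kern),
         labels = scn$labels, scene_seed = sc_seed, kernel_seed = k_seed)
  })
}

#' Write a paired sharp/blurred/label dataset to disk
#'
#' Writes `n` PNG triples plus a JSON manifest listing the files and seeds.
#'
#' @inheritParams synth_dataset
#' @param out_dir writable output directory (created if missing)
#' @return path to the manifest, invisibly; the manifest object has fields
#'   `records` (sharp/blurred/label paths, seeds) and `params`
#' @export
make_paired_dataset <- function(n, spec = scene_spec(), bp = blur_params(),
                                out_dir, seed = 0L) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  ds <- synth_dataset(n, spec, bp, seed)
  records <- lapply(seq_along(ds), function(i) {
    r <- ds[[i]]
    fs <- sprintf("sharp_%04d.png", i)
    fb <- sprintf("blurred_%04d.png", i)
    fl <- sprintf("label_%04d.png", i)
    write_image(r$sharp, file.path(out_dir, fs))
    write_image(r$blurred, file.path(out_dir, fb))
    write_labels(r$labels, file.path(out_dir, fl))
    list(sharp = fs, blurred = fb, label = fl,
         scene_seed = r$scene_seed, kernel_seed = r$kernel_seed)
  })
  manifest <- list(n = n, seed = seed,
                   spec = unclass(spec), blur = bp, records = records)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a dataset written by [make_paired_dataset()]
#'
#' @param manifest_path path to `manifest.json`
#' @return list of records as in [synth_dataset()]
#' @export
load_dataset <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  lapply(man$records, function(r) {
    list(sharp = read_image(file.path(dir, r$sharp)),
         blurred = read_image(file.path(dir, r$blurred)),
         labels = read_labels(file.path(dir, r$label)),
         scene_seed = r$scene_seed, kernel_seed = r$kernel_seed)
  })
}
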