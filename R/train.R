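#' @title Two-stage training: restorer first, then segmenter on restored data
#' @description Stage 1 trains WRA-Net on blurred/sharp pairs with the
#'   composite SSIM + L1 loss, Adam and per-step cosine learning-rate
#'   annealing over random aligned crops. Stage 2 freezes the restorer and
#'   trains the U-Net segmenter with Dice loss on restored crops.
#' @name training
NULL

#' Training configuration
#'
#' Defaults are the reference protocol: Adam with initial learning rate
#' 1e-4 annealed cosine-wise to 1e-7, batch size 2, 450 epochs over 256x256
#' random crops; the segmenter uses learning rate 1e-5. Scaled-down
#' experiments override these explicitly.
#'
#' @param lr0 initial restorer learning rate
#' @param lr_min final learning rate of the cosine schedule
#' @param schedule learning-rate schedule (only `"cosine"`)
#' @param batch batch size
#' @param epochs training epochs
#' @param patch square crop size (must be divisible by `2^(levels-1)` of the
#'   restorer, and by 16 when used for the segmenter)
#' @param betas Adam `(beta1, beta2)`
#' @param seed run seed controlling init, shuffling and crops
#' @param seg_lr segmenter learning rate
#' @param val_frac fraction of records (by manifest order, from the end)
#'   held out as the validation split
#' @return object of class `wranet_train_config`
#' @export
train_config <- function(lr0 = 1e-4, lr_min = 1e-7, schedule = "cosine",
                         batch = 2L, epochs = 450L, patch = 256L,
                         betas = c(0.9, 0.999), seed = 0L, seg_lr = 1e-5,
                         val_frac = 0.1) {
  if (lr_min > lr0) stop("lr_min must not exceed lr0")
  if (!identical(schedule, "cosine")) stop("only the cosine schedule is supported")
  if (batch < 1 || epochs < 1 || patch < 1) stop("batch, epochs, patch must be >= 1")
  structure(list(lr0 = lr0, lr_min = lr_min, schedule = schedule,
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 patch = as.integer(patch), betas = betas,
                 seed = as.integer(seed), seg_lr = seg_lr,
                 val_frac = val_frac),
            class = "wranet_train_config")
}

#' Read a training configuration from a YAML file
#' @param path YAML file whose keys mirror [train_config()] arguments
#' @export
read_train_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  do.call(train_config, yaml::read_yaml(path))
}

#' Cosine-annealed learning rate
#'
#' `lr(step) = lr_min + (lr0 - lr_min) (1 + cos(pi step / total)) / 2`;
#' equals `lr0` at step 0 and `lr_min` at `step = total_steps`, monotone
#' nonincreasing in between. No restarts.
#'
#' @param step current optimizer step, `0..total_steps`
#' @param total_steps total steps of the run
#' @param lr0,lr_min schedule endpoints
#' @export
cosine_lr <- function(step, total_steps, lr0 = 1e-4, lr_min = 1e-7) {
  if (any(step < 0 | step > total_steps)) stop("step out of range [0, total_steps]")
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * step / total_steps))
}

#' Cut the same random window from an aligned sharp/blurred(/label) triple
#'
#' The window origin is uniform over valid positions and drawn from the
#' caller's RNG stream (seed the session for determinism).
#'
#' @param sharp,blurred (H, W, 3) arrays with identical dims
#' @param label optional (H, W) label matrix
#' @param size square crop size
#' @return list with the cropped `sharp`, `blurred`, `label` and the drawn
#'   0-based offsets `oy`, `ox`
#' @export
random_crop_pair <- function(sharp, blurred, label = NULL, size) {
  d <- dim(sharp)
  if (!identical(d[1:2], dim(blurred)[1:2]))
    stop("sharp and blurred dims differ")
  if (!is.null(label) && !identical(d[1:2], dim(label)[1:2]))
    stop("label dims differ")
  if (d[1] < size || d[2] < size)
    stop("image (", d[1], "x", d[2], ") smaller than crop size ", size)
  oy <- sample.int(d[1] - size + 1L, 1L) - 1L
  ox <- sample.int(d[2] - size + 1L, 1L) - 1L
  ys <- (oy + 1):(oy + size); xs <- (ox + 1):(ox + size)
  list(sharp = sharp[ys, xs, , drop = FALSE],
       blurred = blurred[ys, xs, , drop = FALSE],
       label = if (!is.null(label)) label[ys, xs, drop = FALSE],
       oy = oy, ox = ox)
}

split_train_val <- function(dataset, val_frac) {
  n <- length(dataset)
  n_val <- floor(val_frac * n)
  if (n_val >= n) n_val <- n - 1L
  list(train = dataset[seq_len(n - n_val)],
       val = if (n_val > 0) dataset[(n - n_val + 1):n] else list())
}

#' Stage 1: train the WRA-Net restorer
#'
#' Optimizes the composite restoration loss (lambda1 = 0.84) with Adam over
#' random aligned crops, annealing the learning rate per optimizer step.
#' Deterministic given `cfg$seed`. Aborts on a non-finite loss.
#'
#' @param dataset list of records with `sharp` and `blurred` (H, W, 3) arrays
#'   in `[0, 1]` ([synth_dataset()] or [load_dataset()])
#' @param model a [wranet()] model (trained in place and returned)
#' @param cfg a [train_config()]
#' @param steps optional cap on total optimizer steps (overrides `epochs`)
#' @param lambda1 loss mixing weight
#' @param verbose print per-epoch progress
#' @return object of class `wranet_fit`: `model`, `history` (per-epoch
#'   data.frame with `epoch`, `train_loss`, `val_loss`, `lr`), `step_loss`
#' @export
train_restorer <- function(dataset, model, cfg = train_config(), steps = NULL,
                           lambda1 = 0.84, verbose = FALSE) {
  if (length(dataset) < 1) stop("dataset must contain at least one pair")
  sp <- split_train_val(dataset, cfg$val_frac)
  tr <- sp$train; va <- sp$val
  n_tr <- length(tr)
  steps_per_epoch <- ceiling(n_tr / cfg$batch)
  total_steps <- if (is.null(steps)) cfg$epochs * steps_per_epoch else as.integer(steps)
  params <- collect_params(model)
  with_seed(cfg$seed, {
    opt <- adam_init(params)
    step <- 0L
    step_loss <- numeric(0)
    hist <- list()
    epoch <- 0L
    while (step < total_steps) {
      epoch <- epoch + 1L
      ord <- sample.int(n_tr)
      ep_losses <- c()
      for (b in seq_len(steps_per_epoch)) {
        if (step >= total_steps) break
        idx <- ord[(((b - 1L) * cfg$batch + seq_len(cfg$batch) - 1L) %% n_tr) + 1L]
        crops <- lapply(tr[idx], function(r)
          random_crop_pair(r$sharp, r$blurred, size = cfg$patch))
        x <- array(0, dim = c(cfg$patch, cfg$patch, 3, length(idx)))
        y <- x
        for (i in seq_along(crops)) {
          x[, , , i] <- to_model_domain(crops[[i]]$blurred)
          y[, , , i] <- to_model_domain(crops[[i]]$sharp)
        }
        tape <- ag_tape()
        out <- wranet_forward(model, x, tape, training = TRUE)
        loss <- ag_restoration_loss(tape, out, y, lambda1)
        lv <- ag_val(loss)
        if (!is.finite(lv))
          stop("non-finite training loss at step ", step, " (loss = ", lv, ")")
        zero_grads(params)
        ag_backward(tape, loss)
        lr <- cosine_lr(step, total_steps, cfg$lr0, cfg$lr_min)
        adam_step(params, opt, lr, cfg$betas[1], cfg$betas[2])
        step <- step + 1L
        step_loss <- c(step_loss, lv)
        ep_losses <- c(ep_losses, lv)
      }
      val_loss <- NA_real_
      if (length(va) > 0) {
        vls <- vapply(va, function(r) {
          xb <- as_batch(to_model_domain(r$blurred))
          yb <- as_batch(to_model_domain(r$sharp))
          out <- wranet_forward(model, xb, NULL, training = FALSE)
          ag_val(ag_restoration_loss(NULL, out, yb, lambda1))
        }, numeric(1))
        val_loss <- mean(vls)
      }
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(ep_losses), val_loss = val_loss,
        lr = cosine_lr(min(step, total_steps), total_steps, cfg$lr0, cfg$lr_min))
      if (verbose)
        message(sprintf("epoch %d  step %d/%d  train %.5f  val %s", epoch,
                        step, total_steps, mean(ep_losses),
                        ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
    }
    structure(list(model = model, history = do.call(rbind, hist),
                   step_loss = step_loss, total_steps = total_steps),
              class = "wranet_fit")
  })
}

#' @export
print.wranet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("training run: %d steps, loss %.5f -> %.5f\n", x$total_steps,
              h$train_loss[1], h$train_loss[nrow(h)]))
  invisible(x)
}

restorer_apply_frozen <- function(restorer, img01) {
  # inference-only forward; no tape is ever attached, so no gradients can
  # reach the restorer and its parameters stay bit-identical
  out <- restore(restorer, to_model_domain(img01))
  out
}

#' Stage 2: train the U-Net segmenter with Dice loss
#'
#' The restorer (when used) is applied in inference mode only, so its
#' parameters receive no updates. Training inputs are selected by
#' `input`: `"restored"` (the proposed regime), `"sharp"` or `"blurred"`.
#'
#' @param dataset records with `sharp`, `blurred`, `labels`
#' @param seg_model a [unet()] model (trained in place)
#' @param restorer a trained [wranet()] model; required for
#'   `input = "restored"`
#' @param cfg a [train_config()]; `seg_lr` and `patch` are used
#' @param steps optional cap on total optimizer steps
#' @param input which images the segmenter trains on
#' @param verbose print progress
#' @return object of class `wranet_fit`
#' @export
train_segmenter <- function(dataset, seg_model, restorer = NULL,
                            cfg = train_config(), steps = NULL,
                            input = c("restored", "sharp", "blurred"),
                            verbose = FALSE) {
  input <- match.arg(input)
  if (length(dataset) < 1) stop("dataset must contain at least one record")
  if (any(vapply(dataset, function(r) is.null(r$labels), logical(1))))
    stop("dataset records must carry labels")
  if (input == "restored" && is.null(restorer))
    stop("a trained restorer is required for input = 'restored'")
  if (cfg$patch %% 16 != 0) stop("segmenter patch size must be divisible by 16")
  n <- length(dataset)
  steps_per_epoch <- ceiling(n / cfg$batch)
  total_steps <- if (is.null(steps)) cfg$epochs * steps_per_epoch else as.integer(steps)
  # precompute the segmenter's input view of each record
  inputs <- lapply(dataset, function(r) {
    switch(input,
           sharp = to_model_domain(r$sharp),
           blurred = to_model_domain(r$blurred),
           restored = restorer_apply_frozen(restorer, r$blurred))
  })
  params <- collect_params(seg_model)
  with_seed(cfg$seed + 1L, {
    opt <- adam_init(params)
    step <- 0L
    step_loss <- numeric(0)
    hist <- list()
    epoch <- 0L
    while (step < total_steps) {
      epoch <- epoch + 1L
      ord <- sample.int(n)
      ep_losses <- c()
      for (b in seq_len(steps_per_epoch)) {
        if (step >= total_steps) break
        idx <- ord[(((b - 1L) * cfg$batch) %% n + seq_len(cfg$batch) - 1L) %% n + 1L]
        x <- array(0, dim = c(cfg$patch, cfg$patch, 3, length(idx)))
        L <- array(0, dim = c(cfg$patch, cfg$patch, 3, length(idx)))
        for (i in seq_along(idx)) {
          r <- dataset[[idx[i]]]
          cr <- random_crop_pair(inputs[[idx[i]]], inputs[[idx[i]]],
                                 label = r$labels, size = cfg$patch)
          x[, , , i] <- cr$sharp
          L[, , , i] <- one_hot(cr$label, 3L)
        }
        tape <- ag_tape()
        p <- unet_forward(seg_model, x, tape)
        loss <- ag_dice_loss(tape, p, L)
        lv <- ag_val(loss)
        if (!is.finite(lv)) stop("non-finite Dice loss at step ", step)
        zero_grads(params)
        ag_backward(tape, loss)
        adam_step(params, opt, cfg$seg_lr, cfg$betas[1], cfg$betas[2])
        step <- step + 1L
        step_loss <- c(step_loss, lv)
        ep_losses <- c(ep_losses, lv)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(ep_losses),
                                  val_loss = NA_real_, lr = cfg$seg_lr)
      if (verbose)
        message(sprintf("seg epoch %d  step %d/%d  dice %.5f", epoch, step,
                        total_steps, mean(ep_losses)))
    }
    structure(list(model = seg_model, history = do.call(rbind, hist),
                   step_loss = step_loss, total_steps = total_steps),
              class = "wranet_fit")
  })
}

#' Run one train/test scheme of the blur ablation protocol
#'
#' The five schemes combine original, blurred and restored data:
#' \describe{
#'   \item{1}{train on original, test on original}
#'   \item{2}{train on original, test on blurred}
#'   \item{3}{train on blurred, test on blurred}
#'   \item{4}{train on original, test on restored}
#'   \item{5}{train on restored, test on restored}
#' }
#' A fresh segmenter is trained for the scheme's training inputs, then
#' evaluated on the scheme's test inputs; metrics are computed on the pooled
#' per-pixel confusion over the test set.
#'
#' @param scheme_id integer 1..5
#' @param train_data,test_data record lists with `sharp`, `blurred`, `labels`
#' @param restorer trained restorer (required for schemes 4 and 5)
#' @param cfg a [train_config()]
#' @param seg_base segmenter base width
#' @param steps segmenter optimizer steps
#' @param segmenter optional pre-trained segmenter to reuse; schemes that
#'   share a training regime (e.g. 1 and 2, both trained on original data)
#'   can reuse one model instead of retraining
#' @return [seg_metrics()] of the scheme, with the scheme's train/test input
#'   types attached as attributes `train_input` / `test_input` and the
#'   trained segmenter as attribute `segmenter`
#' @export
run_scheme <- function(scheme_id, train_data, test_data, restorer = NULL,
                       cfg = train_config(), seg_base = 8L, steps = NULL,
                       segmenter = NULL) {
  if (!scheme_id %in% 1:5) stop("scheme_id must be in 1..5")
  train_input <- c("sharp", "sharp", "blurred", "sharp", "restored")[scheme_id]
  test_input <- c("sharp", "blurred", "blurred", "restored", "restored")[scheme_id]
  if ((train_input == "restored" || test_input == "restored") && is.null(restorer))
    stop("schemes 4 and 5 need a trained restorer")
  if (is.null(segmenter)) {
    seg <- with_seed(cfg$seed + 2L, unet(base = seg_base))
    train_segmenter(train_data, seg, restorer = restorer, cfg = cfg,
                    steps = steps, input = train_input)
  } else {
    seg <- segmenter
  }
  preds <- lapply(test_data, function(r) {
    x <- switch(test_input,
                sharp = to_model_domain(r$sharp),
                blurred = to_model_domain(r$blurred),
                restored = restorer_apply_frozen(restorer, r$blurred))
    predict_labels(unet_forward(seg, x))
  })
  pred_all <- do.call(cbind, preds)
  gt_all <- do.call(cbind, lapply(test_data, function(r) r$labels))
  m <- seg_metrics(pred_all, gt_all)
  attr(m, "train_input") <- train_input
  attr(m, "test_input") <- test_input
  attr(m, "segmenter") <- seg
  m
}
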