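#' Training configuration
#'
#' Defaults follow the published schedule: 512 x 512 random patches,
#' stochastic gradient descent with momentum 0.9, initial learning rate
#' 0.001 halved every 1,500 iterations, at most 4,000 iterations, and
#' scaling/rotation augmentation. One iteration is one optimizer step on one
#' batch of patches.
#'
#' @param patch_size Training patch edge in pixels (must be divisible by
#'   `2^(depth-1)` of the model).
#' @param max_iterations Optimizer steps.
#' @param lr_initial Initial learning rate.
#' @param lr_halving_period Iterations between halvings of the rate.
#' @param momentum SGD momentum.
#' @param batch_size Patches per step.
#' @param augment_scales,augment_angles Candidate scale factors and rotation
#'   angles (degrees) drawn uniformly per patch; set both to `1` / `0` to
#'   disable augmentation.
#' @param seed Integer seed; the whole run is reproducible given the seed.
#' @param alpha Vessel-constraint strength used during training (overrides
#'   the model configuration when non-`NULL`).
#' @param weights A [loss_weights()] list.
#' @param checkpoint_every Iterations between checkpoints when `out_dir` is
#'   given to [train_model()]; 0 disables intermediate checkpoints.
#' @export
train_config <- function(patch_size = 512L, max_iterations = 4000L,
                         lr_initial = 0.001, lr_halving_period = 1500L,
                         momentum = 0.9, batch_size = 2L,
                         augment_scales = c(0.8, 1, 1.2),
                         augment_angles = seq(0, 345, by = 15),
                         seed = 1L, alpha = NULL,
                         weights = loss_weights(),
                         checkpoint_every = 0L) {
  stopifnot(patch_size >= 16, max_iterations >= 0, lr_initial > 0,
            lr_halving_period > 0, momentum >= 0, momentum < 1,
            batch_size >= 1, all(augment_scales > 0))
  if (max_iterations > 0 && lr_halving_period > max_iterations)
    warning("lr_halving_period exceeds max_iterations; rate never decays")
  structure(list(patch_size = as.integer(patch_size),
                 max_iterations = as.integer(max_iterations),
                 lr_initial = lr_initial,
                 lr_halving_period = as.integer(lr_halving_period),
                 momentum = momentum, batch_size = as.integer(batch_size),
                 augment_scales = augment_scales,
                 augment_angles = augment_angles,
                 seed = as.integer(seed), alpha = alpha, weights = weights,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

#' Tiny preset training configuration
#'
#' 128 x 128 patches, batch 4, 1,000 iterations and a 0.01 initial rate with
#' one halving at 500 iterations — a single-CPU scale-down of the full
#' schedule that keeps its structure (fixed budget, stepped decay, momentum).
#' @param ... Overrides passed to [train_config()].
#' @export
tiny_train_config <- function(...) {
  args <- modifyList(list(patch_size = 128L, max_iterations = 1000L,
                          lr_initial = 0.01, lr_halving_period = 500L,
                          batch_size = 2L),
                     list(...))
  do.call(train_config, args)
}

#' Stepped learning-rate schedule
#'
#' `lr_initial * 0.5 ^ floor(iteration / period)` with `iteration` counted
#' from 0.
#' @param iteration 0-based iteration index (vectorized).
#' @param lr_initial Initial rate.
#' @param period Iterations between halvings.
#' @export
lr_schedule <- function(iteration, lr_initial = 0.001, period = 1500L) {
  stopifnot(all(iteration >= 0), period > 0)
  lr_initial * 0.5^floor(iteration / period)
}

#' Sample a random training patch
#'
#' Uniformly random top-left corner; inputs smaller than `patch_size` are
#' reflection-padded first so sampling is always feasible. Consumes the
#' current R random stream.
#'
#' @param image `(H, W, 3)` array.
#' @param labels `H x W` integer label matrix ([AV_CLASSES] codes).
#' @param valid `H x W` logical validity map (typically the FOV mask).
#' @param patch_size Patch edge in pixels.
#' @return List `image`, `labels`, `valid`, spatially aligned, each
#'   `patch_size` square, plus the sampled `corner` (0-based row, col).
#' @export
sample_patch <- function(image, labels, valid, patch_size) {
  image <- reflect_pad_hw(image, patch_size, patch_size)
  labels <- reflect_pad_hw(labels, patch_size, patch_size)
  valid <- reflect_pad_hw(valid, patch_size, patch_size)
  h <- dim(image)[1]; w <- dim(image)[2]
  i0 <- sample.int(h - patch_size + 1L, 1L) - 1L
  j0 <- sample.int(w - patch_size + 1L, 1L) - 1L
  ri <- i0 + seq_len(patch_size); rj <- j0 + seq_len(patch_size)
  list(image = image[ri, rj, , drop = FALSE], labels = labels[ri, rj],
       valid = valid[ri, rj], corner = c(i0, j0))
}

#' Augment a patch triple
#'
#' Applies one randomly chosen scale factor and rotation angle identically
#' to the image (bilinear), the labels and the validity map (both
#' nearest-neighbour). Regions rotated in from outside the original canvas
#' are marked invalid. Output keeps the input patch size.
#'
#' @param patch A triple from [sample_patch()].
#' @param scales,angles Candidate scale factors / angles (degrees); one of
#'   each is drawn uniformly from the current R random stream.
#' @return Augmented patch triple plus the chosen `scale` and `angle`.
#' @export
augment_patch <- function(patch, scales = c(0.8, 1, 1.2),
                          angles = seq(0, 345, by = 15)) {
  sc <- scales[sample.int(length(scales), 1L)]
  an <- angles[sample.int(length(angles), 1L)]
  if (sc == 1 && an == 0)
    return(c(patch[c("image", "labels", "valid")], list(scale = 1, angle = 0)))
  h <- dim(patch$image)[1]; w <- dim(patch$image)[2]
  g <- affine_grid(h, w, h, w, an, sc)
  img <- bilinear_sample(patch$image, g$i, g$j)
  lab <- nearest_sample(patch$labels, g$i, g$j, fill = AV_CLASSES[["BACKGROUND"]])
  val <- nearest_sample(patch$valid * 1L, g$i, g$j, fill = 0L)
  list(image = img, labels = lab$values,
       valid = (val$values == 1L) & val$inside & lab$inside,
       scale = sc, angle = an)
}

#' Fuse several dataset manifests for joint training
#'
#' Concatenates the train entries of all manifests and shuffles them with
#' the seeded stream (multi-resolution data fusion: patch sampling makes the
#' native resolutions compatible, so no global resizing is applied). Test
#' entries are kept, tagged with their source dataset.
#'
#' @param manifests List of manifests from [read_manifest()] /
#'   [generate_dataset()].
#' @param seed Integer seed for the shuffle.
#' @return A fused manifest; each entry records its `source` dataset.
#' @export
fuse_datasets <- function(manifests, seed = 1L) {
  if (length(manifests) < 1L) stop("at least one manifest required")
  tag <- function(m) lapply(m$entries, function(e) {
    e$source <- m$name
    e
  })
  entries <- do.call(c, lapply(manifests, tag))
  if (length(entries) == 0L) stop("fused manifest has no entries")
  is_train <- vapply(entries, function(e) identical(e$split, "train"), logical(1))
  train <- entries[is_train]
  perm <- with_seed(sub_seed(seed, "fuse"), sample.int(length(train)))
  manifest(name = paste(vapply(manifests, `[[`, "", "name"), collapse = "+"),
           entries = c(train[perm], entries[!is_train]))
}

# Load every entry of a split into memory as image/labels/valid triples.
load_split <- function(man, split) {
  entries <- Filter(function(e) identical(e$split, split), man$entries)
  if (length(entries) == 0L) stop(sprintf("manifest has no '%s' entries", split))
  lapply(entries, function(e) {
    img <- load_image(e$image)
    lab <- decode_label_map(load_raster(e$label))
    fov <- if (!is.null(e$mask) && !is.na(e$mask)) load_mask(e$mask)
           else compute_fov_mask(img)
    list(image = img$pixels, labels = lab$classes, valid = fov$inside,
         source = e$source %||% man$name)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the network
#'
#' Runs `max_iterations` SGD-with-momentum steps on randomly sampled,
#' augmented patches, minimizing the weighted joint objective
#' (artery/vein cross-entropy + vessel binary cross-entropy + L2 on
#' convolution kernels). Fully reproducible given `config$seed`.
#'
#' @param model A `vc_model` (modified in place and returned).
#' @param man A dataset manifest with at least one `train` entry, or a list
#'   of preloaded scenes (elements `image`, `labels`, `valid`).
#' @param config A [train_config()].
#' @param out_dir Optional directory for checkpoints and a JSONL log.
#' @param quiet Suppress progress messages.
#' @return The trained model, with a `log` attribute: a data.frame of
#'   iteration, learning rate, and the three loss components.
#' @export
train_model <- function(model, man, config = train_config(), out_dir = NULL,
                        quiet = TRUE) {
  scenes <- if (!is.null(man$entries)) load_split(man, "train") else man
  stopifnot(length(scenes) >= 1L)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  ps <- config$patch_size
  wts <- config$weights
  alpha <- config$alpha %||% model$config$alpha
  log_it <- integer(0); log_lr <- log_av <- log_v <- log_tot <- numeric(0)
  logfile <- if (!is.null(out_dir)) file.path(out_dir, "train_log.jsonl")

  with_seed(sub_seed(config$seed, "train"), {
    for (it in seq_len(config$max_iterations)) {
      lr <- lr_schedule(it - 1L, config$lr_initial, config$lr_halving_period)
      xb <- array(0, c(ps, ps, 3, config$batch_size))
      lb <- array(AV_CLASSES[["BACKGROUND"]], c(ps, ps, config$batch_size))
      vb <- array(FALSE, c(ps, ps, config$batch_size))
      for (b in seq_len(config$batch_size)) {
        sc <- scenes[[sample.int(length(scenes), 1L)]]
        p <- sample_patch(sc$image, sc$labels, sc$valid, ps)
        p <- augment_patch(p, config$augment_scales, config$augment_angles)
        xb[, , , b] <- p$image
        lb[, , b] <- p$labels
        vb[, , b] <- p$valid
      }
      step <- train_step(model, xb, lb, vb, wts, alpha, lr, config$momentum)
      if (!is.finite(step$total))
        stop(sprintf("non-finite loss at iteration %d; aborting", it))
      log_it <- c(log_it, it); log_lr <- c(log_lr, lr)
      log_av <- c(log_av, step$av); log_v <- c(log_v, step$vessel)
      log_tot <- c(log_tot, step$total)
      if (!is.null(logfile))
        cat(jsonlite::toJSON(list(iteration = it, lr = lr, loss_av = step$av,
                                  loss_vessel = step$vessel,
                                  loss_total = step$total), auto_unbox = TRUE),
            "\n", file = logfile, append = TRUE, sep = "")
      if (!quiet && it %% 50L == 0L)
        message(sprintf("iter %5d lr %.5f loss %.4f (av %.4f, vessel %.4f)",
                        it, lr, step$total, step$av, step$vessel))
      if (!is.null(out_dir) && config$checkpoint_every > 0L &&
          it %% config$checkpoint_every == 0L)
        save_model(model, file.path(out_dir, sprintf("ckpt_%05d.rds", it)))
    }
  })
  if (!is.null(out_dir)) save_model(model, file.path(out_dir, "model.rds"))
  attr(model, "log") <- data.frame(iteration = log_it, lr = log_lr,
                                   loss_av = log_av, loss_vessel = log_v,
                                   loss_total = log_tot)
  model
}

# One SGD step on one batch; seeds the loss gradients at the two logit
# nodes, replays the tape, adds the L2 term, and updates parameters.
train_step <- function(model, xb, lb, vb, wts, alpha, lr, momentum) {
  zero_grads(model$params)
  out <- model_forward(model, xb, train = TRUE, alpha = alpha,
                       tape = ag_tape())
  ps <- dim(xb)[1]; nb <- dim(xb)[4]
  av <- out$av; if (length(dim(av)) == 3L) dim(av) <- c(dim(av), 1L)
  vessel <- out$vessel; dim(vessel) <- c(ps, ps, nb)

  vtruth <- lb != AV_CLASSES[["BACKGROUND"]]   # artery|vein|uncertain
  av_valid <- vb & (lb != AV_CLASSES[["UNCERTAIN"]])
  loss_av <- av_cross_entropy(av, lb, av_valid)
  loss_v <- vessel_bce(vessel, vtruth, vb)
  total <- total_loss(loss_av, loss_v, wts, conv_sq_norm(model))

  # d loss_av / d av_logits = (softmax - onehot) * mask / n_valid
  n_av <- sum(av_valid)
  onehot <- array(0, dim(av))
  hw <- ps * ps
  idx <- which(av_valid)
  n_id <- (idx - 1L) %/% hw
  pix <- (idx - 1L) %% hw
  onehot[pix + hw * lb[idx] + 3L * hw * n_id + 1L] <- 1
  mask4 <- array(av_valid * 1, c(ps, ps, 1, nb))[, , rep(1L, 3L), , drop = FALSE]
  g_av <- wts$gamma * (av - onehot) * mask4 / n_av
  ag_accum(out$av_logits, g_av)

  # d loss_v / d vessel_logits = (sigmoid - y) * mask / n_valid
  n_v <- sum(vb)
  g_v <- wts$delta * (vessel - vtruth) * (vb * 1) / n_v
  dim(g_v) <- c(ps, ps, 1, nb)
  ag_accum(out$vessel_logits, g_v)

  ag_backward(out$tape)
  if (wts$beta > 0)
    for (p in model$conv_weights) param_accum(p, 2 * wts$beta * p$v)
  sgd_update(model$params, lr, momentum)
  list(av = loss_av, vessel = loss_v, total = total)
}
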