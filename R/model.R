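#' Model configuration
#'
#' Hyper-parameters of the vessel-constraint network. The encoder stacks
#' `depth` levels of feature blocks (multi-scale hierarchical residual blocks
#' when `use_msf`, plain double 3x3 convolution blocks otherwise) with 2x2
#' max-pool downsampling between levels; the decoder mirrors it with 2x
#' upsampling and skip connections. Two full-resolution heads emit the vessel
#' probability (sigmoid) and the 3-class background/artery/vein probabilities
#' (softmax). When `use_vc`, the pre-classifier artery/vein features are
#' multiplied by [vc_weight()] of the vessel probability map.
#'
#' @param k Scale dimension of the multi-scale block: channels are split into
#'   `k` subsets chained through 3x3 convolutions (default 4).
#' @param base_channels Channels at the first encoder level; doubled at each
#'   deeper level. Must be divisible by `k`.
#' @param depth Number of encoder levels (>= 2). Input patches must be
#'   divisible by `2^(depth-1)`.
#' @param alpha Vessel-constraint strength used at training time; can be
#'   overridden per prediction (default 1, the published setting).
#' @param use_msf,use_vc Ablation switches for the multi-scale blocks and the
#'   vessel-constraint module.
#' @param upsample_mode `"bilinear"` (default) or `"nearest"` decoder
#'   upsampling.
#' @param vc_detach If `TRUE` the vessel probability entering the constraint
#'   is treated as a constant during backpropagation (default `FALSE`:
#'   gradients flow through the constraint into the vessel branch).
#' @return A `model_config` list.
#' @export
model_config <- function(k = 4, base_channels = 32, depth = 4, alpha = 1,
                         use_msf = TRUE, use_vc = TRUE,
                         upsample_mode = c("bilinear", "nearest"),
                         vc_detach = FALSE) {
  upsample_mode <- match.arg(upsample_mode)
  stopifnot(k >= 1, depth >= 2, alpha > 0, base_channels >= 1)
  if (base_channels %% k != 0)
    stop("base_channels must be divisible by k")
  structure(list(k = as.integer(k), base_channels = as.integer(base_channels),
                 depth = as.integer(depth), alpha = alpha,
                 use_msf = isTRUE(use_msf), use_vc = isTRUE(use_vc),
                 upsample_mode = upsample_mode, vc_detach = isTRUE(vc_detach)),
            class = "model_config")
}

#' Tiny preset configuration for CPU-scale experiments
#'
#' Base 8 channels, depth 3, k = 4: small enough to train on one CPU with
#' 128 x 128 patches while keeping every architectural component of the
#' full-scale network.
#' @param ... Overrides passed to [model_config()].
#' @export
tiny_model_config <- function(...) {
  args <- modifyList(list(k = 4, base_channels = 8, depth = 3), list(...))
  do.call(model_config, args)
}

msf_block_layers <- function(C, k) {
  nf <- max(0L, k - 1L)
  list(open = conv_layer(1, C, C), open_bn = bn_layer(C),
       fs = lapply(seq_len(nf), function(i) conv_layer(3, C %/% k, C %/% k)),
       fs_bn = lapply(seq_len(nf), function(i) bn_layer(C %/% k)),
       close = conv_layer(1, C, C), close_bn = bn_layer(C))
}

plain_block_layers <- function(C) {
  list(c1 = conv_layer(3, C, C), b1 = bn_layer(C),
       c2 = conv_layer(3, C, C), b2 = bn_layer(C))
}

#' Build a vessel-constraint network
#'
#' Instantiates all layers with seeded He-normal initial weights.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `vc_model` list with elements `config`, `layers`, `params`
#'   (all trainable parameter environments) and `conv_weights` (the
#'   convolution kernels subject to L2 regularization).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  with_seed(sub_seed(seed, "init"), {
    d <- config$depth
    ch <- config$base_channels * 2^(seq_len(d) - 1L)
    block <- function(C) if (config$use_msf) msf_block_layers(C, config$k)
                         else plain_block_layers(C)
    L <- list(stem = conv_layer(3, 3, ch[1]), stem_bn = bn_layer(ch[1]))
    L$enc <- lapply(ch, block)
    L$trans <- lapply(seq_len(d - 1L), function(l)
      list(cv = conv_layer(3, ch[l], ch[l + 1]), bn = bn_layer(ch[l + 1])))
    L$dec <- lapply(seq(d - 1L, 1L), function(l)
      list(reduce = conv_layer(1, ch[l + 1], ch[l]), reduce_bn = bn_layer(ch[l]),
           fuse = conv_layer(3, 2L * ch[l], ch[l]), fuse_bn = bn_layer(ch[l])))
    # Both heads read the fused decoder features concatenated with the raw
    # input (an input skip): per-pixel colour evidence reaches the
    # classifiers directly instead of only through the encoder trunk.
    L$vessel_feat <- conv_layer(3, ch[1] + 3L, ch[1])
    L$vessel_feat_bn <- bn_layer(ch[1])
    L$vessel_out <- conv_layer(1, ch[1], 1)
    L$av_feat <- conv_layer(3, ch[1] + 3L, ch[1])
    L$av_feat_bn <- bn_layer(ch[1])
    L$av_out <- conv_layer(1, ch[1], 3)
    model <- list(config = config, layers = L)
    model$params <- collect_params(L)
    model$conv_weights <- collect_conv_weights(L)
    class(model) <- "vc_model"
    model
  })
}

collect_layers <- function(x) {
  if (is.list(x) && !is.null(x$type)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_layers)))
  list()
}

collect_params <- function(L) {
  do.call(c, lapply(collect_layers(L), layer_params))
}

collect_conv_weights <- function(L) {
  lys <- collect_layers(L)
  lapply(Filter(function(l) l$type == "conv", lys), function(l) l$w)
}

#' @export
print.vc_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<vessel-constraint network> depth=%d base=%d k=%d msf=%s vc=%s alpha=%g\n",
    cfg$depth, cfg$base_channels, cfg$k, cfg$use_msf, cfg$use_vc, cfg$alpha))
  cat(sprintf("  trainable parameters: %d\n", n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `vc_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$v), numeric(1)))
}

# ---- forward pass ---------------------------------------------------------

fwd_conv_bn_relu <- function(tape, x, cv, bn, train) {
  op_bn(tape, op_conv(tape, x, cv), bn, train, relu = TRUE)
}

#' Multi-scale feature block forward
#'
#' Hierarchical residual block: a 1x1 convolution, a split of the channels
#' into `k` equal subsets `x_1..x_k`, then `y_1 = x_1`, `y_2 = F_2(x_2)`,
#' `y_i = F_i(x_i + y_(i-1))` for `i > 2` with each `F_i` a 3x3
#' convolution (+ batch norm + ReLU), concatenation, a closing 1x1
#' convolution, and a residual connection from the block input. Each later
#' subset sees an increasingly large receptive field, which is what lets a
#' single block represent vessel calibers from main trunks to capillaries.
#' @noRd
fwd_msf_block <- function(tape, x, ly, k, train) {
  C <- dim(x$v)[3]
  if (C %% k != 0) stop("channel count not divisible by k")
  h <- fwd_conv_bn_relu(tape, x, ly$open, ly$open_bn, train)
  cs <- C %/% k
  ys <- vector("list", k)
  for (i in seq_len(k)) {
    xi <- op_slice(tape, h, (i - 1L) * cs + seq_len(cs))
    ys[[i]] <- if (i == 1L) xi
    else {
      inp <- if (i == 2L) xi else op_add(tape, xi, ys[[i - 1L]])
      fwd_conv_bn_relu(tape, inp, ly$fs[[i - 1L]], ly$fs_bn[[i - 1L]], train)
    }
  }
  cat_node <- ys[[1L]]
  if (k > 1L) for (i in 2:k) cat_node <- op_concat(tape, cat_node, ys[[i]])
  out <- op_bn(tape, op_conv(tape, cat_node, ly$close), ly$close_bn, train)
  op_relu(tape, op_add(tape, out, x))
}

fwd_plain_block <- function(tape, x, ly, train) {
  h <- fwd_conv_bn_relu(tape, x, ly$c1, ly$b1, train)
  fwd_conv_bn_relu(tape, h, ly$c2, ly$b2, train)
}

fwd_block <- function(tape, x, ly, config, train) {
  if (config$use_msf) fwd_msf_block(tape, x, ly, config$k, train)
  else fwd_plain_block(tape, x, ly, train)
}

#' Forward pass of the network
#'
#' Runs a patch (or batch of patches) through the network. When the
#' vessel-constraint module is active, the pre-classifier artery/vein
#' features are multiplied element-wise (broadcast over channels) by
#' [vc_weight()] of the vessel probability map before the final 1x1
#' classifier and softmax.
#'
#' @param model A `vc_model`.
#' @param x Input array `(H, W, 3)` or `(H, W, 3, N)` with intensities in
#'   `[0, 1]`; `H`, `W` must be divisible by `2^(depth-1)`.
#' @param train Logical; batch-norm uses batch statistics (and updates
#'   running statistics) when `TRUE`, running statistics when `FALSE`.
#' @param alpha Optional override of the configured vessel-constraint
#'   strength (the test-time alpha sweep).
#' @param tape Internal: an autograd tape to record onto.
#' @return A list with `vessel` (`H x W [x N]` vessel probabilities),
#'   `av` (`H x W x 3 [x N]` class probabilities summing to 1 per pixel),
#'   and, when a tape is supplied, the tape and the logit nodes.
#' @export
model_forward <- function(model, x, train = FALSE, alpha = NULL, tape = NULL) {
  cfg <- model$config
  x <- as_batch(x)
  d <- dim(x)
  div <- 2^(cfg$depth - 1L)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf(
      "patch size %dx%d not divisible by %d; pad the input first",
      d[1], d[2], div))
  if (is.null(alpha)) alpha <- cfg$alpha
  keep_tape <- !is.null(tape)
  if (is.null(tape)) tape <- ag_tape()
  if (keep_tape) tape$grad <- TRUE   # cache activations needed for backward
  L <- model$layers

  x_in <- op_input(tape, x)
  h <- fwd_conv_bn_relu(tape, x_in, L$stem, L$stem_bn, train)
  skips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    h <- fwd_block(tape, h, L$enc[[l]], cfg, train)
    skips[[l]] <- h
    if (l < cfg$depth) {
      h <- op_maxpool(tape, h)
      h <- fwd_conv_bn_relu(tape, h, L$trans[[l]]$cv, L$trans[[l]]$bn, train)
    }
  }
  for (i in seq_len(cfg$depth - 1L)) {
    l <- cfg$depth - i            # level being restored
    dec <- L$dec[[i]]
    h <- op_upsample(tape, h, cfg$upsample_mode)
    h <- fwd_conv_bn_relu(tape, h, dec$reduce, dec$reduce_bn, train)
    h <- op_concat(tape, h, skips[[l]])
    h <- fwd_conv_bn_relu(tape, h, dec$fuse, dec$fuse_bn, train)
  }

  h <- op_concat(tape, h, x_in)   # input skip into both heads
  vf <- fwd_conv_bn_relu(tape, h, L$vessel_feat, L$vessel_feat_bn, train)
  vessel_logits <- op_conv(tape, vf, L$vessel_out)
  vessel_prob <- op_sigmoid(tape, vessel_logits)

  af <- fwd_conv_bn_relu(tape, h, L$av_feat, L$av_feat_bn, train)
  if (cfg$use_vc) {
    wmap <- op_vc_weight(tape, vessel_prob, alpha, detach = cfg$vc_detach)
    af <- op_mul_bcast(tape, af, wmap)
  }
  av_logits <- op_conv(tape, af, L$av_out)
  av <- softmax3(av_logits$v)

  vessel <- vessel_prob$v
  res <- list(vessel = drop_last(vessel[, , 1L, , drop = FALSE]),
              av = drop_batch(av))
  if (keep_tape) {
    res$tape <- tape
    res$vessel_logits <- vessel_logits
    res$av_logits <- av_logits
    res$vessel_prob_node <- vessel_prob
  }
  res
}

# Stable softmax over the channel dimension of (H, W, 3, N).
softmax3 <- function(z) {
  m <- pmax(z[, , 1L, , drop = FALSE], z[, , 2L, , drop = FALSE],
            z[, , 3L, , drop = FALSE])
  e <- exp(z - m[, , rep(1L, 3L), , drop = FALSE])
  s <- e[, , 1L, , drop = FALSE] + e[, , 2L, , drop = FALSE] +
       e[, , 3L, , drop = FALSE]
  e / s[, , rep(1L, 3L), , drop = FALSE]
}

# (H, W, 1, N) -> H x W (N == 1) or (H, W, N)
drop_last <- function(x) {
  d <- dim(x)
  if (d[4] == 1L) array(x, d[1:2]) else array(x, d[c(1, 2, 4)])
}

# (H, W, 3, N) -> (H, W, 3) when N == 1
drop_batch <- function(x) {
  d <- dim(x)
  if (d[4] == 1L) array(x, d[1:3]) else x
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints embed the configuration, all parameter values, and the
#' batch-norm running statistics.
#' @param model A `vc_model`.
#' @param path File path (`.rds`).
#' @export
save_model <- function(model, path) {
  state <- list(config = unclass(model$config),
                values = lapply(model$params, function(p) p$v),
                stats = lapply(Filter(function(l) l$type == "bn",
                                      collect_layers(model$layers)),
                               function(l) list(rmean = l$stats$rmean,
                                                rvar = l$stats$rvar)))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  cfg <- do.call(model_config, state$config)
  model <- build_model(cfg, seed = 0L)
  stopifnot(length(model$params) == length(state$values))
  for (i in seq_along(model$params)) model$params[[i]]$v <- state$values[[i]]
  bns <- Filter(function(l) l$type == "bn", collect_layers(model$layers))
  stopifnot(length(bns) == length(state$stats))
  for (i in seq_along(bns)) {
    bns[[i]]$stats$rmean <- state$stats[[i]]$rmean
    bns[[i]]$stats$rvar <- state$stats[[i]]$rvar
  }
  model
}
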