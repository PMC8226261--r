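# Layer constructors and tape ops. Layers hold parameter environments; ops
# take/return ag_node objects so gradients flow through arbitrary wiring.

conv_layer <- function(k, cin, cout) {
  # He-normal fan-in initialization; ReLU network throughout.
  sd <- sqrt(2 / (k * k * cin))
  w <- array(rnorm(k * k * cin * cout, sd = sd), c(k, k, cin, cout))
  list(type = "conv", k = k, cin = cin, cout = cout,
       w = new_param(w), b = new_param(numeric(cout)))
}

bn_layer <- function(c) {
  list(type = "bn", c = c,
       gamma = new_param(rep(1, c)), beta = new_param(numeric(c)),
       stats = local({
         e <- new.env(parent = emptyenv())
         e$rmean <- numeric(c); e$rvar <- rep(1, c); e
       }))
}

layer_params <- function(ly) {
  switch(ly$type, conv = list(ly$w, ly$b), bn = list(ly$gamma, ly$beta))
}

op_input <- function(tape, x) ag_node(tape, as_batch(x), leaf = TRUE)

op_conv <- function(tape, x, ly) {
  y <- conv2d_fwd_cpp(x$v, ly$w$v, ly$b$v)
  ag_node(tape, y, backward = function(g) {
    r <- conv2d_bwd_cpp(x$v, ly$w$v, g, !isTRUE(x$leaf))
    param_accum(ly$w, r$gw)
    param_accum(ly$b, r$gb)
    if (!is.null(r$gx)) ag_accum(x, r$gx)
  })
}

# Batch norm, optionally fused with a ReLU (the ubiquitous conv-bn-relu
# pattern); fusing avoids a full-size intermediate array in each direction.
op_bn <- function(tape, x, ly, train, relu = FALSE) {
  r <- bn_fwd_cpp(x$v, ly$gamma$v, ly$beta$v, ly$stats$rmean, ly$stats$rvar,
                  train, 0.1, 1e-5, relu)
  y <- r$y
  if (train) {
    ly$stats$rmean <- r$rmean
    ly$stats$rvar <- r$rvar
    xhat <- r$xhat
    invstd <- r$invstd
    ag_node(tape, y, backward = function(g) {
      b <- bn_bwd_cpp(g, xhat, invstd, ly$gamma$v, if (relu) y, relu)
      param_accum(ly$gamma, b$ggamma)
      param_accum(ly$beta, b$gbeta)
      ag_accum(x, b$gx)
    })
  } else {
    # Eval mode: y = gamma*(x - rmean)*invstd + beta, an affine map per channel.
    invstd <- r$invstd
    ag_node(tape, y, backward = function(g) {
      if (relu) g <- relu_bwd_cpp(g, y)
      sc <- ly$gamma$v * invstd
      gx <- g * rep(sc, each = prod(dim(g)[1:2]))[seq_len(prod(dim(g)[1:3]))]
      dim(gx) <- dim(g)
      ag_accum(x, gx)
    })
  }
}

op_relu <- function(tape, x) {
  v <- x$v
  ag_node(tape, relu_fwd_cpp(v),
          backward = function(g) ag_accum(x, relu_bwd_cpp(g, v)))
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$v))
  ag_node(tape, y, backward = function(g) ag_accum(x, g * y * (1 - y)))
}

op_maxpool <- function(tape, x) {
  r <- maxpool2_fwd_cpp(x$v)
  xd <- dim(x$v)
  ag_node(tape, r$y, backward = function(g)
    ag_accum(x, maxpool2_bwd_cpp(g, r$idx, xd)))
}

op_upsample <- function(tape, x, mode = "bilinear") {
  xd <- dim(x$v)
  y <- upsample2_fwd_cpp(x$v, mode)
  ag_node(tape, y, backward = function(g)
    ag_accum(x, upsample2_bwd_cpp(g, xd, mode)))
}

op_concat <- function(tape, a, b) {
  da <- dim(a$v); db <- dim(b$v)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$v
  y[, , da[3] + seq_len(db[3]), ] <- b$v
  ag_node(tape, y, backward = function(g) {
    ag_accum(a, g[, , seq_len(da[3]), , drop = FALSE])
    ag_accum(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

op_add <- function(tape, a, b) {
  ag_node(tape, a$v + b$v, backward = function(g) {
    ag_accum(a, g)
    ag_accum(b, g)
  })
}

op_slice <- function(tape, x, ch) {
  y <- x$v[, , ch, , drop = FALSE]
  ag_node(tape, y, backward = function(g) {
    gx <- array(0, dim(x$v))
    gx[, , ch, ] <- g
    ag_accum(x, gx)
  })
}

# Multiply every channel of x by a single-channel map w (H, W, 1, N).
op_mul_bcast <- function(tape, x, w) {
  C <- dim(x$v)[3]
  wf <- w$v[, , rep(1L, C), , drop = FALSE]
  ag_node(tape, x$v * wf, backward = function(g) {
    ag_accum(x, g * wf)
    gw <- g * x$v
    gw <- array(rowSums(aperm(gw, c(1, 2, 4, 3)), dims = 3),
                c(dim(g)[1], dim(g)[2], 1, dim(g)[4]))
    ag_accum(w, gw)
  })
}

# Vessel-constraint Gaussian activation as a tape op (see vc_weight()).
# detach = TRUE blocks the gradient into the vessel probability map.
op_vc_weight <- function(tape, p, alpha, detach = FALSE) {
  v <- p$v
  y <- vc_weight(v, alpha)
  ag_node(tape, y, backward = function(g) {
    if (detach) return(invisible(NULL))
    d <- -alpha * sign(v - 0.5) * exp(-abs(v - 0.5))  # subgradient 0 at 0.5
    ag_accum(p, g * d)
  })
}
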