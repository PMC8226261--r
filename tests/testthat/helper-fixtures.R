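# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# A small rendered scene (176 px so full-image prediction divides by 4).
tiny_scene <- function(seed = 3L) {
  fixture(paste0("scene", seed), function()
    render_scene(scene_spec(image_size = 176L, seed = seed)))
}

# A tiny untrained model shared by shape/determinism tests.
tiny_model <- function() {
  fixture("tiny_model", function()
    build_model(model_config(k = 2, base_channels = 4, depth = 2), seed = 7L))
}

# Brute-force AUC by Mann-Whitney pair counting (ties count 1/2).
auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Reference (eval-mode) batch norm on an (H, W, C) array.
bn_reference <- function(x, bnly) {
  for (c in seq_len(dim(x)[3]))
    x[, , c] <- bnly$gamma$v[c] *
      (x[, , c] - bnly$stats$rmean[c]) / sqrt(bnly$stats$rvar[c] + 1e-5) +
      bnly$beta$v[c]
  x
}

# Reference multi-scale block: explicit per-subset loop over the hierarchy
# y_1 = x_1; y_2 = F_2(x_2); y_i = F_i(x_i + y_{i-1}), all in plain R on an
# (H, W, C) array, reading the same layer parameters the package uses.
msf_reference <- function(x, ly, k) {
  relu <- function(z) pmax(z, 0)
  h <- relu(bn_reference(conv2d_reference(x, ly$open$w$v, ly$open$b$v),
                         ly$open_bn))
  C <- dim(h)[3]; cs <- C %/% k
  ys <- vector("list", k)
  for (i in seq_len(k)) {
    xi <- h[, , (i - 1) * cs + seq_len(cs), drop = FALSE]
    ys[[i]] <- if (i == 1) xi else {
      inp <- if (i == 2) xi else xi + ys[[i - 1]]
      relu(bn_reference(
        conv2d_reference(inp, ly$fs[[i - 1]]$w$v, ly$fs[[i - 1]]$b$v),
        ly$fs_bn[[i - 1]]))
    }
  }
  cat_y <- array(unlist(ys), dim(h))
  out <- bn_reference(conv2d_reference(cat_y, ly$close$w$v, ly$close$b$v),
                      ly$close_bn)
  pmax(out + x, 0)
}

# Run one msf block of a built model through the package's own tape ops in
# eval mode, returning an (H, W, C) array.
msf_block_forward <- function(x, ly, k) {
  tape <- retinav:::ag_tape()
  xin <- retinav:::op_input(tape, x)
  out <- retinav:::fwd_msf_block(tape, xin, ly, k, train = FALSE)
  array(out$v, dim(out$v)[1:3])
}

# Reference 2-d "same" convolution by direct looping (independent of the
# compiled kernels); x: (H, W, Cin), w: (k, k, Cin, Cout), returns (H, W, Cout).
conv2d_reference <- function(x, w, b) {
  k <- dim(w)[1]; pad <- k %/% 2
  H <- dim(x)[1]; W <- dim(x)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  y <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(b[co], H, W)
    for (ci in seq_len(cin)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
      di <- ki - 1L - pad; dj <- kj - 1L - pad
      src_i <- (1 + max(0, di)):(H + min(0, di))
      src_j <- (1 + max(0, dj)):(W + min(0, dj))
      acc[src_i - di, src_j - dj] <- acc[src_i - di, src_j - dj] +
        w[ki, kj, ci, co] * x[src_i, src_j, ci]
    }
    y[, , co] <- acc
  }
  y
}
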