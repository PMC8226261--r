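# Network architecture: block semantics, shape contracts, determinism,
# and end-to-end differentiability.

test_that("msf block agrees with the explicit per-subset reference", {
  set.seed(101)
  for (k in c(1, 2, 4)) {
    C <- 8L
    ly <- local({
      set.seed(200 + k)
      retinav:::msf_block_layers(C, k)
    })
    for (rep in 1:3) {
      x <- array(rnorm(16 * 16 * C), c(16, 16, C))
      got <- msf_block_forward(array(x, c(16, 16, C, 1)), ly, k)
      want <- msf_reference(x, ly, k)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("msf block with k = 1 has no 3x3 stage and preserves shape", {
  ly <- retinav:::msf_block_layers(8L, 1L)
  expect_length(ly$fs, 0)
  x <- array(rnorm(32 * 32 * 8), c(32, 32, 8, 1))
  y <- msf_block_forward(x, ly, 1L)
  expect_identical(dim(y), c(32L, 32L, 8L))
})

test_that("zeroing the opening 1x1 leaves only the residual path", {
  # With the split path silenced at its entry, the block reduces to
  # ReLU(input): identity on nonnegative inputs.
  set.seed(11)
  ly <- retinav:::msf_block_layers(8L, 4L)
  ly$open$w$v[] <- 0
  ly$open$b$v[] <- 0
  ly$close$b$v[] <- 0
  ly$close_bn$beta$v[] <- 0
  x <- array(runif(16 * 16 * 8), c(16, 16, 8, 1))
  y <- msf_block_forward(x, ly, 4L)
  expect_equal(y, array(x, c(16, 16, 8)), tolerance = 1e-12)
})

test_that("forward respects shape contracts and softmax/sigmoid ranges", {
  m <- build_model(model_config(k = 1, base_channels = 8, depth = 2,
                                use_vc = FALSE), seed = 2)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- model_forward(m, x)
  expect_identical(dim(out$vessel), c(64L, 64L))
  expect_identical(dim(out$av), c(64L, 64L, 3L))
  expect_true(all(out$vessel >= 0 & out$vessel <= 1))
  sums <- out$av[, , 1] + out$av[, , 2] + out$av[, , 3]
  expect_equal(sums, matrix(1, 64, 64), tolerance = 1e-6)
})

test_that("indivisible patch sizes are rejected with advice to pad", {
  m <- tiny_model()   # depth 2 -> divisible by 2
  expect_error(model_forward(m, array(0.5, c(15, 16, 3))), "pad")
})

test_that("two builds with the same config and seed are identical; msf toggles parameters", {
  cfg <- model_config(k = 2, base_channels = 8, depth = 2)
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  expect_identical(lapply(m1$params, function(p) p$v),
                   lapply(m2$params, function(p) p$v))
  m3 <- build_model(model_config(k = 2, base_channels = 8, depth = 2,
                                 use_msf = FALSE), seed = 5)
  expect_false(n_parameters(m1) == n_parameters(m3))
})

test_that("inference is deterministic and alpha -> 0 approaches the unconstrained branch", {
  m <- tiny_model()
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  o1 <- model_forward(m, x)
  o2 <- model_forward(m, x)
  expect_identical(o1$av, o2$av)
  expect_identical(o1$vessel, o2$vessel)
  # F -> 1 uniformly as alpha -> 0+, so the constrained output converges to
  # the output with the module disabled.
  o_small <- model_forward(m, x, alpha = 1e-8)
  cfg_off <- m$config; cfg_off$use_vc <- FALSE
  m_off <- m; m_off$config <- cfg_off
  o_off <- model_forward(m_off, x)
  expect_equal(o_small$av, o_off$av, tolerance = 1e-6)
})

test_that("analytic gradients match finite differences end to end", {
  set.seed(42)
  cfg <- model_config(k = 2, base_channels = 4, depth = 2, alpha = 1.3)
  model <- build_model(cfg, seed = 7)
  ps <- 16L
  xb <- array(runif(ps * ps * 3), c(ps, ps, 3, 1))
  lb <- array(sample(0:3, ps * ps, TRUE, prob = c(.5, .2, .2, .1)),
              c(ps, ps, 1))
  vb <- array(runif(ps * ps) < 0.9, c(ps, ps, 1))
  wts <- loss_weights()

  loss_of <- function() {
    out <- model_forward(model, xb, train = TRUE)
    av <- out$av; dim(av) <- c(ps, ps, 3, 1)
    vessel <- out$vessel; dim(vessel) <- c(ps, ps, 1)
    la <- av_cross_entropy(av, lb, vb & (lb != 3L))
    lv <- vessel_bce(vessel, lb != 0L, vb)
    total_loss(la, lv, wts, retinav:::conv_sq_norm(model))
  }

  retinav:::zero_grads(model$params)
  out <- model_forward(model, xb, train = TRUE, tape = retinav:::ag_tape())
  av <- out$av; dim(av) <- c(ps, ps, 3, 1)
  vessel <- out$vessel; dim(vessel) <- c(ps, ps, 1)
  av_valid <- vb & (lb != 3L)
  onehot <- array(0, dim(av)); hw <- ps * ps
  idx <- which(av_valid)
  onehot[(idx - 1L) %% hw + hw * lb[idx] + 1L] <- 1
  mask4 <- array(av_valid * 1, c(ps, ps, 1, 1))[, , rep(1, 3), , drop = FALSE]
  retinav:::ag_accum(out$av_logits,
                     wts$gamma * (av - onehot) * mask4 / sum(av_valid))
  g_v <- wts$delta * (vessel - (lb != 0L)) * (vb * 1) / sum(vb)
  dim(g_v) <- c(ps, ps, 1, 1)
  retinav:::ag_accum(out$vessel_logits, g_v)
  retinav:::ag_backward(out$tape)
  for (p in model$conv_weights)
    retinav:::param_accum(p, 2 * wts$beta * p$v)

  eps <- 1e-5
  set.seed(99)
  n_checked <- 0L
  for (rep in 1:30) {
    pi_ <- sample(length(model$params), 1)
    p <- model$params[[pi_]]
    if (is.null(p$g)) next
    k <- sample(length(p$v), 1)
    old <- p$v[k]
    p$v[k] <- old + eps; Lp <- loss_of()
    p$v[k] <- old - eps; Lm <- loss_of()
    p$v[k] <- old
    g_fd <- (Lp - Lm) / (2 * eps)
    rel <- abs(p$g[k] - g_fd) / max(abs(p$g[k]), abs(g_fd), 1e-8)
    expect_lt(rel, 1e-2)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 20L)
})

test_that("checkpoints round-trip through save and load", {
  m <- build_model(model_config(k = 2, base_channels = 4, depth = 2), seed = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(model_forward(m, x)$av, model_forward(m2, x)$av)
})
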