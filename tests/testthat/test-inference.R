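# Tiling, stitching, thresholding, artery/vein decisions.

test_that("tiling grid arithmetic matches hand-derived cases", {
  img <- array(0.5, c(512, 512, 3))
  g <- tile_image(img, 512L, 512L)
  expect_identical(nrow(g$origins), 1L)
  expect_identical(g$padded_shape, c(512L, 512L))

  img2 <- array(0.5, c(600, 600, 3))
  g2 <- tile_image(img2, 512L, 256L)
  expect_identical(g2$padded_shape, c(768L, 768L))
  expect_identical(nrow(g2$origins), 4L)
  expect_identical(unique(g2$origins[, 1]), c(0L, 256L))
  # row-major origin order
  expect_identical(g2$origins[, 1], c(0L, 0L, 256L, 256L))
})

test_that("every pixel is covered by at least one patch (randomized sizes)", {
  set.seed(77)
  for (r in 1:8) {
    h <- sample(40:200, 1); w <- sample(40:200, 1)
    ps <- sample(c(32L, 48L, 64L), 1)
    st <- sample(seq_len(ps), 1)
    g <- tile_image(array(0, c(h, w, 1)), ps, st)
    cover <- matrix(0L, g$padded_shape[1], g$padded_shape[2])
    for (t in seq_len(nrow(g$origins))) {
      ri <- g$origins[t, 1] + seq_len(ps); rj <- g$origins[t, 2] + seq_len(ps)
      cover[ri, rj] <- cover[ri, rj] + 1L
    }
    expect_gte(min(cover), 1L)
  }
  expect_error(tile_image(array(0, c(64, 64, 1)), 32L, 0L), "positive")
  expect_error(tile_image(array(0, c(64, 64, 1)), 32L, 40L), "exceed")
})

test_that("stitching averages overlaps and crops padding", {
  img <- array(0, c(48, 64, 3))
  g <- tile_image(img, 32L, 16L)
  mkpred <- function(v) list(vessel = matrix(v, 32, 32),
                             av = array(1 / 3, c(32, 32, 3)))
  # two constant levels alternating: overlap regions average the values
  preds <- lapply(seq_len(nrow(g$origins)), function(t)
    mkpred(if (t %% 2 == 0) 0.6 else 0.2))
  out <- stitch(g, preds)
  expect_identical(dim(out$vessel), c(48L, 64L))
  expect_true(all(out$vessel >= 0.2 & out$vessel <= 0.6))
  s <- out$av[, , 1] + out$av[, , 2] + out$av[, , 3]
  expect_equal(s, matrix(1, 48, 64))
  # two half-overlapping constant patches: the overlap is the mean
  g1 <- tile_image(array(0, c(32, 48, 3)), 32L, 16L)
  preds2 <- list(mkpred(0.2), mkpred(0.6))
  out2 <- stitch(g1, preds2)
  expect_true(all(out2$vessel[, 1:16] == 0.2))
  expect_true(all(out2$vessel[, 17:32] == 0.4))   # averaged overlap
  expect_error(stitch(g1, preds2[1]), "per patch")
})

test_that("non-overlapping stitched prediction equals per-tile forwards bitwise", {
  m <- tiny_model()
  sc <- tiny_scene()
  img <- sc$image$pixels[1:64, 1:128, , drop = FALSE]
  pr <- predict_image(m, img, patch_size = 64L, stride = 64L)
  direct_l <- model_forward(m, img[, 1:64, , drop = FALSE])
  direct_r <- model_forward(m, img[, 65:128, , drop = FALSE])
  expect_identical(pr$vessel[, 1:64], direct_l$vessel)
  expect_identical(pr$vessel[, 65:128], direct_r$vessel)
  expect_equal(pr$av[, 1:64, ], direct_l$av, tolerance = 1e-12)
})

test_that("prediction is deterministic and continuous in alpha", {
  m <- tiny_model()
  img <- tiny_scene()$image$pixels[1:64, 1:64, , drop = FALSE]
  p1 <- predict_image(m, img, 64L, 64L)
  p2 <- predict_image(m, img, 64L, 64L)
  expect_identical(p1$av, p2$av)
  pa <- predict_image(m, img, 64L, 64L, alpha = 1)
  pb <- predict_image(m, img, 64L, 64L, alpha = 1 + 1e-3)
  expect_lt(max(abs(pa$av - pb$av)), 1e-2)
  # alpha -> 0+ converges to the unconstrained branch
  p0 <- predict_image(m, img, 64L, 64L, alpha = 1e-9)
  m_off <- m; m_off$config$use_vc <- FALSE
  poff <- predict_image(m_off, img, 64L, 64L)
  expect_equal(p0$av, poff$av, tolerance = 1e-7)
})

test_that("vessel thresholding uses the >= tie rule and validates input", {
  expect_true(all(binarize_vessels(matrix(0.6, 3, 3))))
  expect_false(any(binarize_vessels(matrix(0.4, 3, 3))))
  expect_true(all(binarize_vessels(matrix(0.5, 3, 3))))  # ties are vessel
  expect_error(binarize_vessels(matrix(0.4, 2, 2), threshold = 0), "0, 1")
  expect_error(binarize_vessels(matrix(1.4, 2, 2)), "probabilities")
})

test_that("artery/vein decisions ignore background and break ties to artery", {
  av <- array(0, c(2, 2, 3))
  av[, , 1] <- 0.8; av[, , 2] <- 0.1; av[, , 3] <- 0.1
  dom <- matrix(TRUE, 2, 2)
  dec <- classify_av(av, dom)
  expect_true(all(dec == AV_CLASSES[["ARTERY"]]))   # tie -> artery
  av[1, 1, ] <- c(0.1, 0.6, 0.3)
  av[2, 2, ] <- c(0.1, 0.2, 0.7)
  av[2, 1, ] <- c(0.8, 0.15, 0.05)
  av[1, 2, ] <- c(0.0, 0.45, 0.55)
  dec2 <- classify_av(av, dom)
  expect_identical(dec2[1, 1], AV_CLASSES[["ARTERY"]])
  expect_identical(dec2[2, 2], AV_CLASSES[["VEIN"]])
  # swapping channels swaps every (untied) decision
  av_sw <- av[, , c(1, 3, 2)]
  dec_sw <- classify_av(av_sw, dom)
  expect_true(all((dec2 == 1) == (dec_sw == 2)))
  expect_error(classify_av(av, matrix(FALSE, 2, 2)), "empty")
  # outside the domain nothing is decided
  dom2 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_identical(classify_av(av, dom2)[2, 2], AV_CLASSES[["BACKGROUND"]])
})
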