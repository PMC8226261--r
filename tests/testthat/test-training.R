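# Patch sampling, augmentation, schedule, fusion, and the optimizer loop.

test_that("learning rate follows the halving schedule exactly", {
  expect_equal(lr_schedule(0), 0.001)
  expect_equal(lr_schedule(1499), 0.001)
  expect_equal(lr_schedule(1500), 0.0005)
  expect_equal(lr_schedule(3000), 0.00025)
  expect_equal(lr_schedule(3999), 0.00025)
  it <- 0:5000
  expect_equal(lr_schedule(it, 0.001, 1500L),
               0.001 * 0.5^floor(it / 1500))
})

test_that("an image exactly patch-sized yields the whole image", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  lab <- matrix(0L, 32, 32); val <- matrix(TRUE, 32, 32)
  p <- sample_patch(img, lab, val, 32L)
  expect_identical(p$image, img)
  expect_identical(p$corner, c(0L, 0L))
})

test_that("patch corners are uniform over the feasible range", {
  set.seed(31)
  img <- array(0, c(60, 60, 3))
  lab <- matrix(0L, 60, 60); val <- matrix(TRUE, 60, 60)
  corners <- t(replicate(1000, sample_patch(img, lab, val, 16L)$corner))
  # corners uniform over {0..44}: mean 22 with se ~0.41
  expect_lt(abs(mean(corners[, 1]) - 22), 2)
  expect_lt(abs(mean(corners[, 2]) - 22), 2)
  expect_gte(min(corners), 0)
  expect_lte(max(corners), 44)
})

test_that("small images are reflection-padded before sampling", {
  img <- array(runif(20 * 20 * 3), c(20, 20, 3))
  lab <- matrix(1L, 20, 20); val <- matrix(TRUE, 20, 20)
  set.seed(1)
  p <- sample_patch(img, lab, val, 32L)
  expect_identical(dim(p$image), c(32L, 32L, 3L))
  expect_identical(p$image[1:20, 1:20, ], img)
  # reflected row 21 equals row 19
  expect_identical(p$image[21, 1:20, ], img[19, 1:20, ])
})

test_that("identity augmentation is the identity", {
  sc <- as_training_scene(tiny_scene())
  set.seed(2)
  p <- sample_patch(sc$image, sc$labels, sc$valid, 64L)
  a <- augment_patch(p, scales = 1, angles = 0)
  expect_identical(a$image, p$image)
  expect_identical(a$labels, p$labels)
})

test_that("90-degree rotation equals the array index permutation", {
  set.seed(3)
  n <- 33L  # odd so the centre pixel is exact
  img <- array(runif(n * n * 3), c(n, n, 3))
  lab <- matrix(sample(0:3, n * n, TRUE), n, n)
  val <- matrix(TRUE, n, n)
  a <- augment_patch(list(image = img, labels = lab, valid = val),
                     scales = 1, angles = 90)
  # with an odd edge the sources are exact integers: out[i, j] = in[n+1-j, i]
  lab_ref <- t(lab[n:1, ])
  expect_identical(unname(a$labels), unname(lab_ref))
  expect_true(all(a$valid))
  img_ref <- img
  for (c in 1:3) img_ref[, , c] <- t(img[n:1, , c])
  expect_equal(a$image, img_ref, tolerance = 1e-12)
})

test_that("augmented label patches contain only original class values", {
  sc <- as_training_scene(tiny_scene())
  set.seed(5)
  for (r in 1:5) {
    p <- sample_patch(sc$image, sc$labels, sc$valid, 64L)
    a <- augment_patch(p, scales = c(0.8, 1.2), angles = c(37, 90, 215))
    expect_true(all(a$labels %in% unique(as.vector(p$labels))))
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
})

test_that("dataset fusion concatenates train entries and shuffles by seed", {
  mk <- function(name, n_train, n_test) {
    entries <- c(
      lapply(seq_len(n_train), function(i)
        list(image = paste0(name, i, ".png"), label = "l.png",
             split = "train")),
      lapply(seq_len(n_test), function(i)
        list(image = paste0(name, "t", i, ".png"), label = "l.png",
             split = "test")))
    manifest(name, entries)
  }
  mans <- list(mk("a", 20, 3), mk("b", 11, 2), mk("c", 15, 4))
  fused <- fuse_datasets(mans, seed = 9)
  splits <- vapply(fused$entries, `[[`, "", "split")
  expect_identical(sum(splits == "train"), 46L)   # 20 + 11 + 15
  expect_identical(sum(splits == "test"), 9L)
  srcs <- vapply(fused$entries, `[[`, "", "source")
  expect_setequal(unique(srcs), c("a", "b", "c"))
  # same seed -> same permutation; different seed -> different
  fused2 <- fuse_datasets(mans, seed = 9)
  expect_identical(vapply(fused$entries, `[[`, "", "image"),
                   vapply(fused2$entries, `[[`, "", "image"))
  fused3 <- fuse_datasets(mans, seed = 10)
  expect_false(identical(vapply(fused$entries, `[[`, "", "image"),
                         vapply(fused3$entries, `[[`, "", "image")))
  # single manifest: same entries, permuted
  f1 <- fuse_datasets(mans[1], seed = 2)
  expect_setequal(vapply(f1$entries, `[[`, "", "image"),
                  vapply(mans[[1]]$entries, `[[`, "", "image"))
})

test_that("zero iterations leave the model untouched", {
  sc <- as_training_scene(tiny_scene())
  m <- build_model(model_config(k = 2, base_channels = 4, depth = 2), seed = 3)
  before <- lapply(m$params, function(p) p$v)
  m2 <- suppressWarnings(
    train_model(m, list(sc), train_config(patch_size = 64L,
                                          max_iterations = 0L)))
  expect_identical(lapply(m2$params, function(p) p$v), before)
})

test_that("short training decreases the loss and is seed-reproducible", {
  scenes <- lapply(c(3L, 13L), function(s) as_training_scene(tiny_scene(s)))
  run <- function() {
    m <- build_model(tiny_model_config(), seed = 11)
    tc <- tiny_train_config(patch_size = 64L, max_iterations = 60L,
                            batch_size = 2L, lr_halving_period = 60L,
                            seed = 11)
    attr(train_model(m, scenes, tc), "log")
  }
  lg1 <- run()
  expect_lt(mean(tail(lg1$loss_total, 15)), mean(head(lg1$loss_total, 15)))
  lg2 <- run()
  expect_identical(lg1$loss_total, lg2$loss_total)   # bitwise reproducible
  expect_equal(lg1$lr, lr_schedule(lg1$iteration - 1, 0.01, 60L))
})
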