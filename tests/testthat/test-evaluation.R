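# FOV-restricted metrics: confusion counts, ratios, AUC, report assembly.

test_that("confusion counts match hand counts and respond to single flips", {
  truth <- matrix(0L, 5, 5)
  truth[1, 1:5] <- 1L   # 5 artery
  truth[2, 1:5] <- 2L   # 5 vein
  truth[3, 1] <- 3L     # uncertain: never scored
  fov <- matrix(TRUE, 5, 5)
  pred <- matrix(0L, 5, 5)
  pred[1, ] <- 1L; pred[2, ] <- 2L; pred[3, 1] <- 1L
  c0 <- av_confusion(pred, truth, fov)
  expect_identical(c0[c("TP", "TN", "FP", "FN")],
                   list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  expect_identical(c0$n_scored, 10L)
  # all-artery prediction on 10 artery + 10 vein
  truth2 <- matrix(c(rep(1L, 10), rep(2L, 10)), 4, 5)
  pred2 <- matrix(1L, 4, 5)
  c2 <- av_confusion(pred2, truth2, matrix(TRUE, 4, 5))
  expect_identical(c2[c("TP", "TN", "FP", "FN")],
                   list(TP = 10L, TN = 0L, FP = 10L, FN = 0L))
  # toggling one vein prediction to artery moves exactly one count TN -> FP
  pred3 <- pred; pred3[2, 3] <- 1L
  c3 <- av_confusion(pred3, truth, fov)
  expect_identical(c3$TN, c0$TN - 1L)
  expect_identical(c3$FP, c0$FP + 1L)
  expect_identical(c3$TP, c0$TP)
  expect_error(av_confusion(pred, matrix(0L, 5, 5), fov), "scorable")
})

test_that("av metrics match hand-computed ratios and the BACC identity", {
  m <- av_metrics(list(TP = 8, FN = 2, TN = 9, FP = 1))
  expect_equal(m$se_av, 0.8)
  expect_equal(m$sp_av, 0.9)
  expect_equal(m$bacc, 0.85)
  expect_equal(m$f1_a, 16 / 19)
  expect_equal(m$f1_v, 18 / 21)
  perfect <- av_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_true(all(unlist(perfect) == 1))
  # undefined, not zero, on empty denominators
  none <- av_metrics(list(TP = 0, FN = 0, TN = 5, FP = 1))
  expect_true(is.na(none$se_av))
  expect_true(is.na(none$bacc))
})

test_that("swapping artery and vein everywhere swaps SE/SP and F1s", {
  set.seed(12)
  truth <- matrix(sample(0:3, 400, TRUE), 20, 20)
  pred <- matrix(sample(1:2, 400, TRUE), 20, 20)
  fov <- matrix(runif(400) < 0.9, 20, 20)
  m <- av_metrics(av_confusion(pred, truth, fov))
  swap <- function(x) ifelse(x == 1L, 2L, ifelse(x == 2L, 1L, x))
  m2 <- av_metrics(av_confusion(swap(pred), swap(truth), fov))
  expect_equal(m$se_av, m2$sp_av)
  expect_equal(m$f1_a, m2$f1_v)
  expect_equal(m$bacc, m2$bacc)
})

test_that("trapezoid AUC equals pair counting on toys and random instances", {
  # 6-pixel toy: 8 of 9 positive-negative pairs ranked correctly
  truth <- c(1, 1, 1, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.4, 0.6, 0.2, 0.1)
  expect_equal(auc_trapezoid(probs, truth), 8 / 9)
  expect_equal(auc_trapezoid(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc_trapezoid(c(1, 0), c(1, 0)), 1)
  expect_true(is.na(auc_trapezoid(runif(5), rep(1, 5))))
  set.seed(66)
  for (r in 1:25) {
    sc <- sample(seq(0, 1, by = 0.1), 50, TRUE)   # heavy ties
    y <- runif(50) < 0.4
    if (!any(y) || all(y)) next
    expect_equal(auc_trapezoid(sc, y), auc_pairs(sc, y), tolerance = 1e-12)
  }
})

test_that("vessel metrics are exact on perfect predictions and hand cases", {
  truth <- matrix(c(TRUE, FALSE), 6, 6)
  fov <- matrix(TRUE, 6, 6)
  vm <- vessel_metrics(truth * 1, truth, fov)
  expect_equal(unlist(vm), c(acc = 1, se = 1, sp = 1, auc = 1, f1 = 1))
  vm2 <- vessel_metrics(matrix(0.5, 6, 6), truth, fov)
  expect_equal(vm2$auc, 0.5)
  expect_equal(vm2$se, 1)    # 0.5 >= threshold counts vessel
  expect_equal(vm2$sp, 0)
})

test_that("metrics ignore everything outside the FOV", {
  set.seed(14)
  truth <- matrix(sample(0:2, 900, TRUE, prob = c(.6, .2, .2)), 30, 30)
  fov <- matrix(FALSE, 30, 30); fov[8:24, 8:24] <- TRUE
  prob <- matrix(runif(900), 30, 30)
  pred <- matrix(sample(1:2, 900, TRUE), 30, 30)
  v1 <- vessel_metrics(prob, truth != 0, fov)
  a1 <- av_metrics(av_confusion(pred, truth, fov))
  # scramble predictions outside the FOV
  prob2 <- prob; prob2[!fov] <- runif(sum(!fov))
  pred2 <- pred; pred2[!fov] <- sample(0:2, sum(!fov), TRUE)
  expect_equal(vessel_metrics(prob2, truth != 0, fov), v1)
  expect_equal(av_metrics(av_confusion(pred2, truth, fov)), a1)
})

test_that("evaluation reports hold the BACC identity and handle duplicates", {
  m <- tiny_model()
  sc <- as_training_scene(tiny_scene())
  rep1 <- evaluate_model(m, list(sc), patch_size = 64L, stride = 64L)
  expect_equal(rep1$macro$bacc, (rep1$macro$se_av + rep1$macro$sp_av) / 2)
  expect_equal(rep1$pooled$bacc,
               balanced_accuracy(rep1$pooled$se_av, rep1$pooled$sp_av))
  # duplicating the only image changes no macro metric
  rep2 <- evaluate_model(m, list(sc, sc), patch_size = 64L, stride = 64L)
  expect_equal(rep2$macro, rep1$macro)
  expect_identical(rep2$n_images, 2L)
  # single image: macro equals the per-image row
  expect_equal(rep1$macro$auc, rep1$per_image$auc[1])
})

test_that("pooled and macro metrics differ on unbalanced two-image sets", {
  # image A: tiny but perfectly classified; image B: large and poor
  mk <- function(n_art, n_vein, correct) {
    truth <- matrix(0L, 20, 20)
    truth[seq_len(n_art)] <- 1L
    truth[200 + seq_len(n_vein)] <- 2L
    pred <- truth
    if (!correct) pred[truth == 1L] <- 2L   # all arteries wrong
    list(truth = truth, pred = pred)
  }
  a <- mk(4, 4, TRUE); b <- mk(150, 150, FALSE)
  fov <- matrix(TRUE, 20, 20)
  ca <- av_metrics(av_confusion(a$pred, a$truth, fov))
  cb <- av_metrics(av_confusion(b$pred, b$truth, fov))
  macro_se <- mean(c(ca$se_av, cb$se_av))
  pool <- av_metrics(list(TP = 4 + 0, TN = 4 + 150, FP = 0, FN = 0 + 150))
  expect_false(isTRUE(all.equal(macro_se, pool$se_av)))
})
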