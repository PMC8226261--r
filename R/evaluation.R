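#' Artery/vein confusion counts
#'
#' Arteries are positives, veins negatives. Only pixels inside the FOV whose
#' ground truth is artery or vein are scored; background and uncertain truth
#' pixels are never scored.
#'
#' @param pred Integer decision map from [classify_av()].
#' @param truth Integer ground-truth label map ([AV_CLASSES] codes).
#' @param fov Logical FOV mask.
#' @return List `TP` (artery as artery), `TN` (vein as vein), `FP` (vein as
#'   artery), `FN` (artery as vein), and `n_scored`.
#' @export
av_confusion <- function(pred, truth, fov) {
  stopifnot(all(dim(pred) == dim(truth)), all(dim(truth) == dim(fov)))
  dom <- fov & (truth == AV_CLASSES[["ARTERY"]] | truth == AV_CLASSES[["VEIN"]])
  if (!any(dom)) stop("no scorable artery/vein pixels")
  ta <- truth[dom] == AV_CLASSES[["ARTERY"]]
  pa <- pred[dom] == AV_CLASSES[["ARTERY"]]
  list(TP = sum(ta & pa), TN = sum(!ta & !pa),
       FP = sum(!ta & pa), FN = sum(ta & !pa), n_scored = sum(dom))
}

#' Artery/vein classification metrics
#'
#' `SE_AV = TP/(TP+FN)` (artery sensitivity), `SP_AV = TN/(TN+FP)` (vein
#' specificity), `BACC = (SE_AV + SP_AV)/2`,
#' `F1_A = 2TP/(2TP+FP+FN)`, `F1_V = 2TN/(2TN+FN+FP)`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param conf Counts from [av_confusion()].
#' @return Named list `se_av`, `sp_av`, `bacc`, `f1_a`, `f1_v`.
#' @export
av_metrics <- function(conf) {
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  se <- rat(conf$TP, conf$TP + conf$FN)
  sp <- rat(conf$TN, conf$TN + conf$FP)
  list(se_av = se, sp_av = sp, bacc = balanced_accuracy(se, sp),
       f1_a = rat(2 * conf$TP, 2 * conf$TP + conf$FP + conf$FN),
       f1_v = rat(2 * conf$TN, 2 * conf$TN + conf$FN + conf$FP))
}

#' Balanced accuracy from artery sensitivity and vein specificity
#' @param se_av,sp_av Sensitivity/specificity in `[0, 1]`.
#' @export
balanced_accuracy <- function(se_av, sp_av) (se_av + sp_av) / 2

#' Area under the ROC curve
#'
#' Threshold-sweep/trapezoid computation with proper tie handling: scores
#' are sorted, tied scores collapse onto one ROC vertex, and the area is
#' accumulated by the trapezoid rule — algebraically equal to the
#' Mann-Whitney pair statistic with ties counted 1/2.
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive.
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # final index of each tied run
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Vessel segmentation metrics
#'
#' Accuracy, sensitivity, specificity and F1 of the thresholded map plus
#' AUC of the continuous probabilities, all restricted to FOV pixels.
#'
#' @param prob `H x W` vessel probability map.
#' @param truth_vessel Logical ground-truth vessel map.
#' @param fov Logical FOV mask.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list `acc`, `se`, `sp`, `auc`, `f1`.
#' @export
vessel_metrics <- function(prob, truth_vessel, fov, threshold = 0.5) {
  stopifnot(all(dim(prob) == dim(fov)))
  p <- prob[fov]
  y <- as.logical(truth_vessel[fov])
  pred <- p >= threshold
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  list(acc = (tp + tn) / length(y), se = rat(tp, tp + fn),
       sp = rat(tn, tn + fp), auc = auc_trapezoid(p, y),
       f1 = rat(2 * tp, 2 * tp + fp + fn))
}

# Derive the binary vessel ground truth from a label map: artery, vein and
# uncertain (vessel of unknown type) all count as vessel.
vessel_truth_from_labels <- function(labels, strict = FALSE) {
  if (strict) labels == AV_CLASSES[["ARTERY"]] | labels == AV_CLASSES[["VEIN"]]
  else labels != AV_CLASSES[["BACKGROUND"]]
}

#' Evaluate a model on the test split of a dataset
#'
#' Predicts every test image, computes per-image vessel and artery/vein
#' metrics, and reports both their macro average (headline) and the metrics
#' of all FOV pixels pooled across images (the published per-dataset numbers
#' do not state which convention was used, so both are surfaced).
#'
#' @param model A `vc_model`.
#' @param man A manifest, or a list of preloaded scenes.
#' @param alpha Optional vessel-constraint override at test time.
#' @param patch_size,stride Tiling geometry for [predict_image()].
#' @param threshold Vessel decision threshold.
#' @param strict_uncertain If `TRUE`, uncertain truth pixels are excluded
#'   from the vessel ground truth instead of counting as vessel-positive.
#' @param split Manifest split to evaluate (default `"test"`).
#' @return A `metrics_report` list: `per_image` (data.frame), `macro`,
#'   `pooled`, and scored pixel counts.
#' @export
evaluate_model <- function(model, man, alpha = NULL, patch_size = 128L,
                           stride = patch_size %/% 2L, threshold = 0.5,
                           strict_uncertain = FALSE, split = "test") {
  scenes <- if (!is.null(man$entries)) load_split(man, split) else man
  stopifnot(length(scenes) >= 1L)
  rows <- list()
  pool_conf <- list(TP = 0, TN = 0, FP = 0, FN = 0, n_scored = 0)
  pool_v <- list(tp = 0, tn = 0, fp = 0, fn = 0, n = 0)
  pool_scores <- list(); pool_y <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    pr <- predict_image(model, sc$image, patch_size, stride, alpha)
    fov <- sc$valid
    vtruth <- vessel_truth_from_labels(sc$labels, strict_uncertain)
    vm <- vessel_metrics(pr$vessel, vtruth, fov, threshold)
    dom <- fov & (sc$labels == AV_CLASSES[["ARTERY"]] |
                  sc$labels == AV_CLASSES[["VEIN"]])
    dec <- classify_av(pr$av, dom)
    conf <- av_confusion(dec, sc$labels, fov)
    am <- av_metrics(conf)
    rows[[i]] <- data.frame(image = i, acc = vm$acc, se = vm$se, sp = vm$sp,
                            auc = vm$auc, f1 = vm$f1, se_av = am$se_av,
                            sp_av = am$sp_av, bacc = am$bacc,
                            f1_a = am$f1_a, f1_v = am$f1_v)
    for (f in c("TP", "TN", "FP", "FN", "n_scored"))
      pool_conf[[f]] <- pool_conf[[f]] + conf[[f]]
    p <- pr$vessel[fov]; y <- vtruth[fov]; pd <- p >= threshold
    pool_v$tp <- pool_v$tp + sum(pd & y); pool_v$tn <- pool_v$tn + sum(!pd & !y)
    pool_v$fp <- pool_v$fp + sum(pd & !y); pool_v$fn <- pool_v$fn + sum(!pd & y)
    pool_v$n <- pool_v$n + length(y)
    pool_scores[[i]] <- p; pool_y[[i]] <- y
  }
  per_image <- do.call(rbind, rows)
  macro <- as.list(colMeans(per_image[, -1, drop = FALSE], na.rm = TRUE))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  pooled <- c(list(acc = (pool_v$tp + pool_v$tn) / pool_v$n,
                   se = rat(pool_v$tp, pool_v$tp + pool_v$fn),
                   sp = rat(pool_v$tn, pool_v$tn + pool_v$fp),
                   auc = auc_trapezoid(unlist(pool_scores), unlist(pool_y)),
                   f1 = rat(2 * pool_v$tp,
                            2 * pool_v$tp + pool_v$fp + pool_v$fn)),
              av_metrics(pool_conf))
  structure(list(per_image = per_image, macro = macro, pooled = pooled,
                 n_images = length(scenes),
                 scored_av_pixels = pool_conf$n_scored,
                 scored_fov_pixels = pool_v$n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "  NA  ", sprintf("%.4f", v))
  cat(sprintf("Metrics over %d image(s); %d FOV pixels, %d scored A/V pixels\n",
              x$n_images, x$scored_fov_pixels, x$scored_av_pixels))
  cat("            ACC    SE     SP     AUC    F1   | SE_AV  SP_AV  BACC   F1_A   F1_V\n")
  for (nm in c("macro", "pooled")) {
    m <- x[[nm]]
    cat(sprintf("  %-8s %s %s %s %s %s | %s %s %s %s %s\n", nm,
                fmt(m$acc), fmt(m$se), fmt(m$sp), fmt(m$auc), fmt(m$f1),
                fmt(m$se_av), fmt(m$sp_av), fmt(m$bacc), fmt(m$f1_a),
                fmt(m$f1_v)))
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report A `metrics_report`.
#' @param path Output file.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
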