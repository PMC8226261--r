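#' Decompose an image into an ordered patch grid
#'
#' Reflection-pads the image so that `(H, W) - patch_size` is divisible by
#' `stride`, then emits square patches at row-major origins. Every pixel of
#' the padded image is covered by at least one patch.
#'
#' @param image `(H, W, 3)` array (or `H x W` matrix).
#' @param patch_size Patch edge in pixels.
#' @param stride Origin spacing; `stride = patch_size` gives the minimal
#'   non-overlapping ordered tiling, smaller strides overlap.
#' @return List with `origins` (0-based row/col matrix, row-major order),
#'   `patch_size`, `stride`, `padded_shape`, `orig_shape`, and `patches`
#'   (list of `(patch_size, patch_size, C)` arrays).
#' @export
tile_image <- function(image, patch_size, stride = patch_size) {
  if (stride <= 0) stop("stride must be positive")
  if (stride > patch_size) stop("stride must not exceed patch_size")
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  h <- dim(image)[1]; w <- dim(image)[2]
  span <- function(n) {
    if (n <= patch_size) return(patch_size)
    patch_size + ceiling((n - patch_size) / stride) * stride
  }
  hp <- as.integer(span(h)); wp <- as.integer(span(w))
  padded <- reflect_pad_hw(image, hp, wp)
  oi <- as.integer(seq(0L, hp - patch_size, by = stride))
  oj <- as.integer(seq(0L, wp - patch_size, by = stride))
  origins <- cbind(row = rep(oi, each = length(oj)),
                   col = rep(oj, times = length(oi)))
  patches <- lapply(seq_len(nrow(origins)), function(t) {
    padded[origins[t, 1] + seq_len(patch_size),
           origins[t, 2] + seq_len(patch_size), , drop = FALSE]
  })
  list(origins = origins, patch_size = patch_size, stride = stride,
       padded_shape = c(hp, wp), orig_shape = c(h, w), patches = patches)
}

#' Stitch per-patch predictions into whole-image maps
#'
#' Overlapping probabilities are averaged with uniform weights, the padding
#' is cropped away, and artery/vein maps are renormalized to sum to 1 per
#' pixel.
#'
#' @param grid A grid from [tile_image()].
#' @param preds List (one per origin, in origin order) of per-patch
#'   predictions: each a list with `vessel` (`P x P`) and `av` (`P x P x 3`).
#' @return List `vessel` (`H x W`) and `av` (`H x W x 3`) at the original
#'   image size.
#' @export
stitch <- function(grid, preds) {
  if (length(preds) != nrow(grid$origins))
    stop("one prediction per patch origin required")
  hp <- grid$padded_shape[1]; wp <- grid$padded_shape[2]
  ps <- grid$patch_size
  vsum <- matrix(0, hp, wp)
  asum <- array(0, c(hp, wp, 3))
  cnt <- matrix(0, hp, wp)
  for (t in seq_len(nrow(grid$origins))) {
    ri <- grid$origins[t, 1] + seq_len(ps)
    rj <- grid$origins[t, 2] + seq_len(ps)
    vsum[ri, rj] <- vsum[ri, rj] + preds[[t]]$vessel
    asum[ri, rj, ] <- asum[ri, rj, ] + preds[[t]]$av
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  vessel <- vsum / cnt
  av <- asum / array(cnt, dim(asum))
  h <- grid$orig_shape[1]; w <- grid$orig_shape[2]
  vessel <- vessel[seq_len(h), seq_len(w)]
  av <- av[seq_len(h), seq_len(w), , drop = FALSE]
  s <- av[, , 1] + av[, , 2] + av[, , 3]
  av <- av / array(s, dim(av))
  list(vessel = vessel, av = av)
}

#' Whole-image prediction
#'
#' Tiles the image into ordered patches, forwards each through the network
#' in inference mode, and stitches the patch predictions back together.
#' `alpha` overrides the training-time vessel-constraint strength (the
#' test-time alpha sweep on a trained model); leave `NULL` to reuse the
#' configured value.
#'
#' @param model A `vc_model`.
#' @param image `(H, W, 3)` array in `[0, 1]`, or a `fundus_image`.
#' @param patch_size,stride Tiling geometry; defaults to patch 128 with
#'   half-patch overlap. Both image padding and the patch size must respect
#'   the model's `2^(depth-1)` divisibility.
#' @param alpha Optional vessel-constraint override.
#' @param batch_size Patches forwarded per call.
#' @return List `vessel` (`H x W` probabilities) and `av` (`H x W x 3`
#'   probabilities summing to 1 per pixel).
#' @export
predict_image <- function(model, image, patch_size = 128L,
                          stride = patch_size %/% 2L, alpha = NULL,
                          batch_size = 8L) {
  if (inherits(image, "fundus_image")) image <- image$pixels
  grid <- tile_image(image, patch_size, stride)
  np <- length(grid$patches)
  preds <- vector("list", np)
  for (s in seq(1L, np, by = batch_size)) {
    idx <- s:min(np, s + batch_size - 1L)
    xb <- array(0, c(patch_size, patch_size, 3, length(idx)))
    for (q in seq_along(idx)) xb[, , , q] <- grid$patches[[idx[q]]]
    out <- model_forward(model, xb, train = FALSE, alpha = alpha)
    vv <- out$vessel; if (length(dim(vv)) == 2L) dim(vv) <- c(dim(vv), 1L)
    av <- out$av; if (length(dim(av)) == 3L) dim(av) <- c(dim(av), 1L)
    for (q in seq_along(idx))
      preds[[idx[q]]] <- list(vessel = vv[, , q], av = av[, , , q])
  }
  stitch(grid, preds)
}

#' Threshold a vessel probability map
#'
#' A pixel is vessel iff its probability is `>= threshold` (ties at the
#' threshold count as vessel).
#' @param vessel_prob Numeric map in `[0, 1]`.
#' @param threshold Decision threshold in (0, 1); 0.5 is the published
#'   operating point.
#' @return Logical map.
#' @export
binarize_vessels <- function(vessel_prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  stopifnot_prob(vessel_prob, "vessel probability")
  vessel_prob >= threshold
}

#' Artery/vein decision map
#'
#' For every pixel of `domain`, picks artery or vein by comparing the two
#' class probabilities only (the background probability is ignored, so every
#' domain pixel receives a decision). Ties go to artery. The intended
#' `domain` is the set of ground-truth vessel pixels — classification is
#' scored on all annotated artery/vein pixels, not only on pixels the
#' segmentation head recovered — but any subset of the FOV may be supplied
#' (e.g. the predicted vessel mask, for comparability with protocols that
#' score on segmented vessels).
#'
#' @param av `(H, W, 3)` probability array (background, artery, vein).
#' @param domain Logical `H x W` map of pixels to decide.
#' @return Integer `H x W` matrix: `AV_CLASSES["ARTERY"]` or
#'   `AV_CLASSES["VEIN"]` inside `domain`, `AV_CLASSES["BACKGROUND"]`
#'   elsewhere.
#' @export
classify_av <- function(av, domain) {
  if (!any(domain)) stop("empty decision domain")
  out <- matrix(AV_CLASSES[["BACKGROUND"]], dim(av)[1], dim(av)[2])
  art <- av[, , 2][domain] >= av[, , 3][domain]
  out[domain] <- ifelse(art, AV_CLASSES[["ARTERY"]], AV_CLASSES[["VEIN"]])
  out
}
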