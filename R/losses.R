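#' Loss weights of the joint objective
#'
#' The total training objective is
#' `gamma * L_av + delta * L_vessel + beta * ||W||^2`, with the published
#' defaults gamma = 0.6, delta = 0.4 (gamma + delta = 1) and L2 coefficient
#' beta = 0.0002 applied to convolution kernels only (not biases or
#' normalization parameters).
#'
#' @param gamma Weight of the artery/vein cross-entropy.
#' @param delta Weight of the vessel binary cross-entropy.
#' @param beta L2 regularization coefficient.
#' @export
loss_weights <- function(gamma = 0.6, delta = 0.4, beta = 2e-4) {
  stopifnot(gamma >= 0, delta >= 0, beta >= 0)
  if (abs(gamma + delta - 1) > 1e-9)
    stop("gamma + delta must equal 1")
  list(gamma = gamma, delta = delta, beta = beta)
}

.loss_eps <- 1e-7

#' Artery/vein cross-entropy loss
#'
#' Mean over valid pixels of the negative log-probability assigned to the
#' true class among background/artery/vein. Valid pixels are those inside
#' the FOV whose ground truth is not UNCERTAIN; uncertain pixels (vessels of
#' ambiguous type, e.g. crossings) carry no artery/vein supervision.
#'
#' @param av_probs Array `(H, W, 3[, N])` of class probabilities
#'   (background, artery, vein), summing to 1 per pixel.
#' @param labels Integer matrix/array `(H, W[, N])` with [AV_CLASSES] codes.
#' @param valid Logical map, same spatial shape as `labels`.
#' @return Nonnegative scalar.
#' @export
av_cross_entropy <- function(av_probs, labels, valid) {
  d <- dim(av_probs)
  if (length(d) == 3L) dim(av_probs) <- c(d, 1L)
  n4 <- dim(av_probs)[4]
  labels <- array(labels, c(dim(av_probs)[1:2], n4))
  valid <- array(valid, dim(labels)) & labels != AV_CLASSES[["UNCERTAIN"]]
  if (!any(valid)) stop("no valid pixels for the artery/vein loss")
  # class code 0/1/2 -> channel 1/2/3
  ch <- labels + 1L
  hw <- prod(dim(av_probs)[1:2])
  idx <- which(valid)
  n_id <- (idx - 1L) %/% hw
  pix <- (idx - 1L) %% hw
  lin <- pix + hw * (ch[idx] - 1L) + 3L * hw * n_id + 1L
  p <- clamp(av_probs[lin], .loss_eps, 1 - .loss_eps)
  -mean(log(p))
}

#' Vessel binary cross-entropy loss
#'
#' Mean over valid (FOV) pixels of the binary cross-entropy between the
#' predicted vessel probability and the binary vessel ground truth.
#' Uncertain-class pixels are vessels of unknown type and therefore count as
#' vessel-positive for this head.
#'
#' @param vessel_prob Numeric map of vessel probabilities in `[0, 1]`.
#' @param vessel_truth Logical map of the same shape.
#' @param valid Logical map of the same shape (typically the FOV).
#' @return Nonnegative scalar.
#' @export
vessel_bce <- function(vessel_prob, vessel_truth, valid) {
  if (!any(valid)) stop("no valid pixels for the vessel loss")
  p <- clamp(vessel_prob[valid], .loss_eps, 1 - .loss_eps)
  y <- as.numeric(vessel_truth[valid])
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Total joint loss
#'
#' `gamma * av_loss + delta * vessel_loss + beta * parameter_sq_norm`.
#'
#' @param av_loss,vessel_loss Scalars from [av_cross_entropy()] and
#'   [vessel_bce()].
#' @param weights A [loss_weights()] list.
#' @param parameter_sq_norm Sum of squared convolution-kernel entries.
#' @export
total_loss <- function(av_loss, vessel_loss, weights = loss_weights(),
                       parameter_sq_norm = 0) {
  vals <- c(av_loss, vessel_loss, parameter_sq_norm)
  if (any(!is.finite(vals))) stop("non-finite loss input")
  weights$gamma * av_loss + weights$delta * vessel_loss +
    weights$beta * parameter_sq_norm
}

# Squared norm of the regularized (convolution-kernel) parameters.
conv_sq_norm <- function(model) {
  sum(vapply(model$conv_weights, function(p) sum(p$v^2), numeric(1)))
}
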