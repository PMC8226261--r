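#' Vessel-constraint Gaussian activation
#'
#' Maps a vessel probability map to a multiplicative weight map,
#' `F(x) = alpha * (exp(-|x - 0.5|) - exp(-0.5)) + 1`.
#' The weight peaks at `x = 0.5` — vessel-boundary and capillary pixels whose
#' segmentation evidence is ambiguous — and decays to exactly 1 at `x = 0`
#' and `x = 1` (confident background and confident thick vessel). Applied to
#' the artery/vein feature maps, it concentrates the classifier's capacity on
#' the pixels where artery/vein errors actually occur and counteracts the
#' extreme background/vessel class imbalance of fundus images.
#'
#' The output always lies in `[1, alpha * (1 - exp(-0.5)) + 1]`.
#'
#' @param x Numeric vector/matrix/array of vessel probabilities in `[0, 1]`.
#' @param alpha Positive scalar controlling the strength of the constraint
#'   (default 1).
#' @return Weight map of the same shape as `x`.
#' @examples
#' vc_weight(c(0, 0.5, 1))        # 1, 1.393..., 1
#' vc_weight_bounds(1)
#' @export
vc_weight <- function(x, alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  stopifnot_prob(x, "vessel probability")
  alpha * (exp(-abs(x - 0.5)) - exp(-0.5)) + 1
}

#' @rdname vc_weight
#' @return `vc_weight_bounds` returns `c(lower = 1, upper = alpha*(1-e^-0.5)+1)`.
#' @export
vc_weight_bounds <- function(alpha = 1) {
  c(lower = 1, upper = alpha * (1 - exp(-0.5)) + 1)
}
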