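# Joint affine resampling used by the training augmentation: image channels
# are sampled bilinearly, label/validity maps nearest-neighbour, and pixels
# whose source falls outside the input canvas are marked invalid. Rotation is
# counter-clockwise about the patch centre in the row-major (i = row down,
# j = column right) pixel grid; scale > 1 zooms in.

affine_grid <- function(in_h, in_w, out_h, out_w, angle_deg, scale) {
  th <- angle_deg * pi / 180
  # inverse map: for each output pixel, the source location
  ci <- (in_h - 1) / 2; cj <- (in_w - 1) / 2
  co_i <- (out_h - 1) / 2; co_j <- (out_w - 1) / 2
  di <- (seq_len(out_h) - 1) - co_i
  dj <- (seq_len(out_w) - 1) - co_j
  # CCW rotation of the image content = rotate output coords by -theta.
  # Row index grows downward, so the visual CCW matrix has the sign of the
  # off-diagonal terms flipped relative to the usual (x up) convention.
  src_i <- outer(di, dj, function(a, b) (cos(th) * a - sin(th) * b) / scale) + ci
  src_j <- outer(di, dj, function(a, b) (sin(th) * a + cos(th) * b) / scale) + cj
  list(i = src_i, j = src_j)
}

bilinear_sample <- function(img, src_i, src_j, fill = 0) {
  h <- dim(img)[1]; w <- dim(img)[2]; C <- dim(img)[3]
  i0 <- floor(src_i); j0 <- floor(src_j)
  ti <- src_i - i0; tj <- src_j - j0
  inside <- src_i >= 0 & src_i <= h - 1 & src_j >= 0 & src_j <= w - 1
  gi0 <- clamp(i0, 0, h - 1); gi1 <- clamp(i0 + 1, 0, h - 1)
  gj0 <- clamp(j0, 0, w - 1); gj1 <- clamp(j0 + 1, 0, w - 1)
  out <- array(fill, c(dim(src_i), C))
  for (c in seq_len(C)) {
    pl <- img[, , c]
    v <- pl[gi0 + h * gj0 + 1] * (1 - ti) * (1 - tj) +
         pl[gi1 + h * gj0 + 1] * ti * (1 - tj) +
         pl[gi0 + h * gj1 + 1] * (1 - ti) * tj +
         pl[gi1 + h * gj1 + 1] * ti * tj
    v[!inside] <- fill
    out[, , c] <- v
  }
  out
}

nearest_sample <- function(m, src_i, src_j, fill = 0L) {
  h <- dim(m)[1]; w <- dim(m)[2]
  ri <- round(src_i); rj <- round(src_j)
  inside <- ri >= 0 & ri <= h - 1 & rj >= 0 & rj <= w - 1
  out <- array(fill, dim(src_i))
  out[inside] <- m[ri[inside] + h * rj[inside] + 1]
  list(values = out, inside = inside)
}
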