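# Reading/writing fundus images, artery/vein label maps, FOV masks and
# dataset manifests. File decoding is delegated to EBImage (PNG/TIFF/JPEG);
# arrays in this package are row-major (H, W[, C]) with intensities in [0,1],
# so EBImage's (x, y) layout is transposed on the way in and out.

ebi_to_hwc <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- t(a)
    array(a, c(dim(a), 1L))
  } else aperm(a, c(2L, 1L, 3L))
}

hwc_to_ebi <- function(a) {
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (dim(a)[3] == 1L)
    EBImage::Image(t(a[, , 1L]), colormode = "Grayscale")
  else
    EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
}

#' Load a fundus photograph
#'
#' Decodes an 8- or 16-bit PNG/TIFF/JPEG raster to an `(H, W, 3)` array with
#' intensities rescaled to `[0, 1]`. Grayscale inputs are replicated to
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path Image file path.
#' @return A `fundus_image` list: `pixels` (`H x W x 3`), `height`, `width`,
#'   `source_id` (the file name).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop(sprintf("cannot decode '%s' as an image: %s",
                                 path, conditionMessage(e))))
  px <- ebi_to_hwc(img)
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px <- clamp(px, 0, 1)   # 16-bit TIFFs already arrive scaled by EBImage
  structure(list(pixels = px, height = dim(px)[1], width = dim(px)[2],
                 source_id = basename(path)),
            class = "fundus_image")
}

# Load a raster as integer 0..255 RGB (for palette decoding).
load_raster <- function(path) {
  px <- load_image(path)$pixels
  r <- round(px * 255)
  storage.mode(r) <- "integer"
  r
}

#' Default artery/vein colour palette
#'
#' The RITE/LES colour convention: red = artery, blue = vein, green =
#' uncertain (crossings/unknown type), white = vessel of unknown type
#' (mapped to uncertain), black = background.
#'
#' @return A data.frame with columns `r`, `g`, `b` (0-255) and `class`.
#' @export
default_palette <- function() {
  data.frame(r = c(0L, 255L, 0L, 0L, 255L),
             g = c(0L, 0L, 0L, 255L, 255L),
             b = c(0L, 0L, 255L, 0L, 255L),
             class = AV_CLASSES[c("BACKGROUND", "ARTERY", "VEIN",
                                  "UNCERTAIN", "UNCERTAIN")],
             row.names = NULL)
}

#' Decode a colour-coded label raster to a class map
#'
#' Every pixel colour must match a palette entry exactly; unknown colours
#' raise an error listing the offending colour(s) and their counts.
#'
#' @param raster Integer `(H, W, 3)` array with values 0-255 (e.g. from a
#'   palette PNG), or a `fundus_image` (intensities are rescaled to 0-255).
#' @param palette A palette data.frame as from [default_palette()].
#' @return An `av_label_map` list: `classes` (`H x W` integer matrix of
#'   [AV_CLASSES] codes) and `counts` (pixels per class).
#' @export
decode_label_map <- function(raster, palette = default_palette()) {
  if (inherits(raster, "fundus_image")) {
    raster <- round(raster$pixels * 255)
    storage.mode(raster) <- "integer"
  }
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3] >= 3L)
  if (anyDuplicated(palette[, c("r", "g", "b")]))
    stop("palette contains duplicate colours")
  key <- raster[, , 1] * 65536L + raster[, , 2] * 256L + raster[, , 3]
  pkey <- palette$r * 65536L + palette$g * 256L + palette$b
  m <- match(key, pkey)
  if (anyNA(m)) {
    bad <- table(key[is.na(m)])
    cols <- as.integer(names(bad))
    stop(sprintf(
      "label raster contains colours absent from the palette: %s",
      paste(sprintf("rgb(%d,%d,%d) x%d", cols %/% 65536, (cols %/% 256) %% 256,
                    cols %% 256, as.integer(bad)), collapse = ", ")))
  }
  classes <- matrix(as.integer(palette$class[m]), dim(raster)[1], dim(raster)[2])
  counts <- vapply(AV_CLASSES, function(cl) sum(classes == cl), integer(1))
  structure(list(classes = classes, counts = counts), class = "av_label_map")
}

#' Encode a class map back to a colour raster
#'
#' Inverse of [decode_label_map()] under a palette without duplicate
#' classes; classes mapped by several colours use the first entry.
#'
#' @param labels `H x W` integer matrix of [AV_CLASSES] codes, or an
#'   `av_label_map`.
#' @param palette Palette data.frame.
#' @return Integer `(H, W, 3)` raster with values 0-255.
#' @export
encode_label_map <- function(labels, palette = default_palette()) {
  if (inherits(labels, "av_label_map")) labels <- labels$classes
  first <- palette[!duplicated(palette$class), , drop = FALSE]
  m <- match(as.integer(labels), first$class)
  if (anyNA(m)) stop("label map contains classes absent from the palette")
  out <- array(0L, c(dim(labels), 3L))
  out[, , 1] <- first$r[m]
  out[, , 2] <- first$g[m]
  out[, , 3] <- first$b[m]
  out
}

#' Construct a field-of-view mask from image luminance
#'
#' Thresholds the mean-RGB luminance, keeps the largest connected component
#' with area at least `min_area`, and fills its holes. Fundus photographs
#' have a bright circular field of view on a dark border, so this recovers
#' the FOV when no hand-made mask ships with a dataset.
#'
#' @param image A `fundus_image` or `(H, W, 3)` array in `[0, 1]`.
#' @param luminance_threshold Fraction in (0, 1); default 0.06.
#' @param min_area Minimum component area in pixels; default 1% of the
#'   image.
#' @return An `fov_mask` list with `inside` (`H x W` logical matrix).
#' @export
compute_fov_mask <- function(image, luminance_threshold = 0.06,
                             min_area = NULL) {
  if (inherits(image, "fundus_image")) image <- image$pixels
  stopifnot(luminance_threshold > 0, luminance_threshold < 1)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(min_area)) min_area <- ceiling(0.01 * h * w)
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  bw <- lum > luminance_threshold
  cc <- EBImage::bwlabel(EBImage::Image(t(bw)))
  areas <- tabulate(as.integer(EBImage::imageData(cc)))
  keep <- which(areas >= min_area)
  if (length(keep) == 0L)
    stop("degenerate image: no connected component above min_area")
  best <- keep[which.max(areas[keep])]
  comp <- EBImage::imageData(cc) == best
  comp <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp)))
  structure(list(inside = t(comp == 1)), class = "fov_mask")
}

#' Read / write a binary mask PNG
#' @param path PNG path.
#' @export
load_mask <- function(path) {
  px <- load_image(path)$pixels
  structure(list(inside = px[, , 1] > 0.5), class = "fov_mask")
}

#' @rdname load_mask
#' @param mask An `fov_mask` or logical matrix.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "fov_mask")) mask <- mask$inside
  EBImage::writeImage(hwc_to_ebi(mask * 1), path)
  invisible(path)
}

#' Write an image or label raster to disk
#' @param x `(H, W, 3)` array in `[0, 1]`, integer 0-255 raster, or a
#'   `fundus_image`.
#' @param path Output path (format from the extension).
#' @export
write_image <- function(x, path) {
  if (inherits(x, "fundus_image")) x <- x$pixels
  if (is.integer(x)) x <- x / 255
  EBImage::writeImage(hwc_to_ebi(clamp(x, 0, 1)), path)
  invisible(path)
}

# ---- manifests ------------------------------------------------------------

#' Create a dataset manifest
#'
#' A manifest lists (image, label, mask, split) path tuples for one dataset.
#' @param name Dataset name.
#' @param entries List of entries, each a list with `image`, `label`,
#'   optional `mask`, and `split` (`"train"` or `"test"`).
#' @export
manifest <- function(name, entries) {
  for (e in entries)
    stopifnot(!is.null(e$image), !is.null(e$label),
              e$split %in% c("train", "test"))
  structure(list(name = name, entries = entries), class = "dataset_manifest")
}

#' Read / write a dataset manifest (JSON or YAML)
#'
#' Relative paths inside the file are resolved against its directory.
#' @param path Manifest file (`.json`, `.yaml`, or `.yml`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p) || is.na(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  entries <- lapply(raw$entries, function(e)
    list(image = fix(e$image), label = fix(e$label), mask = fix(e$mask),
         split = e$split, source = e$source))
  for (e in entries) {
    for (f in c("image", "label"))
      if (!file.exists(e[[f]]))
        stop(sprintf("manifest references missing %s file: %s", f, e[[f]]))
    if (!is.null(e$mask) && !file.exists(e$mask))
      stop(sprintf("manifest references missing mask file: %s", e$mask))
  }
  manifest(name = raw$name %||% "dataset", entries = entries)
}

#' @rdname read_manifest
#' @param man A manifest.
#' @param relative_to Optional directory; stored paths are made relative to
#'   it.
#' @export
write_manifest <- function(man, path, relative_to = NULL) {
  entries <- lapply(man$entries, function(e) {
    if (!is.null(relative_to)) {
      rel <- function(p) if (is.null(p)) NULL
        else sub(paste0("^", normalizePath(relative_to), "/?"), "",
                 normalizePath(p, mustWork = FALSE))
      e$image <- rel(e$image); e$label <- rel(e$label); e$mask <- rel(e$mask)
    }
    e[!vapply(e, is.null, logical(1))]
  })
  jsonlite::write_json(list(name = man$name, entries = entries), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
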