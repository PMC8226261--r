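#' Synthetic fundus scene specification
#'
#' Parameters of the scene generator. Defaults are chosen so that vessels
#' occupy roughly 15% of the circular field of view with arteries and veins
#' contributing about half each, mirroring the class balance of real fundus
#' photographs; artery root calibers are slightly smaller than vein root
#' calibers, and calibers decay along the branching hierarchy from trunks
#' down to capillary-scale vessels.
#'
#' @param image_size Square image edge in pixels (>= 128; default 256).
#' @param n_trees_artery,n_trees_vein Vessel trees per class.
#' @param root_caliber_artery,root_caliber_vein Root vessel diameters in
#'   pixels; artery < vein by default.
#' @param branch_depth Binary branching levels (0 = a single unbranched
#'   vessel).
#' @param caliber_decay Per-level caliber multiplier in (0, 1); the caliber
#'   at level `d` is `root * caliber_decay^d`, floored at 1 pixel.
#' @param tortuosity Maximum per-step heading change in radians.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity
#'   fraction).
#' @param background_drift Amplitude of the smooth background intensity
#'   drift.
#' @param seed Integer master seed; all randomness flows from it through
#'   named substreams.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_size = 256L, n_trees_artery = 2L,
                       n_trees_vein = 2L, root_caliber_artery = 6,
                       root_caliber_vein = 8, branch_depth = 3L,
                       caliber_decay = 0.72, tortuosity = 0.15,
                       noise_sd = 0.02, background_drift = 0.06, seed = 1L) {
  stopifnot(image_size >= 128, caliber_decay > 0, caliber_decay < 1,
            branch_depth >= 0, n_trees_artery >= 1, n_trees_vein >= 1,
            root_caliber_artery > 0, root_caliber_vein > 0,
            tortuosity >= 0, noise_sd >= 0, background_drift >= 0)
  if (root_caliber_artery >= root_caliber_vein)
    warning("artery root caliber is usually smaller than the vein's")
  structure(list(image_size = as.integer(image_size),
                 n_trees_artery = as.integer(n_trees_artery),
                 n_trees_vein = as.integer(n_trees_vein),
                 root_caliber_artery = root_caliber_artery,
                 root_caliber_vein = root_caliber_vein,
                 branch_depth = as.integer(branch_depth),
                 caliber_decay = caliber_decay, tortuosity = tortuosity,
                 noise_sd = noise_sd, background_drift = background_drift,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

fov_geometry <- function(image_size) {
  list(center = (image_size - 1) / 2, radius = 0.47 * image_size)
}

#' Grow one branching vessel tree
#'
#' Recursive binary branching from a root on the FOV boundary toward the
#' centre. Each branch is a polyline stepped 1 pixel at a time with the
#' heading perturbed by at most `tortuosity` radians per step; at each level
#' the two children inherit the parent's endpoint (so every tree is
#' connected) and the caliber decays by `caliber_decay`, floored at 1 px.
#' Branches stop at the FOV boundary.
#'
#' @param spec A [scene_spec()].
#' @param cls `"artery"` or `"vein"` (selects the root caliber).
#' @param stream Substream name seeding this tree's randomness (combined
#'   with `spec$seed`); the same spec and stream always grow the same tree.
#' @return A data.frame of centreline samples: `i`, `j` (0-based pixel
#'   coordinates), `caliber` (diameter, px), `level`, `branch`.
#' @export
grow_vessel_tree <- function(spec, cls = c("artery", "vein"),
                             stream = "tree-1") {
  cls <- match.arg(cls)
  root_cal <- if (cls == "artery") spec$root_caliber_artery
              else spec$root_caliber_vein
  geo <- fov_geometry(spec$image_size)
  with_seed(sub_seed(spec$seed, paste0(cls, "-", stream)), {
    theta <- runif(1, 0, 2 * pi)
    start <- c(geo$center + 0.92 * geo$radius * sin(theta),
               geo$center + 0.92 * geo$radius * cos(theta))
    heading <- theta + pi + runif(1, -0.4, 0.4)  # roughly toward the centre
    seg_len <- 0.18 * spec$image_size
    branch_id <- 0L
    rows <- list()
    grow <- function(pos, heading, level) {
      branch_id <<- branch_id + 1L
      my_id <- branch_id
      cal <- max(1, root_cal * spec$caliber_decay^level)
      len <- seg_len * 0.85^level
      pts <- matrix(NA_real_, ceiling(len), 2)
      np <- 0L
      for (s in seq_len(ceiling(len))) {
        heading <- heading + runif(1, -spec$tortuosity, spec$tortuosity)
        pos <- pos + c(sin(heading), cos(heading))
        r <- sqrt(sum((pos - geo$center)^2))
        if (r > geo$radius - cal / 2 - 1) break
        np <- np + 1L
        pts[np, ] <- pos
      }
      if (np > 0L)
        rows[[length(rows) + 1L]] <<- data.frame(
          i = pts[seq_len(np), 1], j = pts[seq_len(np), 2],
          caliber = cal, level = level, branch = my_id)
      if (level < spec$branch_depth && np > 0L) {
        spread <- 0.45 + runif(1, -0.1, 0.1)
        grow(pos, heading + spread, level + 1L)
        grow(pos, heading - spread, level + 1L)
      }
    }
    grow(start, heading, 0L)
    do.call(rbind, rows)
  })
}

# Stamp centreline points into minimum-distance fields. Returns `tube`
# (signed distance to the tube surface: dist - caliber/2) and `axis`
# (distance to the centreline scaled by caliber, for the central reflex).
stamp_tree <- function(h, w, pts) {
  tube <- matrix(Inf, h, w)
  axis <- matrix(Inf, h, w)
  for (t in seq_len(nrow(pts))) {
    pi_ <- pts$i[t]; pj <- pts$j[t]; r <- pts$caliber[t] / 2
    win <- ceiling(r + 1.5)
    i0 <- max(1, floor(pi_) - win + 1); i1 <- min(h, floor(pi_) + win + 1)
    j0 <- max(1, floor(pj) - win + 1); j1 <- min(w, floor(pj) + win + 1)
    if (i0 > i1 || j0 > j1) next
    di2 <- ((i0:i1) - 1 - pi_)^2
    dj2 <- ((j0:j1) - 1 - pj)^2
    d <- sqrt(outer(di2, dj2, `+`))
    sub <- tube[i0:i1, j0:j1]
    tube[i0:i1, j0:j1] <- pmin(sub, d - r)
    suba <- axis[i0:i1, j0:j1]
    axis[i0:i1, j0:j1] <- pmin(suba, d / max(r, 0.5))
  }
  list(tube = tube, axis = axis)
}

# Smooth random field in [-1, 1] from a coarse grid, bilinearly upsampled.
smooth_field <- function(h, w, n_knots = 5L) {
  g <- matrix(runif(n_knots^2, -1, 1), n_knots, n_knots)
  gi <- seq(0, 1, length.out = n_knots)
  ti <- seq(0, 1, length.out = h); tj <- seq(0, 1, length.out = w)
  fi <- findInterval(ti, gi, rightmost.closed = TRUE)
  fj <- findInterval(tj, gi, rightmost.closed = TRUE)
  wi <- (ti - gi[fi]) / diff(gi)[1]; wj <- (tj - gi[fj]) / diff(gi)[1]
  wi <- clamp(wi, 0, 1); wj <- clamp(wj, 0, 1)
  fi1 <- pmin(fi + 1L, n_knots); fj1 <- pmin(fj + 1L, n_knots)
  a <- g[fi, fj] * outer(1 - wi, 1 - wj) + g[fi1, fj] * outer(wi, 1 - wj) +
       g[fi, fj1] * outer(1 - wi, wj) + g[fi1, fj1] * outer(wi, wj)
  a
}

#' Render a synthetic fundus scene
#'
#' Rasterizes the vessel trees as anti-aliased tubes over a textured
#' background inside a circular field of view. Arteries are drawn brighter
#' red and thinner with a central reflex (the bright midline stripe real
#' arteries show); veins are darker and wider. Pixels where an artery and a
#' vein tube overlap are labelled uncertain, imitating the crossing
#' convention of real artery/vein ground truth.
#'
#' @param spec A [scene_spec()].
#' @return A `synthetic_scene` list: `image` (`fundus_image`), `labels`
#'   (`av_label_map`), `mask` (`fov_mask`), `spec`.
#' @export
render_scene <- function(spec) {
  n <- spec$image_size
  geo <- fov_geometry(n)
  dist_c <- sqrt(outer(((0:(n - 1)) - geo$center)^2,
                       ((0:(n - 1)) - geo$center)^2, `+`))
  fov <- dist_c <= geo$radius

  trees_a <- lapply(seq_len(spec$n_trees_artery), function(t)
    grow_vessel_tree(spec, "artery", paste0("tree-", t)))
  trees_v <- lapply(seq_len(spec$n_trees_vein), function(t)
    grow_vessel_tree(spec, "vein", paste0("tree-", t)))
  sa <- stamp_tree(n, n, do.call(rbind, trees_a))
  sv <- stamp_tree(n, n, do.call(rbind, trees_v))

  cov_a <- clamp(0.5 - sa$tube, 0, 1) * fov
  cov_v <- clamp(0.5 - sv$tube, 0, 1) * fov

  with_seed(sub_seed(spec$seed, "texture"), {
    drift <- smooth_field(n, n) * spec$background_drift
    vign <- 1 - 0.25 * (dist_c / geo$radius)^2
    base <- c(0.82, 0.46, 0.22)
    art_col <- c(0.80, 0.26, 0.20)
    reflex_col <- c(0.97, 0.42, 0.34)
    vein_col <- c(0.46, 0.12, 0.12)
    reflex <- (sa$axis < 0.35) * cov_a   # bright midline stripe of arteries
    img <- array(0, c(n, n, 3))
    for (c in 1:3) {
      pl <- (base[c] + drift) * vign
      pl <- pl * (1 - cov_v) + vein_col[c] * cov_v
      pl <- pl * (1 - cov_a) + art_col[c] * cov_a
      pl <- pl * (1 - reflex) + reflex_col[c] * reflex
      if (spec$noise_sd > 0) pl <- pl + rnorm(n * n, sd = spec$noise_sd)
      img[, , c] <- clamp(pl, 0, 1) * fov
    }
  })

  lab <- matrix(AV_CLASSES[["BACKGROUND"]], n, n)
  in_a <- sa$tube < 0 & fov
  in_v <- sv$tube < 0 & fov
  lab[in_v] <- AV_CLASSES[["VEIN"]]
  lab[in_a] <- AV_CLASSES[["ARTERY"]]
  lab[in_a & in_v] <- AV_CLASSES[["UNCERTAIN"]]
  counts <- vapply(AV_CLASSES, function(cl) sum(lab == cl), integer(1))

  structure(list(
    image = structure(list(pixels = img, height = n, width = n,
                           source_id = sprintf("synthetic-%d", spec$seed)),
                      class = "fundus_image"),
    labels = structure(list(classes = lab, counts = counts),
                       class = "av_label_map"),
    mask = structure(list(inside = fov), class = "fov_mask"),
    spec = spec), class = "synthetic_scene")
}

#' Convert a synthetic scene to a training triple
#' @param scene A `synthetic_scene`.
#' @return List `image`, `labels`, `valid` as consumed by [train_model()]
#'   and [evaluate_model()].
#' @export
as_training_scene <- function(scene) {
  list(image = scene$image$pixels, labels = scene$labels$classes,
       valid = scene$mask$inside)
}

#' Generate a synthetic dataset on disk
#'
#' Renders `n_train + n_test` scenes with disjoint per-scene substreams,
#' writes images, colour-coded label maps and FOV masks as PNGs, and a JSON
#' manifest. Re-running with the same spec reproduces identical files.
#'
#' @param spec A [scene_spec()]; per-scene seeds derive from `spec$seed`.
#' @param n_train,n_test Scene counts per split (>= 1).
#' @param out_dir Output directory (created if needed).
#' @return The dataset manifest (also written to `manifest.json`).
#' @export
generate_dataset <- function(spec, n_train, n_test, out_dir) {
  stopifnot(n_train >= 1, n_test >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir))
  entries <- list()
  k <- 0L
  for (split in c("train", "test")) {
    nn <- if (split == "train") n_train else n_test
    for (i in seq_len(nn)) {
      k <- k + 1L
      sspec <- spec
      sspec$seed <- sub_seed(spec$seed, paste0("scene-", split, "-", i))
      sc <- render_scene(sspec)
      stem <- sprintf("%s_%03d", split, i)
      ip <- file.path(out_dir, paste0(stem, "_image.png"))
      lp <- file.path(out_dir, paste0(stem, "_label.png"))
      mp <- file.path(out_dir, paste0(stem, "_mask.png"))
      write_image(sc$image, ip)
      write_image(encode_label_map(sc$labels), lp)
      write_mask(sc$mask, mp)
      entries[[k]] <- list(image = ip, label = lp, mask = mp, split = split)
    }
  }
  man <- manifest(name = sprintf("synthetic-%d", spec$seed), entries = entries)
  write_manifest(man, file.path(out_dir, "manifest.json"))
  man
}
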