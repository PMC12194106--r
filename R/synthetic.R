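# Synthetic field-scene generator. Emulates the properties that make field
# rice-pest segmentation hard: multi-scale pests (tiny to large), elongated
# bodies with thin leg/antenna appendages, low-contrast pests close to the
# background luminance, cluttered vegetation texture, occlusion by foliage,
# and class imbalance. Masks are exact: a pixel is foreground iff a visible
# pest body/appendage pixel was drawn there.

#' Scene generation parameters
#'
#' @param canvas_size Canvas side length in pixels.
#' @param n_pests Range (min, max) of pests per scene.
#' @param pest_scale_range Body length range as a fraction of the canvas.
#' @param body_aspect_range Body length/width ratio range.
#' @param n_appendages Range of thin appendages (legs/antennae) per pest.
#' @param contrast_level `"normal"` or `"low"` (pest luminance within
#'   +/-10% of the local background).
#' @param background_style `"leaf_stripes"`, `"soil_texture"` or
#'   `"clutter"`.
#' @param occlusion_prob Probability that a pest is partly occluded by a
#'   drawn grass blade.
#' @param class_id Optional shape family (1 capsule, 2 segmented, 3
#'   winged); drawn at random when NULL.
#' @param seed Optional default seed used by [generate_pest_scene()].
#' @return A `catu_scene_params` list.
#' @export
scene_params <- function(canvas_size = 640L, n_pests = c(1L, 6L),
                         pest_scale_range = c(0.02, 0.25),
                         body_aspect_range = c(1.8, 4),
                         n_appendages = c(4L, 8L),
                         contrast_level = c("normal", "low"),
                         background_style = c("leaf_stripes", "soil_texture", "clutter"),
                         occlusion_prob = 0.15, class_id = NULL, seed = NULL) {
  contrast_level <- match.arg(contrast_level)
  background_style <- match.arg(background_style)
  if (any(pest_scale_range <= 0) || any(pest_scale_range >= 1))
    stop("pest_scale_range must lie in (0, 1)")
  if (diff(range(pest_scale_range)) < 0 || pest_scale_range[1] > pest_scale_range[2])
    stop("pest_scale_range must be increasing")
  if (any(n_pests < 0)) stop("n_pests must be non-negative")
  if (any(body_aspect_range < 1)) stop("body_aspect_range must be >= 1")
  p <- list(canvas_size = as.integer(canvas_size), n_pests = as.integer(n_pests),
            pest_scale_range = pest_scale_range,
            body_aspect_range = body_aspect_range,
            n_appendages = as.integer(n_appendages),
            contrast_level = contrast_level, background_style = background_style,
            occlusion_prob = occlusion_prob, class_id = class_id, seed = seed)
  class(p) <- "catu_scene_params"
  p
}

bilinear_grid <- function(grid, n) {
  g <- nrow(grid) - 1L
  t <- (seq_len(n) - 0.5) / n * g + 1
  i0 <- pmin(floor(t), g)
  fi <- t - i0
  # interpolate rows then columns
  a <- grid[i0, , drop = FALSE] * (1 - fi) + grid[i0 + 1L, , drop = FALSE] * fi
  b <- a[, i0, drop = FALSE] * rep(1 - fi, each = n) + a[, i0 + 1L, drop = FALSE] * rep(fi, each = n)
  b
}

value_noise <- function(n, octaves = 4L, base = 4L) {
  acc <- matrix(0, n, n)
  amp <- 1
  tot <- 0
  for (o in seq_len(octaves) - 1L) {
    g <- base * 2L^o
    grid <- matrix(stats::rnorm((g + 1L)^2), g + 1L, g + 1L)
    acc <- acc + amp * bilinear_grid(grid, n)
    tot <- tot + amp
    amp <- amp / 2
  }
  acc <- acc / tot
  rng <- range(acc)
  if (diff(rng) == 0) return(matrix(0.5, n, n))
  (acc - rng[1]) / diff(rng)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

make_background <- function(style, n) {
  lum <- 0.35 + 0.45 * value_noise(n)
  X <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  Y <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  img <- array(0, dim = c(n, n, 3L))
  if (style == "soil_texture") {
    base <- c(0.48, 0.35, 0.22)
    for (ch in 1:3) img[, , ch] <- base[ch] * (0.5 + lum)
  } else {
    base <- c(0.30, 0.52, 0.20)
    shade <- matrix(1, n, n)
    for (k in seq_len(2L + stats::rpois(1, 1))) {
      th <- stats::runif(1, 0, pi)
      freq <- stats::runif(1, 3, 12)
      ph <- stats::runif(1, 0, 2 * pi)
      s <- sin(2 * pi * freq * (cos(th) * X + sin(th) * Y) / n + ph)
      shade <- shade * (0.88 + 0.12 * s)
    }
    for (ch in 1:3) img[, , ch] <- base[ch] * (0.45 + 0.85 * lum) * shade
  }
  if (style == "clutter") {
    # overlay bright/dark vegetation blades and debris blobs
    for (k in seq_len(8L + stats::rpois(1, 4))) {
      img <- draw_blade(img, cx = stats::runif(1, 1, n), cy = stats::runif(1, 1, n),
                        theta = stats::runif(1, 0, pi),
                        width = stats::runif(1, 1.5, 5),
                        len = stats::runif(1, 0.2, 0.9) * n,
                        tint = stats::runif(1, 0.6, 1.4))
    }
  }
  clamp01(img)
}

# Draw a grass blade (thick oriented segment) onto an RGB image; returns it.
draw_blade <- function(img, cx, cy, theta, width, len, tint) {
  n <- dim(img)[1]
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), times = n), n, n)
  u <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  v <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  sel <- abs(u) <= len / 2 & abs(v) <= width / 2
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[sel] <- clamp01(pl[sel] * tint)
    img[, , ch] <- pl
  }
  attr(img, "last_sel") <- sel
  img
}

# Rasterize one pest body; returns a logical mask of body pixels.
pest_body_mask <- function(n, cx, cy, L, Wb, theta, family) {
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), times = n), n, n)
  u <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  v <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  r <- Wb / 2
  if (family == 1L) {
    # capsule: rectangle with half-disc caps
    du <- pmax(abs(u) - (L / 2 - r), 0)
    sel <- du^2 + v^2 <= r^2
  } else if (family == 2L) {
    # segmented body: three overlapping ellipses along the axis
    sel <- matrix(FALSE, n, n)
    for (off in c(-L / 3, 0, L / 3)) {
      a <- L / 4
      sel <- sel | ((u - off)^2 / a^2 + v^2 / r^2 <= 1)
    }
  } else {
    # winged: slim body ellipse plus two swept-back wing ellipses
    sel <- (u^2 / (L / 2)^2 + v^2 / (r * 0.7)^2 <= 1)
    for (sgn in c(-1, 1)) {
      uw <- (u + L * 0.1) * cos(0.5 * sgn) + (v - sgn * r) * sin(0.5 * sgn)
      vw <- -(u + L * 0.1) * sin(0.5 * sgn) + (v - sgn * r) * cos(0.5 * sgn)
      sel <- sel | (uw^2 / (L * 0.35)^2 + vw^2 / (r * 0.8)^2 <= 1)
    }
  }
  sel
}

# Rasterize thin polyline appendages starting at the body boundary.
appendage_pixels <- function(n, cx, cy, L, Wb, theta, k) {
  pts <- NULL
  for (j in seq_len(k)) {
    phi <- stats::runif(1, 0, 2 * pi)
    # boundary of an ellipse with half-axes L/2, Wb/2 in body frame
    rho <- 1 / sqrt((cos(phi) / (L / 2))^2 + (sin(phi) / (Wb / 2))^2)
    bx <- cx + rho * cos(phi + theta)
    by <- cy + rho * sin(phi + theta)
    dir <- phi + theta + stats::runif(1, -0.4, 0.4)
    x0 <- bx; y0 <- by
    for (seg in 1:2) {
      len <- stats::runif(1, 0.15, 0.45) * L
      x1 <- x0 + len * cos(dir)
      y1 <- y0 + len * sin(dir)
      m <- ceiling(2 * len) + 1L
      ts <- seq(0, 1, length.out = m)
      px <- round(x0 + ts * (x1 - x0))
      py <- round(y0 + ts * (y1 - y0))
      pts <- rbind(pts, cbind(py, px))
      x0 <- x1; y0 <- y1
      dir <- dir + stats::runif(1, -0.7, 0.7)
    }
  }
  if (is.null(pts)) return(matrix(integer(0), 0, 2))
  keep <- pts[, 1] >= 1 & pts[, 1] <= n & pts[, 2] >= 1 & pts[, 2] <= n
  unique(pts[keep, , drop = FALSE])
}

luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Generate a synthetic pest scene
#'
#' Draws a procedurally textured background, places pests as oriented
#' capsule/segmented/winged bodies with thin polyline appendages, optionally
#' occludes them with foliage, and records the exact binary mask of the
#' visible pest pixels. The output image is quantized to 8-bit levels so
#' that a PNG round trip is lossless. Fully determined by
#' `(params, seed)`.
#'
#' @param params A [scene_params()].
#' @param seed Integer seed (falls back to `params$seed`).
#' @return A `catu_sample`: `image` (H x W x 3 in \[0, 1\]), `mask`
#'   (H x W integer 0/1), `class_id`, `provenance`.
#' @export
generate_pest_scene <- function(params = scene_params(), seed = params$seed) {
  stopifnot(inherits(params, "catu_scene_params"))
  if (is.null(seed)) stop("generate_pest_scene: a seed is required for reproducibility")
  with_seed(seed, {
    n <- params$canvas_size
    img <- make_background(params$background_style, n)
    mask <- matrix(FALSE, n, n)
    family <- params$class_id %||% sample(1:3, 1)
    npest <- if (params$n_pests[1] == params$n_pests[2]) params$n_pests[1] else
      sample(params$n_pests[1]:params$n_pests[2], 1)
    bg_lum <- luminance(img)
    for (p in seq_len(npest)) {
      L <- stats::runif(1, params$pest_scale_range[1], params$pest_scale_range[2]) * n
      L <- max(L, 2)
      aspect <- stats::runif(1, params$body_aspect_range[1], params$body_aspect_range[2])
      Wb <- max(L / aspect, 1.2)
      margin <- L / 2 + 2
      cx <- stats::runif(1, margin, n - margin)
      cy <- stats::runif(1, margin, n - margin)
      theta <- stats::runif(1, 0, pi)
      body <- pest_body_mask(n, cx, cy, L, Wb, theta, family)
      app <- appendage_pixels(n, cx, cy, L, Wb, theta,
                              sample(params$n_appendages[1]:params$n_appendages[2], 1))
      pm <- body
      if (nrow(app)) pm[app] <- TRUE
      if (!any(pm)) next
      local_lum <- mean(bg_lum[pm])
      if (params$contrast_level == "low") {
        target <- local_lum * stats::runif(1, 0.9, 1.1)
        col <- clamp01(c(0.9, 1.0, 0.85) * target)
      } else {
        # dark-bodied pest well separated from the background luminance
        target <- max(0.04, local_lum - stats::runif(1, 0.3, 0.45))
        hue <- stats::runif(3, 0.8, 1.2)
        col <- clamp01(hue * target * c(1.15, 1.0, 0.8))
      }
      mottle <- stats::rnorm(sum(pm), sd = 0.015)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[pm] <- clamp01(col[ch] + mottle)
        img[, , ch] <- pl
      }
      mask <- mask | pm
      if (stats::runif(1) < params$occlusion_prob) {
        img <- draw_blade(img, cx, cy, theta = stats::runif(1, 0, pi),
                          width = stats::runif(1, 2, max(3, Wb)),
                          len = n, tint = stats::runif(1, 0.7, 1.2))
        occ <- attr(img, "last_sel")
        mask[occ] <- FALSE
        attr(img, "last_sel") <- NULL
      }
    }
    img <- round(clamp01(img) * 255) / 255  # 8-bit quantization, PNG-exact
    attr(img, "last_sel") <- NULL
    new_sample(img, mask + 0L, family,
               provenance = list(params = unclass(params), seed = seed,
                                 augmentation = character(0)))
  })
}

new_sample <- function(image, mask, class_id, provenance = list()) {
  s <- list(image = image, mask = mask, class_id = class_id, provenance = provenance)
  class(s) <- "catu_sample"
  s
}

#' @export
print.catu_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("catu_sample: %dx%d image, class %s, foreground %.2f%%%s\n",
              d[1], d[2], x$class_id, 100 * mean(x$mask > 0),
              if (length(x$provenance$augmentation))
                paste0(" [", paste(x$provenance$augmentation, collapse = "+"), "]")
              else ""))
  invisible(x)
}

#' @export
plot.catu_sample <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  plot_raster(x$image, main = "image")
  plot_raster(array(rep(x$mask, 3), dim = c(dim(x$mask), 3)), main = "mask")
  invisible(x)
}

plot_raster <- function(img, main = "") {
  graphics::plot(0:1, 0:1, type = "n", axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1)
}

rot90cw_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_geom <- function(image, mask, fun) {
  chans <- lapply(1:3, function(ch) fun(image[, , ch]))
  img <- array(0, dim = c(dim(chans[[1]]), 3L))
  for (ch in 1:3) img[, , ch] <- chans[[ch]]
  list(image = img, mask = fun(mask))
}

augment_bank <- c("hflip", "vflip", "rot90", "rot180", "rot270",
                  "transpose", "antitranspose",
                  "bright_up", "bright_down", "gamma", "contrast",
                  "crop1", "crop2", "crop3")

apply_transform <- function(sample, name, seed = 0L) {
  img <- sample$image
  msk <- sample$mask
  hfl <- function(m) m[, ncol(m):1, drop = FALSE]
  vfl <- function(m) m[nrow(m):1, , drop = FALSE]
  out <- switch(name,
    hflip = apply_geom(img, msk, hfl),
    vflip = apply_geom(img, msk, vfl),
    rot90 = apply_geom(img, msk, rot90cw_mat),
    rot180 = apply_geom(img, msk, function(m) hfl(vfl(m))),
    rot270 = apply_geom(img, msk, function(m) rot90cw_mat(rot90cw_mat(rot90cw_mat(m)))),
    transpose = apply_geom(img, msk, t),
    antitranspose = apply_geom(img, msk, function(m) t(m)[ncol(m):1, nrow(m):1, drop = FALSE]),
    bright_up = list(image = round(clamp01(img * 1.2) * 255) / 255, mask = msk),
    bright_down = list(image = round(clamp01(img * 0.8) * 255) / 255, mask = msk),
    gamma = list(image = round(clamp01(img^0.85) * 255) / 255, mask = msk),
    contrast = list(image = round(clamp01((img - 0.5) * 1.15 + 0.5) * 255) / 255, mask = msk),
    crop1 = crop_resize_aug(img, msk, 0.85, seed + 11L),
    crop2 = crop_resize_aug(img, msk, 0.90, seed + 22L),
    crop3 = crop_resize_aug(img, msk, 0.95, seed + 33L),
    stop("unknown transform: ", name)
  )
  prov <- sample$provenance
  prov$augmentation <- c(prov$augmentation, name)
  new_sample(out$image, out$mask, sample$class_id, prov)
}

crop_resize_aug <- function(img, msk, frac, seed) {
  with_seed(seed, {
    H <- dim(img)[1]; W <- dim(img)[2]
    h <- max(16L, floor(frac * H)); w <- max(16L, floor(frac * W))
    i0 <- sample.int(H - h + 1L, 1L); j0 <- sample.int(W - w + 1L, 1L)
    ci <- img[i0:(i0 + h - 1L), j0:(j0 + w - 1L), , drop = FALSE]
    cm <- msk[i0:(i0 + h - 1L), j0:(j0 + w - 1L), drop = FALSE]
    list(image = round(resize_image(ci, H, W) * 255) / 255,
         mask = resize_mask(cm, H, W))
  })
}

#' Augment a sample
#'
#' Applies image/mask-consistent transforms from a bank of 14 variants:
#' the 7 non-identity dihedral flips/rotations (which conserve mask area
#' exactly), 3 photometric jitters, and 3 random crop-and-resize variants.
#'
#' @param sample A `catu_sample`.
#' @param n_variants Number of variants to emit (up to 14 distinct ones).
#' @param transform Apply one named transform instead (see
#'   `catransunet:::augment_bank`).
#' @param seed Seed for the stochastic crop transforms.
#' @return A single sample when `transform` is given, otherwise a list of
#'   `n_variants` samples.
#' @export
augment_sample <- function(sample, n_variants = 14L, transform = NULL, seed = 1L) {
  stopifnot(inherits(sample, "catu_sample"))
  if (!is.null(transform)) return(apply_transform(sample, transform, seed))
  picks <- augment_bank[((seq_len(n_variants) - 1L) %% length(augment_bank)) + 1L]
  lapply(seq_along(picks), function(i) apply_transform(sample, picks[i], seed + i))
}

resize_image <- function(img, H, W) {
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- array(0, dim = c(H, W, dim(img)[3]))
  yi <- (seq_len(H) - 0.5) * h / H + 0.5
  xi <- (seq_len(W) - 0.5) * w / W + 0.5
  y0 <- pmin(pmax(floor(yi), 1L), h - 1L); fy <- pmin(pmax(yi - y0, 0), 1)
  x0 <- pmin(pmax(floor(xi), 1L), w - 1L); fx <- pmin(pmax(xi - x0, 0), 1)
  for (ch in seq_len(dim(img)[3])) {
    pl <- img[, , ch]
    a <- pl[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
      pl[y0 + 1L, x0, drop = FALSE] * outer(fy, 1 - fx) +
      pl[y0, x0 + 1L, drop = FALSE] * outer(1 - fy, fx) +
      pl[y0 + 1L, x0 + 1L, drop = FALSE] * outer(fy, fx)
    out[, , ch] <- a
  }
  out
}

resize_mask <- function(msk, H, W) {
  h <- dim(msk)[1]; w <- dim(msk)[2]
  yi <- pmin(pmax(ceiling((seq_len(H) - 0.5) * h / H), 1L), h)
  xi <- pmin(pmax(ceiling((seq_len(W) - 0.5) * w / W), 1L), w)
  msk[yi, xi, drop = FALSE] + 0L
}

#' Preprocess a sample for training
#'
#' Random square crop (seeded) followed by a resize: bilinear for the
#' image, nearest-neighbour for the mask so it stays binary.
#'
#' @param sample A `catu_sample`.
#' @param crop_size Side of the random crop (input must be at least this
#'   large).
#' @param target_size Output side length.
#' @param seed Seed for the crop offset.
#' @return The preprocessed `catu_sample`.
#' @export
preprocess_sample <- function(sample, crop_size = 640L, target_size = 256L, seed = 1L) {
  stopifnot(inherits(sample, "catu_sample"))
  H <- dim(sample$image)[1]; W <- dim(sample$image)[2]
  if (H < crop_size || W < crop_size)
    stop("preprocess_sample: input (", H, "x", W, ") smaller than crop size ", crop_size)
  with_seed(seed, {
    i0 <- if (H == crop_size) 1L else sample.int(H - crop_size + 1L, 1L)
    j0 <- if (W == crop_size) 1L else sample.int(W - crop_size + 1L, 1L)
    ci <- sample$image[i0:(i0 + crop_size - 1L), j0:(j0 + crop_size - 1L), , drop = FALSE]
    cm <- sample$mask[i0:(i0 + crop_size - 1L), j0:(j0 + crop_size - 1L), drop = FALSE]
    img <- round(clamp01(resize_image(ci, target_size, target_size)) * 255) / 255
    new_sample(img, resize_mask(cm, target_size, target_size), sample$class_id,
               within_prov(sample, sprintf("crop%d_resize%d", crop_size, target_size)))
  })
}

within_prov <- function(sample, tag) {
  prov <- sample$provenance
  prov$augmentation <- c(prov$augmentation, tag)
  prov
}

#' Build a synthetic dataset
#'
#' Generates `n_per_class[i]` scenes for each class, mapping class identity
#' to a pest shape family and background style, with per-sample sub-seeds
#' derived from `seed`. Optionally balances small classes up to
#' `balance_to` samples by augmentation.
#'
#' @param n_per_class Integer vector of per-class scene counts.
#' @param seed Master seed.
#' @param canvas_size Scene canvas side.
#' @param balance_to If non-NULL, augment each class up to this count.
#' @param base_params A [scene_params()] template.
#' @return A `catu_dataset` (list of samples plus a manifest data frame).
#' @export
build_dataset <- function(n_per_class, seed = 1L, canvas_size = 640L,
                          balance_to = NULL, base_params = NULL) {
  if (length(n_per_class) == 0L) stop("build_dataset: n_per_class must be nonempty")
  base_params <- base_params %||% scene_params(canvas_size = canvas_size)
  styles <- c("leaf_stripes", "soil_texture", "clutter")
  sub_seeds <- with_seed(seed, sample.int(2^30, sum(pmax(n_per_class, 0))))
  samples <- list()
  manifest <- NULL
  k <- 0L
  for (cl in seq_along(n_per_class)) {
    pars <- base_params
    pars$class_id <- ((cl - 1L) %% 3L) + 1L
    pars$background_style <- styles[((cl - 1L) %% 3L) + 1L]
    for (j in seq_len(n_per_class[cl])) {
      k <- k + 1L
      s <- generate_pest_scene(pars, seed = sub_seeds[k])
      s$class_id <- cl
      samples[[k]] <- s
      manifest <- rbind(manifest,
                        data.frame(id = k, class_id = cl, seed = sub_seeds[k],
                                   augmented_from = NA_integer_))
    }
  }
  if (!is.null(balance_to)) {
    for (cl in seq_along(n_per_class)) {
      have <- which(manifest$class_id == cl)
      need <- balance_to - length(have)
      j <- 0L
      while (need > 0L) {
        j <- j + 1L
        src <- have[((j - 1L) %% length(have)) + 1L]
        tr <- augment_bank[((j - 1L) %% length(augment_bank)) + 1L]
        k <- k + 1L
        samples[[k]] <- apply_transform(samples[[src]], tr, seed + k)
        manifest <- rbind(manifest,
                          data.frame(id = k, class_id = cl, seed = NA_integer_,
                                     augmented_from = src))
        need <- need - 1L
      }
    }
  }
  ds <- list(samples = samples, manifest = manifest, seed = seed)
  class(ds) <- "catu_dataset"
  ds
}

#' @export
print.catu_dataset <- function(x, ...) {
  tab <- table(x$manifest$class_id)
  cat(sprintf("catu_dataset: %d samples, %d classes (%s)\n",
              length(x$samples), length(tab),
              paste(sprintf("c%s:%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
length.catu_dataset <- function(x) length(x$samples)

as_sample_list <- function(x) {
  if (inherits(x, "catu_dataset")) return(x$samples)
  if (inherits(x, "catu_sample")) return(list(x))
  if (is.list(x) && length(x) == 0L) return(list())
  if (is.list(x) && length(x) && !is.null(x[[1]]$image)) return(x)
  if (is.list(x) && !is.null(x$image)) return(list(x))
  stop("expected a catu_dataset, a catu_sample, or a list of samples")
}
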