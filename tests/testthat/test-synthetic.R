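# Synthetic pest-scene generator, augmentation, preprocessing, datasets.

test_that("scene generation is a pure function of (params, seed)", {
  p <- scene_params(canvas_size = 64L)
  s1 <- generate_pest_scene(p, seed = 7)
  s2 <- generate_pest_scene(p, seed = 7)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  s3 <- generate_pest_scene(p, seed = 8)
  expect_false(identical(s1$image, s3$image))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_pest_scene(p, seed = 9)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("a scene with no pests has an all-zero mask", {
  p <- scene_params(canvas_size = 48L, n_pests = c(0L, 0L))
  s <- generate_pest_scene(p, seed = 1)
  expect_true(all(s$mask == 0))
  expect_equal(dim(s$image), c(48L, 48L, 3L))
})

test_that("masks are exact binary rasters consistent with the drawn pests", {
  for (sd in 1:5) {
    s <- generate_pest_scene(scene_params(canvas_size = 64L), seed = 20 + sd)
    expect_true(all(s$mask %in% c(0L, 1L)))
    expect_equal(dim(s$mask), dim(s$image)[1:2])
  }
  # images are quantized to 8-bit levels
  s <- generate_pest_scene(scene_params(canvas_size = 48L), seed = 31)
  expect_true(all(abs(s$image * 255 - round(s$image * 255)) < 1e-9))
})

test_that("a fixed-scale capsule covers an analytically bounded area fraction", {
  n <- 160L
  p <- scene_params(canvas_size = n, n_pests = c(1L, 1L),
                    pest_scale_range = c(0.2, 0.2),
                    body_aspect_range = c(1.8, 4),
                    n_appendages = c(0L, 0L), occlusion_prob = 0,
                    class_id = 1L)
  L <- 0.2 * n
  # capsule area (L - W) * W + pi * (W/2)^2 for W = L / aspect
  area <- function(a) {
    W <- L / a
    (L - W) * W + pi * (W / 2)^2
  }
  lo <- min(area(1.8), area(4)) / n^2
  hi <- max(area(1.8), area(4)) / n^2
  fr <- vapply(1:10, function(sd)
    mean(generate_pest_scene(p, seed = 100 + sd)$mask), numeric(1))
  expect_true(all(fr >= lo * 0.8))
  expect_true(all(fr <= hi * 1.2))
})

test_that("over many seeded scenes the mean foreground fraction is in band", {
  n <- 96L
  p <- scene_params(canvas_size = n, n_pests = c(1L, 3L),
                    pest_scale_range = c(0.08, 0.3),
                    body_aspect_range = c(2, 3),
                    n_appendages = c(0L, 0L), occlusion_prob = 0, class_id = 1L)
  frs <- vapply(1:100, function(sd) mean(generate_pest_scene(p, seed = sd)$mask),
                numeric(1))
  area <- function(s, a) {
    L <- s * n; W <- L / a
    ((L - W) * W + pi * (W / 2)^2) / n^2
  }
  lo <- 1 * area(0.08, 3)   # one smallest slim pest
  hi <- 3 * area(0.3, 2)    # three largest fat pests
  expect_gt(mean(frs), lo)
  expect_lt(mean(frs), hi)
})

test_that("low-contrast scenes place pests near the background luminance", {
  lum <- function(img) 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  p_lo <- scene_params(canvas_size = 64L, n_pests = c(2L, 2L),
                       pest_scale_range = c(0.15, 0.25), contrast_level = "low",
                       occlusion_prob = 0, class_id = 1L)
  p_no <- scene_params(canvas_size = 64L, n_pests = c(2L, 2L),
                       pest_scale_range = c(0.15, 0.25), contrast_level = "normal",
                       occlusion_prob = 0, class_id = 1L)
  d_lo <- d_no <- numeric(5)
  for (sd in 1:5) {
    slo <- generate_pest_scene(p_lo, seed = 200 + sd)
    sno <- generate_pest_scene(p_no, seed = 200 + sd)
    d_lo[sd] <- abs(mean(lum(slo$image)[slo$mask == 1]) - mean(lum(slo$image)[slo$mask == 0]))
    d_no[sd] <- abs(mean(lum(sno$image)[sno$mask == 1]) - mean(lum(sno$image)[sno$mask == 0]))
  }
  expect_lt(mean(d_lo), mean(d_no))
})

test_that("horizontal flip is an involution and rotations conserve mask area", {
  s <- generate_pest_scene(scene_params(canvas_size = 48L), seed = 41)
  ff <- augment_sample(augment_sample(s, transform = "hflip"), transform = "hflip")
  expect_identical(ff$image, s$image)
  expect_identical(ff$mask, s$mask)
  for (tr in c("rot90", "rot180", "rot270", "vflip", "transpose", "antitranspose")) {
    a <- augment_sample(s, transform = tr)
    expect_equal(sum(a$mask), sum(s$mask))
  }
  r4 <- s
  for (i in 1:4) r4 <- augment_sample(r4, transform = "rot90")
  expect_identical(r4$image, s$image)
})

test_that("fourteen augmentation variants are distinct and traceable", {
  s <- generate_pest_scene(scene_params(canvas_size = 48L), seed = 42)
  vars <- augment_sample(s, n_variants = 14L, seed = 5)
  expect_length(vars, 14L)
  tags <- vapply(vars, function(v) tail(v$provenance$augmentation, 1), character(1))
  expect_length(unique(tags), 14L)
  imgs <- vapply(vars, function(v) digest_num(v$image), character(1))
  expect_length(unique(imgs), 14L)
  # photometric transforms leave the mask untouched
  for (v in vars[tags %in% c("bright_up", "bright_down", "gamma", "contrast")])
    expect_identical(v$mask, s$mask)
})

test_that("preprocessing crops then resizes, keeping the mask binary", {
  s <- generate_pest_scene(scene_params(canvas_size = 800L,
                                        pest_scale_range = c(0.05, 0.15)), seed = 43)
  out <- preprocess_sample(s, crop_size = 640L, target_size = 256L, seed = 3)
  expect_equal(dim(out$image), c(256L, 256L, 3L))
  expect_equal(dim(out$mask), c(256L, 256L))
  expect_true(all(out$mask %in% c(0L, 1L)))
  out2 <- preprocess_sample(s, crop_size = 640L, target_size = 256L, seed = 3)
  expect_identical(out$image, out2$image)
  out3 <- preprocess_sample(s, crop_size = 640L, target_size = 256L, seed = 4)
  expect_false(identical(out$image, out3$image))
  expect_error(preprocess_sample(out, crop_size = 640L), "smaller")
})

test_that("build_dataset honours per-class counts and balances by augmentation", {
  ds <- build_dataset(c(10L, 2L), seed = 1, canvas_size = 48L, balance_to = 10L)
  tab <- table(ds$manifest$class_id)
  expect_equal(as.numeric(tab), c(10, 10))
  expect_equal(sum(!is.na(ds$manifest$augmented_from)), 8L)
  expect_true(all(ds$manifest$class_id[!is.na(ds$manifest$augmented_from)] == 2))

  counts <- as.integer(round(c(1115, 485, 261, 1053, 504, 506, 369,
                               838, 889, 553, 856, 404, 173, 409) / 50))
  ds14 <- build_dataset(counts, seed = 2, canvas_size = 32L)
  expect_equal(length(ds14), sum(counts))
  expect_gt(length(ds14), 160L)
  expect_equal(length(unique(ds14$manifest$class_id)), 14L)

  m1 <- build_dataset(c(3L, 2L), seed = 9, canvas_size = 32L)$manifest
  m2 <- build_dataset(c(3L, 2L), seed = 9, canvas_size = 32L)$manifest
  expect_identical(m1, m2)
})
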