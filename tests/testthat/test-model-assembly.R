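# Whole-model assembly: shape contracts, variants, accounting.

test_that("configuration invariants are enforced", {
  expect_error(model_config(stage_widths = c(8L, 8L, 8L)), "4 strictly positive")
  expect_error(model_config(dilation_rates = c(1L, 2L)), "4 positive")
  expect_error(model_config(bottleneck_width = 30L, gsa_reduction = 8L), "divide")
  expect_error(model_config(input_size = 100L), "divisible by 16")
  expect_error(model_config(encoder_variant = "resnet"), "arg")
  expect_error(model_config(bottleneck_variant = "SE"), "arg")
})

test_that("forward output matches input resolution with one sigmoid channel", {
  for (sz in c(64L, 112L, 128L)) {  # 112 exercises non-dyadic pooled attention grids
    m <- build_model(tiny_cfg(sz), seed = 1)
    p <- forward_pass(m, rand_fmap(3, sz, sz, seed = sz))
    expect_equal(dim(p), c(1L, sz, sz))
    expect_true(all(p >= 0 & p <= 1) && all(is.finite(p)))
  }
  # all-zero input also yields finite probabilities in range
  m <- build_model(tiny_cfg(64L), seed = 2)
  p0 <- forward_pass(m, array(0, dim = c(3, 64, 64)))
  expect_true(all(is.finite(p0)) && all(p0 >= 0 & p0 <= 1))
})

test_that("evaluation mode is deterministic and batched shapes are honoured", {
  m <- build_model(tiny_cfg(32L), seed = 3)
  x <- rand_fmap(3, 32, 32, seed = 5)
  b <- array(0, dim = c(3, 32, 32, 32))
  for (i in 1:32) b[, , , i] <- x
  p <- forward_pass(m, b)
  expect_equal(dim(p), c(1L, 32L, 32L, 32L))
  for (i in 2:32) expect_identical(p[, , , i], p[, , , 1])
})

test_that("wrong input shapes raise shape errors instead of resizing", {
  m <- build_model(tiny_cfg(64L), seed = 4)
  expect_error(forward_pass(m, rand_fmap(3, 32, 32, seed = 1)), "spatial size")
  expect_error(forward_pass(m, rand_fmap(1, 64, 64, seed = 1)), "channels")
})

test_that("single-layer parameter counts follow their closed forms", {
  c1 <- catransunet:::mod_conv(3, 4, k = 1L, bn = FALSE, bias = TRUE)
  expect_equal(sum(vapply(catransunet:::collect_params(c1), function(p)
    length(p$value), numeric(1))), 16)  # 3*4 + 4
  c2 <- catransunet:::mod_conv(2, 2, k = 3L, bn = FALSE, bias = FALSE)
  expect_equal(sum(vapply(catransunet:::collect_params(c2), function(p)
    length(p$value), numeric(1))), 36)  # 3*3*2*2
})

test_that("count_parameters totals equal the per-block breakdown", {
  m <- build_model(tiny_cfg(64L), seed = 5)
  rep <- count_parameters(m)
  expect_equal(rep$total_params, sum(rep$per_block_params))
  expect_identical(rep$total_params,
                   sum(vapply(m$params, function(p) length(p$value), numeric(1))))
  # parameter count does not depend on the configured input size
  m2 <- build_model(tiny_cfg(128L), seed = 5)
  expect_equal(count_parameters(m2)$total_params, rep$total_params)
  tmp <- tempfile(fileext = ".json")
  write_param_report(rep, tmp)
  expect_equal(jsonlite::fromJSON(tmp)$total_params, rep$total_params)
})

test_that("FLOP metering follows the MACx2 closed forms and scales with area", {
  x8 <- array(0, dim = c(3, 8, 8, 1))
  w <- matrix(0, 4, 3)
  f8 <- catransunet:::with_flop_meter(catransunet:::t_conv1x1(x8, w))$flops
  expect_equal(f8, 2 * 3 * 4 * 64)  # 3072
  x16 <- array(0, dim = c(3, 16, 16, 1))
  f16 <- catransunet:::with_flop_meter(catransunet:::t_conv1x1(x16, w))$flops
  expect_equal(f16, 4 * f8)
  # dense 3x3 convolution: 2 * k^2 * cin * cout * H * W
  xc <- array(0, dim = c(2, 8, 8, 1))
  wc <- array(0, dim = c(5, 2, 3, 3))
  fc <- catransunet:::with_flop_meter(catransunet:::t_conv2d(xc, wc))$flops
  expect_equal(fc, 2 * 9 * 2 * 5 * 64)
})

test_that("estimate_flops scales near-linearly in pixel count for conv variants", {
  cfg <- tiny_cfg(64L, skip = "plain_skip", bottleneck = "none")
  m <- build_model(cfg, seed = 6)
  g64 <- estimate_flops(m, 64L)
  g128 <- estimate_flops(m, 128L)
  expect_equal(g128 / g64, 4, tolerance = 0.02)
})

test_that("every ablation variant builds and completes forward + backward at 64x64", {
  grid <- ablation_grid()
  expect_equal(nrow(grid), 11L)
  y <- array(0, dim = c(1, 64, 64, 1))
  y[1, 20:40, 20:40, 1] <- 1
  for (i in seq_len(nrow(grid))) {
    cfg <- tiny_cfg(64L, skip = grid$skip[i], bottleneck = grid$bottleneck[i],
                    encoder = grid$encoder[i])
    m <- build_model(cfg, seed = 10 + i)
    x <- rand_fmap(3, 64, 64, B = 1, seed = 20 + i)
    tp <- catransunet:::with_tape({
      z <- catransunet:::model_forward(m, x, training = TRUE, logits = TRUE)
      catransunet:::t_bce_logits(z, y)
    })
    loss <- catransunet:::nval(tp$result)
    expect_true(is.finite(loss))
    catransunet:::backward(tp$result, tp$tape)
    grads <- vapply(m$params, function(p) !is.null(p$grad), logical(1))
    expect_true(all(grads),
                info = paste("variant", i, "missing grads:",
                             paste(names(m$params)[!grads], collapse = ", ")))
  }
})

test_that("gradient reaches every parameter of the full architecture", {
  m <- build_model(tiny_cfg(32L), seed = 30)
  x <- rand_fmap(3, 32, 32, B = 2, seed = 31)
  y <- array((runif(2 * 32 * 32) > 0.8) + 0, dim = c(1, 32, 32, 2))
  tp <- catransunet:::with_tape({
    z <- catransunet:::model_forward(m, x, training = TRUE, logits = TRUE)
    catransunet:::t_bce_logits(z, y)
  })
  catransunet:::backward(tp$result, tp$tape)
  nz <- vapply(m$params, function(p) !is.null(p$grad) && any(p$grad != 0), logical(1))
  expect_true(all(vapply(m$params, function(p) !is.null(p$grad), logical(1))))
  # gates start at 0 yet still receive a gradient signal
  expect_true(nz[["bottleneck_attn.gamma1"]] || nz[["bottleneck_attn.gamma2"]])
})

test_that("print and summary methods expose the architecture accounting", {
  m <- build_model(tiny_cfg(32L), seed = 40)
  expect_output(print(m), "trainable parameters")
  expect_output(print(m$config), "stage widths")
  s <- capture.output(rep <- summary(m))
  expect_true(any(grepl("Per-block", s)))
  expect_s3_class(rep, "catu_param_report")
})
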