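# Differentiable primitive ops: value oracles and finite-difference
# gradient checks for every kernel used by the network.

fd_check <- function(op, inputs, param_idx = seq_along(inputs), eps = 1e-6,
                     tol = 1e-4, seed = 99) {
  # builds scalar loss sum(out * r) and compares analytic input gradients
  # against central differences at a few random positions
  set.seed(seed)
  nodes <- lapply(inputs, catransunet:::ad_node)
  tp <- catransunet:::with_tape({
    out <- do.call(op, nodes)
    out
  })
  r <- array(rnorm(length(catransunet:::nval(tp$result))),
             dim = dim(catransunet:::nval(tp$result)))
  loss_of <- function(vals) {
    nds <- lapply(vals, catransunet:::ad_node)
    sum(catransunet:::nval(do.call(op, nds)) * r)
  }
  tp$result$grad <- r
  tp$result$is_param <- TRUE  # keep the output node alive through the sweep
  for (i in seq.int(tp$tape$n, 1L)) {
    nd <- tp$tape$nodes[[i]]
    if (!is.null(nd$grad)) nd$backward(nd)
  }
  for (ii in param_idx) {
    an <- nodes[[ii]]$grad
    expect_false(is.null(an), info = paste("no gradient for input", ii))
    idx <- sample(length(inputs[[ii]]), min(3L, length(inputs[[ii]])))
    for (k in idx) {
      vp <- inputs; vp[[ii]][k] <- vp[[ii]][k] + eps
      vm <- inputs; vm[[ii]][k] <- vm[[ii]][k] - eps
      fd <- (loss_of(vp) - loss_of(vm)) / (2 * eps)
      expect_lt(abs(fd - an[k]) / max(1, abs(fd), abs(an[k])), tol)
    }
  }
}

test_that("dense and dilated convolution match a nested-loop reference", {
  set.seed(5)
  x <- rand_fmap(2, 7, 7, B = 1, seed = 5)
  w <- array(rnorm(3 * 2 * 3 * 3), dim = c(3, 2, 3, 3))
  y <- catransunet:::nval(catransunet:::t_conv2d(x, w, dilation = 1L))
  ref <- ref_conv2d(x[, , , 1], w, 1L)
  expect_lt(rel_err(y[, , , 1], ref), 1e-12)

  x9 <- rand_fmap(1, 9, 9, B = 1, seed = 6)
  w9 <- array(rnorm(2 * 1 * 9), dim = c(2, 1, 3, 3))
  y9 <- catransunet:::nval(catransunet:::t_conv2d(x9, w9, dilation = 3L))
  ref9 <- ref_conv2d(x9[, , , 1], w9, 3L)
  expect_lt(rel_err(y9[, , , 1], ref9), 1e-12)
})

test_that("convolution gradients pass finite differences", {
  x <- rand_fmap(2, 5, 5, B = 2, seed = 7)
  w <- array(rnorm(3 * 2 * 9, sd = 0.5), dim = c(3, 2, 3, 3))
  b <- rnorm(3)
  fd_check(function(x, w, b) catransunet:::t_conv2d(x, w, b, dilation = 1L),
           list(x, w, b))
  fd_check(function(x, w) catransunet:::t_conv2d(x, w, dilation = 2L),
           list(rand_fmap(1, 6, 6, B = 1, seed = 8),
                array(rnorm(9), dim = c(1, 1, 3, 3))))
})

test_that("1x1 convolution, transposed convolution and linear gradients check out", {
  fd_check(function(x, w, b) catransunet:::t_conv1x1(x, w, b),
           list(rand_fmap(3, 4, 4, B = 2, seed = 9),
                matrix(rnorm(6), 2, 3), rnorm(2)))
  fd_check(function(x, w, b) catransunet:::t_convT2x2(x, w, b),
           list(rand_fmap(2, 3, 3, B = 2, seed = 10),
                array(rnorm(2 * 2 * 4), dim = c(2, 2, 2, 2)), rnorm(2)))
  fd_check(function(x, w) catransunet:::t_linear(x, w),
           list(matrix(rnorm(6), 3, 2), matrix(rnorm(9), 3, 3)))
})

test_that("transposed 2x2 stride-2 convolution doubles the spatial size", {
  x <- rand_fmap(2, 3, 5, B = 1, seed = 11)
  w <- array(rnorm(3 * 2 * 4), dim = c(3, 2, 2, 2))
  y <- catransunet:::nval(catransunet:::t_convT2x2(x, w))
  expect_equal(dim(y), c(3, 6, 10, 1))
  # output at (2i-1+a', 2j-1+b') equals W_ab x[., i, j]
  expect_equal(y[, 1, 1, 1], w[, , 1, 1] %*% x[, 1, 1, 1, drop = TRUE] |> as.numeric())
  expect_equal(y[, 2, 2, 1], w[, , 2, 2] %*% x[, 1, 1, 1, drop = TRUE] |> as.numeric())
})

test_that("pooling and upsampling behave and differentiate correctly", {
  x <- rand_fmap(2, 4, 4, B = 2, seed = 12)
  m <- catransunet:::nval(catransunet:::t_maxpool2(x))
  expect_equal(dim(m), c(2, 2, 2, 2))
  expect_equal(m[1, 1, 1, 1], max(x[1, 1:2, 1:2, 1]))
  fd_check(function(x) catransunet:::t_maxpool2(x), list(x))

  a <- catransunet:::nval(catransunet:::t_avgpool(x, 2L))
  expect_equal(a[2, 1, 2, 1], mean(x[2, 1:2, 3:4, 1]))
  fd_check(function(x) catransunet:::t_avgpool(x, 2L), list(x))

  u <- catransunet:::nval(catransunet:::t_upsample_nn(x, 3L))
  expect_equal(dim(u), c(2, 12, 12, 2))
  expect_equal(u[1, 4:6, 4:6, 1], matrix(x[1, 2, 2, 1], 3, 3))
  fd_check(function(x) catransunet:::t_upsample_nn(x, 2L), list(x))
})

test_that("batch normalization normalizes and differentiates in both modes", {
  x <- rand_fmap(3, 4, 4, B = 2, seed = 13)
  g <- rnorm(3, 1, 0.1)
  be <- rnorm(3, 0, 0.1)
  st <- catransunet:::bn_state(3)
  y <- catransunet:::nval(catransunet:::t_bn(x, g, be, st, training = TRUE))
  ym <- y
  dim(ym) <- c(3, 32)
  # per-channel standardization then affine
  for (c in 1:3) {
    expect_equal(mean((ym[c, ] - be[c]) / g[c]), 0, tolerance = 1e-8)
    expect_equal(stats::sd((ym[c, ] - be[c]) / g[c]) * sqrt(31 / 32), 1, tolerance = 1e-3)
  }
  st2 <- catransunet:::bn_state(3)
  fd_check(function(x, g, b) catransunet:::t_bn(x, g, b, st2, training = TRUE),
           list(x, g, be), tol = 5e-4)
  st3 <- catransunet:::bn_state(3)
  fd_check(function(x, g, b) catransunet:::t_bn(x, g, b, st3, training = FALSE),
           list(x, g, be))
})

test_that("attention primitive matches the reference and differentiates", {
  set.seed(14)
  Q <- array(rnorm(2 * 4 * 1), dim = c(2, 4, 1))
  K <- array(rnorm(2 * 4 * 1), dim = c(2, 4, 1))
  V <- array(rnorm(3 * 4 * 1), dim = c(3, 4, 1))
  out <- catransunet:::nval(catransunet:::t_attn(Q, K, V, scale = sqrt(2)))
  ref <- ref_attention(Q[, , 1], K[, , 1], V[, , 1], sqrt(2))
  expect_lt(rel_err(out[, , 1], ref$O), 1e-12)
  fd_check(function(Q, K, V) catransunet:::t_attn(Q, K, V, scale = sqrt(2)),
           list(Q, K, V), tol = 5e-4)
})

test_that("elementwise ops differentiate", {
  x <- rand_fmap(2, 3, 3, B = 1, seed = 15)
  fd_check(function(x) catransunet:::t_relu(x), list(x))
  fd_check(function(x) catransunet:::t_sigmoid(x), list(x))
  fd_check(function(x) catransunet:::t_spatial_mean(x), list(x))
  g <- matrix(runif(2), 2, 1)
  fd_check(function(x, g) catransunet:::t_chmul(x, g), list(x, g))
  s <- 0.7
  fd_check(function(x, s) catransunet:::t_scalar_gate(x, s), list(x, s))
  y <- rand_fmap(3, 3, 3, B = 1, seed = 16)
  fd_check(function(x, y) catransunet:::t_concat_ch(x, y), list(x, y))
})
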