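# Dual Transformer-attention bottleneck: self-attention, position
# attention, gating, and their brute-force oracles.

test_that("Q/K/V projection matches an explicit matrix-product oracle", {
  blk <- tsa_block(4, seed = 1)
  x <- rand_fmap(4, 2, 2, seed = 2)
  pq <- project_qkv(x, blk)
  Fm <- matrix(x, 4, 4)
  for (nm in c("wq", "wk", "wv")) {
    W <- blk$params[[nm]]$value
    ref <- matrix(0, 4, 4)
    for (i in 1:4) for (p in 1:4) ref[i, p] <- sum(W[i, ] * Fm[, p])
    got <- switch(nm, wq = pq$Q, wk = pq$K, wv = pq$V)
    expect_lt(max(abs(got - ref)), 1e-12)
  }
  # identity projection passes the flattened map through
  blk$params$wq$value <- diag(4)
  expect_equal(project_qkv(x, blk)$Q, Fm)
  # zero key projection gives all-zero logits
  blk$params$wk$value <- matrix(0, 4, 4)
  expect_true(all(project_qkv(x, blk)$K == 0))
})

test_that("tsa_forward matches the brute-force attention oracle", {
  blk <- tsa_block(2, seed = 3)
  x <- rand_fmap(2, 2, 2, seed = 4)
  out <- tsa_forward(x, blk)
  pq <- project_qkv(x, blk)
  ref <- ref_attention(pq$Q, pq$K, pq$V, sqrt(2))
  expect_lt(rel_err(out, array(ref$O, dim = c(2, 2, 2))), 1e-5)
})

test_that("tsa degenerate cases: single position and constant input", {
  blk <- tsa_block(3, seed = 5)
  x1 <- rand_fmap(3, 1, 1, seed = 6)
  out1 <- tsa_forward(x1, blk)
  v <- blk$params$wv$value %*% as.numeric(x1)
  expect_equal(as.numeric(out1), as.numeric(v), tolerance = 1e-12)

  set.seed(6)
  xc <- array(rnorm(3), dim = c(3, 2, 2))  # recycles: constant across positions
  outc <- tsa_forward(xc, blk)
  for (c in 1:3) expect_lt(diff(range(outc[c, , ])), 1e-10)
})

test_that("the literal /dk scaling switch is honoured", {
  blk_sqrt <- tsa_block(4, scale = "sqrt", seed = 7)
  blk_lin <- tsa_block(4, scale = "linear", seed = 7)
  x <- rand_fmap(4, 2, 2, seed = 8)
  pq <- project_qkv(x, blk_sqrt)
  expect_equal(tsa_forward(x, blk_sqrt),
               array(ref_attention(pq$Q, pq$K, pq$V, sqrt(4))$O, dim = c(4, 2, 2)),
               tolerance = 1e-10)
  expect_equal(tsa_forward(x, blk_lin),
               array(ref_attention(pq$Q, pq$K, pq$V, 4)$O, dim = c(4, 2, 2)),
               tolerance = 1e-10)
})

test_that("gsa_position_map is a row-stochastic softmax of pairwise logits", {
  expect_equal(gsa_position_map(matrix(0, 4, 2), matrix(0, 2, 4)),
               matrix(0.25, 4, 4))
  expect_equal(gsa_position_map(matrix(1.3, 1, 1), matrix(2.1, 1, 1)),
               matrix(1, 1, 1))
  set.seed(9)
  m1 <- matrix(rnorm(6), 3, 2)
  M <- gsa_position_map(m1, t(m1))
  S <- m1 %*% t(m1)
  ref <- ref_softmax_rows(S)
  expect_lt(max(abs(M - ref)), 1e-12)
})

test_that("gsa_forward matches a nested-loop oracle with c' = c/8", {
  blk <- gsa_block(8, seed = 10)
  x <- rand_fmap(8, 2, 2, seed = 11)
  out <- gsa_forward(x, blk)
  Fm <- matrix(x, 8, 4)
  red <- blk$params$w_reduce$value %*% Fm
  val <- blk$params$w_value$value %*% Fm
  M <- gsa_position_map(t(red), red)
  ref <- matrix(0, 8, 4)
  for (i in 1:4) for (j in 1:4) ref[, i] <- ref[, i] + M[i, j] * val[, j]
  expect_lt(rel_err(out, array(ref, dim = c(8, 2, 2))), 1e-5)
  expect_error(gsa_block(9), "divide")
})

test_that("uniform position attention averages the value branch; n = 1 passes it through", {
  blk <- gsa_block(8, seed = 12)
  blk$params$w_reduce$value[] <- 0  # all logits zero -> uniform rows
  x <- rand_fmap(8, 2, 2, seed = 13)
  out <- gsa_forward(x, blk)
  val <- blk$params$w_value$value %*% matrix(x, 8, 4)
  for (i in 1:4) expect_equal(matrix(out, 8, 4)[, i], rowMeans(val), tolerance = 1e-12)

  x1 <- rand_fmap(8, 1, 1, seed = 14)
  out1 <- gsa_forward(x1, blk)
  expect_equal(as.numeric(out1),
               as.numeric(blk$params$w_value$value %*% as.numeric(x1)),
               tolerance = 1e-12)
})

test_that("the DTA gates start at zero giving an exact bitwise pass-through", {
  blk <- dta_block(8, seed = 15)
  x <- rand_fmap(8, 4, 4, seed = 16)
  expect_identical(dta_forward(x, blk), x)
})

test_that("dta_forward composes its branches with the gate weights", {
  blk <- dta_block(8, seed = 17)
  x <- rand_fmap(8, 2, 2, seed = 18)
  out <- dta_forward(x, blk, gamma1 = 0.5, gamma2 = 0.5)
  comp <- 0.5 * tsa_forward(x, blk$children$tsa) +
    0.5 * gsa_forward(x, blk$children$gsa) + x
  expect_lt(rel_err(out, comp), 1e-12)
  # gamma1 = 1, gamma2 = 0 on zero input reduces to TSA of zeros
  z <- array(0, dim = c(8, 2, 2))
  expect_equal(dta_forward(z, blk, gamma1 = 1, gamma2 = 0),
               tsa_forward(z, blk$children$tsa), tolerance = 1e-12)
})

test_that("every attention map row sums to one on random inputs", {
  tsa <- tsa_block(4, seed = 19)
  gsa <- gsa_block(8, seed = 20)
  for (s in 1:25) {
    xt <- rand_fmap(4, 3, 3, seed = 200 + s)
    for (A in tsa_attention(xt, tsa)) {
      expect_true(all(A >= 0))
      expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
    }
    xg <- rand_fmap(8, 3, 3, seed = 300 + s)
    for (A in gsa_attention(xg, gsa)) {
      expect_true(all(A >= 0))
      expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
    }
  }
})

test_that("tsa_forward is equivariant to spatial permutations", {
  blk <- tsa_block(4, seed = 21)
  x <- rand_fmap(4, 2, 3, seed = 22)
  n <- 6
  set.seed(23)
  perm <- sample(n)
  xf <- matrix(x, 4, n)
  xp <- array(xf[, perm], dim = c(4, 2, 3))
  out <- matrix(tsa_forward(x, blk), 4, n)
  outp <- matrix(tsa_forward(xp, blk), 4, n)
  expect_lt(max(abs(out[, perm] - outp)), 1e-10)
})

test_that("multi-head attention splits channels and preserves shape", {
  blk <- tsa_block(8, heads = 2L, seed = 24)
  x <- rand_fmap(8, 4, 4, seed = 25)
  out <- tsa_forward(x, blk)
  expect_equal(dim(out), c(8L, 4L, 4L))
  expect_equal(length(tsa_attention(x, blk)), 2L)
  expect_error(tsa_block(8, heads = 3L), "divide")
})
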