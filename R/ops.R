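# Differentiable tensor primitives.
#
# All feature maps are (C, H, W, B) arrays. Convolutions are computed as a
# sum of per-tap matrix products: for kernel tap (a, b) the padded input is
# shifted, flattened to a C x (H*W*B) matrix (free, since C is the fastest
# dimension) and multiplied by the (Cout x Cin) tap weight. This keeps every
# heavy operation inside BLAS.
#
# FLOP accounting convention (used by estimate_flops): a multiply-accumulate
# counts as 2 FLOPs; bias addition 1 per element; batch normalization 4 per
# element; ReLU 1; sigmoid 4; softmax 3 per matrix entry; attention matrix
# products as dense GEMMs at MACx2.

pad4d <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xp[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  xp
}

flat_sp <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  x
}

# 2-D convolution, stride 1, odd kernel k, "same" padding = dilation*(k-1)/2.
# w is a parameter node with value dim (Cout, Cin, k, k); bias optional node
# of length Cout.
t_conv2d <- function(x, w, bias = NULL, dilation = 1L) {
  xv <- nval(x)
  wv <- nval(w)
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  kd <- dim(wv)
  cout <- kd[1]; cin <- kd[2]; k <- kd[3]
  if (cin != C) stop("t_conv2d: channel mismatch (input ", C, ", weight ", cin, ")")
  N <- H * W * B
  y <- cpp_conv2d_fwd(xv, wv, as.integer(dilation))
  count_flops(2 * k * k * cin * cout * N)
  if (!is.null(bias)) {
    y <- y + as.numeric(nval(bias))  # recycles along the fastest (channel) dimension
    count_flops(cout * N)
    dim(y) <- c(cout, H, W, B)
  }
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x, w, bias), backward = function(nd) {
    dy <- nd$grad
    dim(dy) <- c(cout, H, W, B)
    gr <- cpp_conv2d_bwd(xv, wv, dy, as.integer(dilation))
    acc_grad(x, gr$dx)
    acc_grad(w, gr$dw)
    if (!is.null(bias)) {
      dim(dy) <- c(cout, N)
      acc_grad(bias, rowSums(dy))
    }
  })
}

# 1x1 convolution (per-pixel linear map).
t_conv1x1 <- function(x, w, bias = NULL) {
  xv <- nval(x)
  wv <- nval(w)  # (Cout, Cin) or (Cout, Cin, 1, 1)
  if (length(dim(wv)) == 4L) dim(wv) <- dim(wv)[1:2]
  d <- dim(xv)
  C <- d[1]; N <- prod(d[-1])
  if (ncol(wv) != C) stop("t_conv1x1: channel mismatch")
  cout <- nrow(wv)
  xm <- xv
  dim(xm) <- c(C, N)
  y <- wv %*% xm
  count_flops(2 * C * cout * N)
  if (!is.null(bias)) {
    y <- y + as.numeric(nval(bias))
    count_flops(cout * N)
  }
  dim(y) <- c(cout, d[2], d[3], d[4])
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x, w, bias), backward = function(nd) {
    dy <- nd$grad
    dim(dy) <- c(cout, N)
    dx <- crossprod(wv, dy)
    dim(dx) <- d
    acc_grad(x, dx)
    dw <- tcrossprod(dy, xm)
    if (length(dim(nval(w))) == 4L) dim(dw) <- dim(nval(w))
    acc_grad(w, dw)
    if (!is.null(bias)) acc_grad(bias, rowSums(dy))
  })
}

# Transposed convolution, 2x2 kernel, stride 2 (exact 2x upsampling).
# w value dim (Cout, Cin, 2, 2).
t_convT2x2 <- function(x, w, bias = NULL) {
  xv <- nval(x)
  wv <- nval(w)
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  cout <- dim(wv)[1]
  if (dim(wv)[2] != C) stop("t_convT2x2: channel mismatch")
  N <- H * W * B
  xm <- xv
  dim(xm) <- c(C, N)
  y <- array(0, dim = c(cout, 2 * H, 2 * W, B))
  for (a in 1:2) for (b in 1:2) {
    wt <- matrix(wv[, , a, b], cout, C)
    g <- wt %*% xm
    dim(g) <- c(cout, H, W, B)
    y[, seq.int(a, 2 * H, 2), seq.int(b, 2 * W, 2), ] <- g
  }
  count_flops(2 * 4 * C * cout * N)
  if (!is.null(bias)) {
    y <- y + as.numeric(nval(bias))
    count_flops(cout * length(y) / cout)
  }
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x, w, bias), backward = function(nd) {
    dyf <- nd$grad
    dx <- matrix(0, C, N)
    dw <- array(0, dim = dim(wv))
    for (a in 1:2) for (b in 1:2) {
      dys <- dyf[, seq.int(a, 2 * H, 2), seq.int(b, 2 * W, 2), , drop = FALSE]
      dim(dys) <- c(cout, N)
      wt <- matrix(wv[, , a, b], cout, C)
      dx <- dx + crossprod(wt, dys)
      dw[, , a, b] <- tcrossprod(dys, xm)
    }
    dim(dx) <- d
    acc_grad(x, dx)
    acc_grad(w, dw)
    if (!is.null(bias)) {
      dyb <- nd$grad
      dim(dyb) <- c(cout, length(dyb) / cout)
      acc_grad(bias, rowSums(dyb))
    }
  })
}

# 2x2 max pooling, stride 2. Ties route the gradient to the first slot in
# (1,1),(2,1),(1,2),(2,2) order.
t_maxpool2 <- function(x) {
  xv <- nval(x)
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  if (H %% 2L || W %% 2L) stop("t_maxpool2: spatial size must be even")
  io <- seq.int(1L, H, 2L); ie <- seq.int(2L, H, 2L)
  jo <- seq.int(1L, W, 2L); je <- seq.int(2L, W, 2L)
  s <- list(
    xv[, io, jo, , drop = FALSE], xv[, ie, jo, , drop = FALSE],
    xv[, io, je, , drop = FALSE], xv[, ie, je, , drop = FALSE]
  )
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  count_flops(3 * length(m))
  if (!is.null(dim(m))) dim(m) <- c(C, H / 2, W / 2, B) else dim(m) <- c(C, H / 2, W / 2, B)
  if (!recording()) return(ad_node(m))
  taken <- array(FALSE, dim = dim(m))
  masks <- vector("list", 4L)
  for (q in 1:4) {
    mk <- (s[[q]] == m) & !taken
    taken <- taken | mk
    masks[[q]] <- mk
  }
  ad_node(m, parents = list(x), backward = function(nd) {
    dy <- nd$grad
    dx <- array(0, dim = d)
    dx[, io, jo, ] <- dy * masks[[1]]
    dx[, ie, jo, ] <- dy * masks[[2]]
    dx[, io, je, ] <- dy * masks[[3]]
    dx[, ie, je, ] <- dy * masks[[4]]
    acc_grad(x, dx)
  })
}

# Average pooling with integer factor f.
t_avgpool <- function(x, f) {
  if (f == 1L) return(if (inherits(x, "ad_node")) x else ad_node(x))
  xv <- nval(x)
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  Ho <- H %/% f; Wo <- W %/% f
  y <- array(0, dim = c(C, Ho, Wo, B))
  for (a in seq_len(f)) for (b in seq_len(f)) {
    y <- y + xv[, seq.int(a, H, f), seq.int(b, W, f), , drop = FALSE]
  }
  y <- y / (f * f)
  count_flops((f * f + 1) * length(y))
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x), backward = function(nd) {
    dy <- nd$grad / (f * f)
    dx <- array(0, dim = d)
    for (a in seq_len(f)) for (b in seq_len(f)) {
      dx[, seq.int(a, H, f), seq.int(b, W, f), ] <- dy
    }
    acc_grad(x, dx)
  })
}

# Nearest-neighbour upsampling by integer factor f.
t_upsample_nn <- function(x, f) {
  if (f == 1L) return(if (inherits(x, "ad_node")) x else ad_node(x))
  xv <- nval(x)
  d <- dim(xv)
  H <- d[2]; W <- d[3]
  y <- xv[, rep(seq_len(H), each = f), rep(seq_len(W), each = f), , drop = FALSE]
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x), backward = function(nd) {
    dy <- nd$grad
    dx <- array(0, dim = d)
    Hf <- H * f; Wf <- W * f
    for (a in seq_len(f)) for (b in seq_len(f)) {
      dx <- dx + dy[, seq.int(a, Hf, f), seq.int(b, Wf, f), , drop = FALSE]
    }
    acc_grad(x, dx)
  })
}

# Batch normalization over (H, W, B) per channel. state is an environment
# with running $mean and $var; biased batch variance is used both for
# normalization and for the running average.
t_bn <- function(x, gamma, beta, state, training = FALSE, eps = 1e-5,
                 momentum = .ad$bn_momentum %||% 0.1) {
  xv <- nval(x)
  d <- dim(xv)
  C <- d[1]; N <- prod(d[-1])
  if (training) {
    st <- cpp_bn_stats(xv, C)
    mu <- st$mean
    v <- st$var
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  gv <- as.numeric(nval(gamma)); bv <- as.numeric(nval(beta))
  rec <- recording()
  ap <- cpp_bn_apply(xv, mu, inv, gv, bv, rec && training)
  y <- ap$y
  count_flops(4 * C * N)
  if (!rec) return(ad_node(y))
  xhat <- ap$xhat
  ad_node(y, parents = list(x, gamma, beta), backward = function(nd) {
    dy <- nd$grad
    if (training) {
      gr <- cpp_bn_bwd(dy, xhat, gv, inv)
      acc_grad(x, gr$dx)
      acc_grad(gamma, gr$dgamma)
      acc_grad(beta, gr$dbeta)
    } else {
      dim(dy) <- c(C, N)
      acc_grad(gamma, rowSums(dy * array(xhat_eval(xv, mu, inv), dim = c(C, N))))
      acc_grad(beta, rowSums(dy))
      acc_grad(x, cpp_bn_bwd_eval(nd$grad, gv, inv))
    }
  })
}

xhat_eval <- function(xv, mu, inv) {
  d <- dim(xv)
  xm <- xv
  dim(xm) <- c(d[1], prod(d[-1]))
  (xm - mu) * inv
}

t_relu <- function(x) {
  xv <- nval(x)
  y <- cpp_relu_fwd(xv)
  count_flops(length(y))
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x), backward = function(nd) {
    acc_grad(x, cpp_relu_bwd(nd$grad, xv))
  })
}

t_sigmoid <- function(x) {
  xv <- nval(x)
  y <- 1 / (1 + exp(-xv))
  count_flops(4 * length(y))
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x), backward = function(nd) {
    acc_grad(x, nd$grad * y * (1 - y))
  })
}

t_add <- function(x, y) {
  out <- nval(x) + nval(y)
  count_flops(length(out))
  if (!recording()) return(ad_node(out))
  ad_node(out, parents = list(x, y), backward = function(nd) {
    acc_grad(x, nd$grad)
    acc_grad(y, nd$grad)
  })
}

# Multiply a tensor by a trainable scalar gate.
t_scalar_gate <- function(x, s) {
  xv <- nval(x)
  sv <- as.numeric(nval(s))
  y <- sv * xv
  count_flops(length(y))
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x, s), backward = function(nd) {
    acc_grad(x, sv * nd$grad)
    acc_grad(s, sum(nd$grad * xv))
  })
}

# Per-channel gate g of shape (C, B) applied to x of shape (C, H, W, B).
t_chmul <- function(x, g) {
  xv <- nval(x)
  gv <- nval(g)
  d <- dim(xv)
  HW <- d[2] * d[3]
  y <- cpp_chmul(xv, as.matrix(gv), as.integer(HW))
  count_flops(length(y))
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x, g), backward = function(nd) {
    gr <- cpp_chmul_bwd(nd$grad, xv, as.matrix(gv), as.integer(HW))
    acc_grad(x, gr$dx)
    acc_grad(g, gr$dg)
  })
}

# Spatial mean -> (C, B) descriptor.
t_spatial_mean <- function(x) {
  xv <- nval(x)
  d <- dim(xv)
  C <- d[1]; HW <- d[2] * d[3]; B <- d[4]
  xm <- xv
  dim(xm) <- c(C, HW, B)
  y <- matrix(0, C, B)
  for (b in seq_len(B)) y[, b] <- rowMeans(xm[, , b, drop = FALSE])
  count_flops(length(xv))
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x), backward = function(nd) {
    dy <- nd$grad / HW
    dx <- array(0, dim = d)
    dxm <- dx
    dim(dxm) <- c(C, HW, B)
    for (b in seq_len(B)) dxm[, , b] <- dy[, b]
    dim(dxm) <- d
    acc_grad(x, dxm)
  })
}

# Linear map on a (C, B) descriptor: y = W x (+ bias).
t_linear <- function(x, w, bias = NULL) {
  xv <- nval(x)
  wv <- nval(w)
  y <- wv %*% xv
  count_flops(2 * length(wv) * ncol(xv))
  if (!is.null(bias)) y <- y + as.numeric(nval(bias))
  if (!recording()) return(ad_node(y))
  ad_node(y, parents = list(x, w, bias), backward = function(nd) {
    dy <- nd$grad
    acc_grad(x, crossprod(wv, dy))
    acc_grad(w, tcrossprod(dy, xv))
    if (!is.null(bias)) acc_grad(bias, rowSums(dy))
  })
}

# Concatenate along the channel dimension.
t_concat_ch <- function(x, y) {
  xv <- nval(x); yv <- nval(y)
  dx <- dim(xv); dy2 <- dim(yv)
  out <- array(0, dim = c(dx[1] + dy2[1], dx[2], dx[3], dx[4]))
  out[seq_len(dx[1]), , , ] <- xv
  out[dx[1] + seq_len(dy2[1]), , , ] <- yv
  if (!recording()) return(ad_node(out))
  ad_node(out, parents = list(x, y), backward = function(nd) {
    g <- nd$grad
    acc_grad(x, g[seq_len(dx[1]), , , , drop = FALSE])
    acc_grad(y, g[dx[1] + seq_len(dy2[1]), , , , drop = FALSE])
  })
}

softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# Scaled dot-product attention. Q (cq, nq, B), K (cq, nk, B), V (cv, nk, B).
# Logits S = t(Q) K / scale, row-softmax over the key axis, output
# O[, i, b] = sum_j A[i, j] V[, j, b], i.e. O_b = V_b t(A_b).
# Returns list(out, attn) where attn is the list of per-sample maps.
t_attn <- function(Q, K, V, scale = 1, keep_attn = FALSE) {
  qv <- nval(Q); kv <- nval(K); vv <- nval(V)
  dq <- dim(qv); dk2 <- dim(kv); dv <- dim(vv)
  cq <- dq[1]; nq <- dq[2]; B <- dq[3]
  nk <- dk2[2]; cv <- dv[1]
  out <- array(0, dim = c(cv, nq, B))
  A_list <- vector("list", B)
  for (b in seq_len(B)) {
    S <- crossprod(as_mat(qv[, , b], cq, nq), as_mat(kv[, , b], cq, nk)) / scale
    A <- softmax_rows(S)
    A_list[[b]] <- A
    out[, , b] <- as_mat(vv[, , b], cv, nk) %*% t(A)
  }
  count_flops(B * (2 * cq * nq * nk + 3 * nq * nk + 2 * cv * nq * nk))
  nd <- if (!recording()) {
    ad_node(out)
  } else {
    ad_node(out, parents = list(Q, K, V), backward = function(nd) {
      dOut <- nd$grad
      dQ <- array(0, dim = dq); dK <- array(0, dim = dk2); dV <- array(0, dim = dv)
      for (b in seq_len(B)) {
        A <- A_list[[b]]
        dO <- as_mat(dOut[, , b], cv, nq)
        Vb <- as_mat(vv[, , b], cv, nk)
        dV[, , b] <- dO %*% A
        dA <- crossprod(dO, Vb)              # nq x nk
        dS <- A * (dA - rowSums(dA * A))     # softmax backward, per row
        dS <- dS / scale
        dQ[, , b] <- as_mat(kv[, , b], cq, nk) %*% t(dS)
        dK[, , b] <- as_mat(qv[, , b], cq, nq) %*% dS
      }
      acc_grad(Q, dQ)
      acc_grad(K, dK)
      acc_grad(V, dV)
    })
  }
  if (keep_attn) list(out = nd, attn = A_list) else nd
}

as_mat <- function(x, r, co) {
  dim(x) <- c(r, co)
  x
}

# Free reshape between (C, H, W, B) and (C, n, B) views.
t_reshape <- function(x, newdim) {
  xv <- nval(x)
  olddim <- dim(xv)
  dim(xv) <- newdim
  if (!recording()) return(ad_node(xv))
  ad_node(xv, parents = list(x), backward = function(nd) {
    g <- nd$grad
    dim(g) <- olddim
    acc_grad(x, g)
  })
}

# Balanced binary cross-entropy from logits, numerically stable.
# loss = mean_p [ w_p * gt_p * softplus(-z_p) + (1 - gt_p) * softplus(z_p) ]
# with w_p = pos_weight on foreground pixels (1 when pos_weight is NULL).
t_bce_logits <- function(z, gt, pos_weight = NULL) {
  zv <- nval(z)
  n <- length(zv)
  g <- as.numeric(gt)
  w <- if (is.null(pos_weight)) 1 else pos_weight
  sp_pos <- log1p(exp(-abs(zv))) + pmax(-zv, 0)  # softplus(-z)
  sp_neg <- log1p(exp(-abs(zv))) + pmax(zv, 0)   # softplus(z)
  loss <- sum(w * g * sp_pos + (1 - g) * sp_neg) / n
  if (!recording()) return(ad_node(loss))
  ad_node(loss, parents = list(z), backward = function(nd) {
    s <- 1 / (1 + exp(-zv))
    dz <- (-w * g * (1 - s) + (1 - g) * s) * (nd$grad / n)
    dim(dz) <- dim(zv)
    acc_grad(z, dz)
  })
}
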