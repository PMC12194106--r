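# Module system: a module is a list with $params (named parameter nodes),
# $buffers (environments holding non-trainable state such as BN running
# statistics), $children (named sub-modules) and $forward. Parameters are
# created as zeros and filled in by init_weights(); each parameter node
# carries its initialization rule ("kaiming", "zero", "one") and fan-in.

new_module <- function(forward, params = list(), children = list(), buffers = list(),
                       meta = list()) {
  m <- list(forward = forward, params = params, children = children,
            buffers = buffers, meta = meta)
  class(m) <- "catu_module"
  m
}

conv_param <- function(cout, cin, k) {
  ad_param(c(cout, cin, k, k), init = "kaiming", fan_in = cin * k * k)
}

bn_state <- function(C) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(C)
  st$var <- rep(1, C)
  st
}

# Conv(k x k, dilated) -> optional BN -> optional ReLU.
mod_conv <- function(cin, cout, k = 3L, dilation = 1L, bn = TRUE,
                     act = c("none", "relu"), bias = !bn) {
  act <- match.arg(act)
  params <- list(weight = conv_param(cout, cin, k))
  if (bias) params$bias <- ad_param(cout, init = "zero")
  buffers <- list()
  if (bn) {
    params$gamma <- ad_param(cout, init = "one")
    params$beta <- ad_param(cout, init = "zero")
    buffers$bn <- bn_state(cout)
  }
  fwd <- function(self, x, training = FALSE) {
    h <- if (k == 1L) {
      t_conv1x1(x, self$params$weight, self$params$bias)
    } else {
      t_conv2d(x, self$params$weight, self$params$bias, dilation = dilation)
    }
    if (bn) h <- t_bn(h, self$params$gamma, self$params$beta, self$buffers$bn, training)
    if (act == "relu") h <- t_relu(h)
    h
  }
  new_module(fwd, params, buffers = buffers,
             meta = list(kind = "conv", cin = cin, cout = cout, k = k, dilation = dilation))
}

run_mod <- function(m, x, training = FALSE) m$forward(m, x, training)

# Residual Dilated Inception block: four parallel dilated 3x3 conv+BN
# branches, channel concatenation, 1x1 conv+BN fusion, plus (optionally)
# a 1x1 conv+BN residual projection of the input, then ReLU.
mod_rdi <- function(cin, cout, rates = c(1L, 3L, 5L, 7L), residual = TRUE) {
  if (cout %% 4L != 0L) stop("RDI block: out_channels must be divisible by 4")
  bch <- cout %/% 4L
  branches <- lapply(rates, function(r) mod_conv(cin, bch, k = 3L, dilation = r, bn = TRUE))
  names(branches) <- paste0("branch", seq_along(rates))
  fuse <- mod_conv(cout, cout, k = 1L, bn = TRUE)
  children <- c(branches, list(fuse = fuse))
  if (residual) children$shortcut <- mod_conv(cin, cout, k = 1L, bn = TRUE)
  fwd <- function(self, x, training = FALSE) {
    bs <- lapply(seq_along(rates), function(i)
      run_mod(self$children[[paste0("branch", i)]], x, training))
    h <- bs[[1]]
    for (i in 2:length(bs)) h <- t_concat_ch(h, bs[[i]])
    h <- run_mod(self$children$fuse, h, training)
    if (residual) h <- t_add(h, run_mod(self$children$shortcut, x, training))
    t_relu(h)
  }
  new_module(fwd, children = children,
             meta = list(kind = "rdi", cin = cin, cout = cout, rates = rates,
                         residual = residual, branch_channels = bch))
}

# Plain double 3x3 conv stage (U-Net baseline encoder block).
mod_double_conv <- function(cin, cout) {
  c1 <- mod_conv(cin, cout, k = 3L, bn = TRUE, act = "relu")
  c2 <- mod_conv(cout, cout, k = 3L, bn = TRUE, act = "relu")
  fwd <- function(self, x, training = FALSE) {
    run_mod(self$children$c2, run_mod(self$children$c1, x, training), training)
  }
  new_module(fwd, children = list(c1 = c1, c2 = c2),
             meta = list(kind = "double_conv", cin = cin, cout = cout))
}

encoder_stage <- function(variant, cin, cout, rates) {
  switch(variant,
    RDI = mod_rdi(cin, cout, rates, residual = TRUE),
    dilated_inception = mod_rdi(cin, cout, rates, residual = FALSE),
    inception = mod_rdi(cin, cout, rep(1L, length(rates)), residual = FALSE),
    plain_conv = mod_double_conv(cin, cout),
    stop("unknown encoder_variant: ", variant)
  )
}

# Transformer self-attention: 1x1-conv Q/K/V projections over the flattened
# spatial positions, scaled dot-product with row softmax, reshaped back.
mod_tsa <- function(channels, heads = 1L, scale = c("sqrt", "linear")) {
  scale <- match.arg(scale)
  if (channels %% heads != 0L) stop("TSA: heads must divide channels")
  params <- list(
    wq = ad_param(c(channels, channels), init = "kaiming", fan_in = channels),
    wk = ad_param(c(channels, channels), init = "kaiming", fan_in = channels),
    wv = ad_param(c(channels, channels), init = "kaiming", fan_in = channels)
  )
  fwd <- function(self, x, training = FALSE) {
    d <- dim(nval(x))
    C <- d[1]; n <- d[2] * d[3]; B <- d[4]
    Q <- t_reshape(t_conv1x1(x, self$params$wq), c(C, n, B))
    K <- t_reshape(t_conv1x1(x, self$params$wk), c(C, n, B))
    V <- t_reshape(t_conv1x1(x, self$params$wv), c(C, n, B))
    ch <- C %/% heads
    outs <- vector("list", heads)
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * ch + 1L):(h * ch)
      qs <- t_slice_ch3(Q, idx); ks <- t_slice_ch3(K, idx); vs <- t_slice_ch3(V, idx)
      dk <- ch
      sc <- if (scale == "sqrt") sqrt(dk) else dk
      outs[[h]] <- t_attn(qs, ks, vs, scale = sc)
    }
    o <- outs[[1]]
    if (heads > 1L) for (h in 2:heads) o <- t_concat3(o, outs[[h]])
    t_reshape(o, d)
  }
  new_module(fwd, params, meta = list(kind = "tsa", channels = channels, heads = heads,
                                      scale = scale))
}

# Channel slice / concat on (C, n, B) tensors (used for attention heads).
t_slice_ch3 <- function(x, idx) {
  xv <- nval(x)
  y <- xv[idx, , , drop = FALSE]
  if (!recording()) return(ad_node(y))
  d <- dim(xv)
  ad_node(y, parents = list(x), backward = function(nd) {
    g <- array(0, dim = d)
    g[idx, , ] <- nd$grad
    acc_grad(x, g)
  })
}

t_concat3 <- function(x, y) {
  xv <- nval(x); yv <- nval(y)
  dx <- dim(xv); dy2 <- dim(yv)
  out <- array(0, dim = c(dx[1] + dy2[1], dx[2], dx[3]))
  out[seq_len(dx[1]), , ] <- xv
  out[dx[1] + seq_len(dy2[1]), , ] <- yv
  if (!recording()) return(ad_node(out))
  ad_node(out, parents = list(x, y), backward = function(nd) {
    g <- nd$grad
    acc_grad(x, g[seq_len(dx[1]), , , drop = FALSE])
    acc_grad(y, g[dx[1] + seq_len(dy2[1]), , , drop = FALSE])
  })
}

# Global spatial (position) attention: one c -> c/r reduction conv whose
# flattened form gives Map1 (and its transpose Map2), one c -> c value conv;
# position map = row softmax of Map1^T Map1 (no scaling divisor), applied to
# the value branch.
mod_gsa <- function(channels, reduction = 8L) {
  if (channels %% reduction != 0L)
    stop("GSA: reduction (", reduction, ") must divide channels (", channels, ")")
  cr <- channels %/% reduction
  params <- list(
    w_reduce = ad_param(c(cr, channels), init = "kaiming", fan_in = channels),
    w_value = ad_param(c(channels, channels), init = "kaiming", fan_in = channels)
  )
  fwd <- function(self, x, training = FALSE) {
    d <- dim(nval(x))
    C <- d[1]; n <- d[2] * d[3]; B <- d[4]
    red <- t_reshape(t_conv1x1(x, self$params$w_reduce), c(cr, n, B))
    val <- t_reshape(t_conv1x1(x, self$params$w_value), c(C, n, B))
    o <- t_attn(red, red, val, scale = 1)
    t_reshape(o, d)
  }
  new_module(fwd, params, meta = list(kind = "gsa", channels = channels, reduction = reduction))
}

# Dual Transformer-attention: gated residual fusion of the TSA and GSA
# branches, F_out = gamma1 * TSA(F) + gamma2 * GSA(F) + F, gates start at 0.
mod_dta <- function(channels, heads = 1L, reduction = 8L, scale = "sqrt",
                    use_tsa = TRUE, use_gsa = TRUE) {
  children <- list()
  params <- list()
  if (use_tsa) {
    children$tsa <- mod_tsa(channels, heads, scale)
    params$gamma1 <- ad_param(1L, init = "zero")
  }
  if (use_gsa) {
    children$gsa <- mod_gsa(channels, reduction)
    params$gamma2 <- ad_param(1L, init = "zero")
  }
  fwd <- function(self, x, training = FALSE) {
    out <- x
    if (!inherits(out, "ad_node")) out <- ad_node(out)
    if (use_tsa) {
      ft <- run_mod(self$children$tsa, x, training)
      out <- t_add(t_scalar_gate(ft, self$params$gamma1), out)
    }
    if (use_gsa) {
      fg <- run_mod(self$children$gsa, x, training)
      out <- t_add(t_scalar_gate(fg, self$params$gamma2), out)
    }
    out
  }
  new_module(fwd, params, children,
             meta = list(kind = "dta", channels = channels, use_tsa = use_tsa,
                         use_gsa = use_gsa))
}

# Atrous spatial pyramid pooling substitute for the bottleneck: four dilated
# 3x3 conv+BN branches at the same rates, concatenated and fused by 1x1
# conv+BN+ReLU back to the input width.
mod_aspp <- function(channels, rates = c(1L, 3L, 5L, 7L)) {
  if (channels %% 4L != 0L) stop("ASPP: channels must be divisible by 4")
  bch <- channels %/% 4L
  branches <- lapply(rates, function(r) mod_conv(channels, bch, k = 3L, dilation = r, bn = TRUE))
  names(branches) <- paste0("branch", seq_along(rates))
  fuse <- mod_conv(channels, channels, k = 1L, bn = TRUE, act = "relu")
  fwd <- function(self, x, training = FALSE) {
    bs <- lapply(seq_along(rates), function(i)
      run_mod(self$children[[paste0("branch", i)]], x, training))
    h <- bs[[1]]
    for (i in 2:length(bs)) h <- t_concat_ch(h, bs[[i]])
    run_mod(self$children$fuse, h, training)
  }
  new_module(fwd, children = c(branches, list(fuse = fuse)),
             meta = list(kind = "aspp", channels = channels, rates = rates))
}

bottleneck_module <- function(variant, channels, heads, reduction, scale, rates) {
  switch(variant,
    DTA = mod_dta(channels, heads, reduction, scale),
    TSA_only = mod_dta(channels, heads, reduction, scale, use_gsa = FALSE),
    GSA_only = mod_dta(channels, heads, reduction, scale, use_tsa = FALSE),
    ASPP = mod_aspp(channels, rates),
    none = new_module(function(self, x, training = FALSE)
      if (inherits(x, "ad_node")) x else ad_node(x),
      meta = list(kind = "identity")),
    stop("unknown bottleneck_variant: ", variant)
  )
}

# Channel-selection gate: per-channel spatial mean descriptor, linear map,
# sigmoid, broadcast-multiplied back onto the features.
mod_channel_select <- function(channels) {
  params <- list(w = ad_param(c(channels, channels), init = "kaiming", fan_in = channels))
  fwd <- function(self, x, training = FALSE) {
    g <- t_sigmoid(t_linear(t_spatial_mean(x), self$params$w))
    t_chmul(x, g)
  }
  new_module(fwd, params, meta = list(kind = "channel_select", channels = channels))
}

# Cross-attention skip connection. Queries come from the (gated) decoder
# map, keys/values from the (gated) encoder skip; attention runs on a pooled
# grid of at most `grid` cells per side for memory feasibility, and the
# attended low-level features are upsampled back before concatenation with
# the high-level map and 1x1 fusion to the stage width.
mod_casc <- function(channels, grid = 32L, scale = c("sqrt", "linear")) {
  scale <- match.arg(scale)
  children <- list(
    select_low = mod_channel_select(channels),
    select_high = mod_channel_select(channels),
    fuse = mod_conv(2L * channels, channels, k = 1L, bn = TRUE, act = "relu")
  )
  params <- list(
    wq = ad_param(c(channels, channels), init = "kaiming", fan_in = channels),
    wk = ad_param(c(channels, channels), init = "kaiming", fan_in = channels),
    wv = ad_param(c(channels, channels), init = "kaiming", fan_in = channels)
  )
  fwd <- function(self, low, high, training = FALSE) {
    dl <- dim(nval(low)); dh <- dim(nval(high))
    if (!all(dl == dh))
      stop("casc_forward: low/high feature maps must share shape after up-sampling")
    C <- dl[1]; H <- dl[2]; B <- dl[4]
    lo <- run_mod(self$children$select_low, low, training)
    hi <- run_mod(self$children$select_high, high, training)
    f <- pool_factor(H, grid)
    lo_p <- t_avgpool(lo, f)
    hi_p <- t_avgpool(hi, f)
    hg <- H %/% f
    n <- hg * hg
    Q <- t_reshape(t_conv1x1(hi_p, self$params$wq), c(C, n, B))
    K <- t_reshape(t_conv1x1(lo_p, self$params$wk), c(C, n, B))
    V <- t_reshape(t_conv1x1(lo_p, self$params$wv), c(C, n, B))
    sc <- if (scale == "sqrt") sqrt(C) else C
    att <- t_attn(Q, K, V, scale = sc)
    att <- t_reshape(att, c(C, hg, hg, B))
    att <- t_upsample_nn(att, f)
    run_mod(self$children$fuse, t_concat_ch(att, hi), training)
  }
  new_module(fwd, params, children,
             meta = list(kind = "casc", channels = channels, grid = grid))
}

# Pooling factor for the CASC attention grid: the largest divisor of H not
# exceeding H / grid, so the pooled resolution is exact and close to `grid`.
pool_factor <- function(H, grid) {
  f <- max(1L, H %/% grid)
  while (f > 1L && H %% f != 0L) f <- f - 1L
  f
}

# Plain U-Net skip: concatenate and fuse to the stage width.
mod_plain_skip <- function(channels) {
  fuse <- mod_conv(2L * channels, channels, k = 1L, bn = TRUE, act = "relu")
  fwd <- function(self, low, high, training = FALSE) {
    run_mod(self$children$fuse, t_concat_ch(low, high), training)
  }
  new_module(fwd, children = list(fuse = fuse),
             meta = list(kind = "plain_skip", channels = channels))
}

# Decoder stage: 2x up-sampling (transposed 2x2 conv, or bilinear-style
# nearest + 1x1 projection) followed, after skip fusion, by a residual pair
# of 3x3 conv+BN(+ReLU) layers.
mod_upsample_stage <- function(cin, cout, mode = c("deconv", "bilinear")) {
  mode <- match.arg(mode)
  if (mode == "deconv") {
    params <- list(weight = ad_param(c(cout, cin, 2L, 2L), init = "kaiming", fan_in = cin * 4L),
                   bias = ad_param(cout, init = "zero"))
    fwd <- function(self, x, training = FALSE)
      t_convT2x2(x, self$params$weight, self$params$bias)
    new_module(fwd, params, meta = list(kind = "deconv", cin = cin, cout = cout))
  } else {
    proj <- mod_conv(cin, cout, k = 1L, bn = FALSE, bias = TRUE)
    fwd <- function(self, x, training = FALSE)
      run_mod(self$children$proj, t_upsample_nn(x, 2L), training)
    new_module(fwd, children = list(proj = proj),
               meta = list(kind = "upsample_proj", cin = cin, cout = cout))
  }
}

mod_residual_pair <- function(channels) {
  c1 <- mod_conv(channels, channels, k = 3L, bn = TRUE, act = "relu")
  c2 <- mod_conv(channels, channels, k = 3L, bn = TRUE, act = "none")
  fwd <- function(self, x, training = FALSE) {
    if (!inherits(x, "ad_node")) x <- ad_node(x)
    h <- run_mod(self$children$c1, x, training)
    h <- run_mod(self$children$c2, h, training)
    t_relu(t_add(h, x))
  }
  new_module(fwd, children = list(c1 = c1, c2 = c2),
             meta = list(kind = "residual_pair", channels = channels))
}

# 1x1 prediction head (sigmoid applied by the model forward).
mod_head <- function(cin) {
  mod_conv(cin, 1L, k = 1L, bn = FALSE, bias = TRUE)
}

# ---- parameter bookkeeping -------------------------------------------------

collect_params <- function(module, prefix = "") {
  out <- list()
  for (nm in names(module$params)) {
    out[[paste0(prefix, nm)]] <- module$params[[nm]]
  }
  for (nm in names(module$children)) {
    out <- c(out, collect_params(module$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

collect_buffers <- function(module, prefix = "") {
  out <- list()
  for (nm in names(module$buffers)) {
    out[[paste0(prefix, nm)]] <- module$buffers[[nm]]
  }
  for (nm in names(module$children)) {
    out <- c(out, collect_buffers(module$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}
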