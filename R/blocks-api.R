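# Functional block-level interface. Each constructor builds a standalone,
# seeded block; each *_forward runs it in evaluation mode on a plain
# channel-first array (C, H, W) or batch (C, H, W, B) and returns an array.
# These are the units the test oracles exercise; the assembled model uses
# the same modules internally.

as_fmap <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("feature map must be a (C, H, W) or (C, H, W, B) array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

run_block <- function(block, x, training = FALSE) {
  xin <- as_fmap(x)
  out <- nval(run_mod(block, xin, training))
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

seed_block <- function(block, seed) {
  if (!is.null(seed)) {
    ps <- collect_params(block)
    with_seed(seed, for (p in ps) {
      d <- dim(p$value) %||% length(p$value)
      p$value <- switch(p$init,
        kaiming = array(stats::rnorm(prod(d), sd = sqrt(2 / p$fan_in)), dim = d),
        zero = array(0, dim = d),
        one = array(1, dim = d))
    })
  }
  block
}

#' Residual dilated Inception (RDI) block
#'
#' Four parallel dilated 3x3 convolution branches (each Conv+BN) with
#' "same" padding equal to the dilation rate, concatenated and fused by a
#' 1x1 Conv+BN, added to a 1x1 Conv+BN residual projection of the input,
#' then ReLU.
#'
#' @param in_channels,out_channels Block input/output widths
#'   (`out_channels` divisible by 4; each branch carries
#'   `out_channels / 4` channels).
#' @param dilation_rates Four dilation rates.
#' @param residual Keep the residual projection (FALSE gives the plain
#'   Inception ablation variant).
#' @param seed Optional seed for the block weights.
#' @return A block usable with [dri_block_forward()].
#' @export
dri_block <- function(in_channels, out_channels, dilation_rates = c(1L, 3L, 5L, 7L),
                      residual = TRUE, seed = NULL) {
  seed_block(mod_rdi(in_channels, out_channels, as.integer(dilation_rates), residual), seed)
}

#' @rdname dri_block
#' @param x Feature map array `(C, H, W)` or `(C, H, W, B)`.
#' @param block A block built by [dri_block()].
#' @param training Use batch statistics in BN layers.
#' @export
dri_block_forward <- function(x, block, training = FALSE) run_block(block, x, training)

#' Run the four-stage encoder of a model
#'
#' @param model A `catu_model`.
#' @param image Channel-first image array (spatial size divisible by 16).
#' @return A list with `skips` (stage outputs before pooling) and
#'   `deepest` (the pooled stage-4 output handed to the bottleneck).
#' @export
encoder_forward <- function(model, image) {
  x <- as_fmap(image)
  d <- dim(x)
  if (d[2] %% 16L != 0L || d[3] %% 16L != 0L)
    stop("encoder_forward: spatial size must be divisible by 16")
  skips <- vector("list", 4L)
  h <- x
  for (i in 1:4) {
    h <- run_mod(model$blocks[[paste0("encoder", i)]], h, FALSE)
    skips[[i]] <- nval(h)
    h <- t_maxpool2(h)
  }
  list(skips = skips, deepest = nval(h))
}

#' Transformer self-attention (TSA) block
#'
#' Scaled dot-product self-attention over spatial positions: 1x1-conv
#' Q/K/V projections of the flattened feature map, row-softmax of
#' `Q^T K / sqrt(d_k)` (or `/ d_k` with `scale = "linear"`), applied to V
#' and reshaped back.
#'
#' @param channels Feature width c.
#' @param heads Number of attention heads (must divide `channels`).
#' @param scale `"sqrt"` or `"linear"` logit scaling.
#' @param seed Optional seed.
#' @export
tsa_block <- function(channels, heads = 1L, scale = c("sqrt", "linear"), seed = NULL) {
  seed_block(mod_tsa(channels, heads, match.arg(scale)), seed)
}

#' @rdname tsa_block
#' @param x Feature map `(C, H, W)` or `(C, H, W, B)`.
#' @param block A `tsa_block()`.
#' @export
tsa_forward <- function(x, block) run_block(block, x)

#' Q/K/V projection of a feature map
#'
#' Flattens the spatial dimensions and applies the block's linear
#' projections, returning the three `c x (h*w)` matrices.
#'
#' @param x Feature map `(C, H, W)`.
#' @param block A `tsa_block()`.
#' @return List with `Q`, `K`, `V` matrices and `dk`.
#' @export
project_qkv <- function(x, block) {
  xin <- as_fmap(x)
  d <- dim(xin)
  n <- d[2] * d[3]
  fl <- function(w) {
    m <- nval(t_conv1x1(xin, w))
    dim(m) <- c(d[1], n)
    m
  }
  list(Q = fl(block$params$wq), K = fl(block$params$wk), V = fl(block$params$wv),
       dk = d[1] %/% block$meta$heads)
}

#' Global spatial attention (GSA) block
#'
#' Position attention with channel reduction: a 1x1 convolution reduces the
#' input to `c / reduction` channels giving `Map1` (its transpose is
#' `Map2`), a second 1x1 convolution gives the full-width value branch; the
#' row-softmax position map aggregates the value branch at every position.
#'
#' @param channels Feature width (divisible by `reduction`).
#' @param reduction Channel reduction factor (default 8, so c' = c/8).
#' @param seed Optional seed.
#' @export
gsa_block <- function(channels, reduction = 8L, seed = NULL) {
  seed_block(mod_gsa(channels, reduction), seed)
}

#' @rdname gsa_block
#' @param x Feature map `(C, H, W)` or `(C, H, W, B)`.
#' @param block A `gsa_block()`.
#' @export
gsa_forward <- function(x, block) run_block(block, x)

#' Position attention map
#'
#' Row-softmax of the pairwise position logits `Map1 %*% Map2`: entry
#' (i, j) is the weight of position j on position i, and every row sums
#' to 1.
#'
#' @param map1 `n x c'` matrix of reduced position features.
#' @param map2 `c' x n` matrix (typically `t(map1)`).
#' @return An `n x n` row-stochastic matrix.
#' @export
gsa_position_map <- function(map1, map2) {
  softmax_rows(map1 %*% map2)
}

#' Dual Transformer-attention (DTA) block
#'
#' Gated residual fusion of the TSA and GSA branches:
#' `F_out = gamma1 * TSA(F) + gamma2 * GSA(F) + F`. Both gates are learned
#' scalars initialized to 0, so at initialization the block is an exact
#' identity.
#'
#' @param channels Feature width.
#' @param heads Attention heads for the TSA branch.
#' @param reduction GSA channel reduction.
#' @param scale Attention logit scaling.
#' @param seed Optional seed.
#' @export
dta_block <- function(channels, heads = 1L, reduction = 8L,
                      scale = c("sqrt", "linear"), seed = NULL) {
  seed_block(mod_dta(channels, heads, reduction, match.arg(scale)), seed)
}

#' @rdname dta_block
#' @param x Feature map `(C, H, W)` or `(C, H, W, B)`.
#' @param block A `dta_block()`.
#' @param gamma1,gamma2 Optional gate overrides (scalars).
#' @export
dta_forward <- function(x, block, gamma1 = NULL, gamma2 = NULL) {
  if (!is.null(gamma1)) block$params$gamma1$value <- array(gamma1, 1L)
  if (!is.null(gamma2)) block$params$gamma2$value <- array(gamma2, 1L)
  run_block(block, x)
}

#' Channel selection gate
#'
#' Per-channel spatial mean descriptor `P`, gate `A = sigmoid(W P)` in
#' (0, 1), output `A * F` broadcast over the spatial dimensions.
#'
#' @param x Feature map `(C, H, W)`.
#' @param W A `c x c` weight matrix.
#' @return The gated feature map, same shape as `x`.
#' @export
channel_select <- function(x, W) {
  xin <- as_fmap(x)
  d <- dim(xin)
  g <- nval(t_sigmoid(t_linear(t_spatial_mean(xin), ad_node(W))))
  out <- nval(t_chmul(xin, ad_node(g)))
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

#' Cross-attention skip connection (CASC) block
#'
#' Fuses a low-level encoder map with the same-resolution decoder map:
#' both are channel-gated, the decoder map provides queries and the encoder
#' map keys/values; the row-stochastic cross-attention map aggregates the
#' encoder values, which are concatenated with the decoder map and fused by
#' a 1x1 Conv+BN+ReLU back to the stage width. Resolutions above `grid`
#' are average-pooled for the attention and upsampled back.
#'
#' @param channels Stage width.
#' @param grid Maximum attention grid side.
#' @param scale Attention logit scaling.
#' @param seed Optional seed.
#' @export
casc_block <- function(channels, grid = 32L, scale = c("sqrt", "linear"), seed = NULL) {
  seed_block(mod_casc(channels, as.integer(grid), match.arg(scale)), seed)
}

#' @rdname casc_block
#' @param low Encoder skip feature map `(C, H, W)` or batched.
#' @param high Decoder feature map at the same resolution and width.
#' @param block A `casc_block()`.
#' @param training Use batch statistics in the fusion BN.
#' @export
casc_forward <- function(low, high, block, training = FALSE) {
  lo <- as_fmap(low)
  hi <- as_fmap(high)
  out <- nval(block$forward(block, lo, hi, training))
  if (length(dim(low)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

#' Decoder block
#'
#' 2x up-sampling (transposed 2x2 convolution by default) from
#' `in_channels` to `out_channels`, followed by a residual pair of 3x3
#' Conv+BN(+ReLU) layers at the output width.
#'
#' @param in_channels,out_channels Stage widths.
#' @param upsample_mode `"deconv"` or `"bilinear"`.
#' @param seed Optional seed.
#' @export
decoder_block <- function(in_channels, out_channels,
                          upsample_mode = c("deconv", "bilinear"), seed = NULL) {
  up <- mod_upsample_stage(in_channels, out_channels, match.arg(upsample_mode))
  refine <- mod_residual_pair(out_channels)
  blk <- new_module(function(self, x, training = FALSE) {
    run_mod(self$children$refine, run_mod(self$children$up, x, training), training)
  }, children = list(up = up, refine = refine),
     meta = list(kind = "decoder", cin = in_channels, cout = out_channels))
  seed_block(blk, seed)
}

#' @rdname decoder_block
#' @param x Feature map with `in_channels` channels.
#' @param block A `decoder_block()`.
#' @param training Use batch statistics in BN layers.
#' @export
decoder_block_forward <- function(x, block, training = FALSE) run_block(block, x, training)

#' Prediction head
#'
#' 1x1 convolution to a single channel followed by the sigmoid; values lie
#' strictly in (0, 1) for finite logits.
#'
#' @param x Feature map `(C, H, W)`.
#' @param head A head built by `prediction_head_block()`, or NULL to build
#'   one with the given seed.
#' @param seed Optional seed when `head` is NULL.
#' @return Single-channel probability map.
#' @export
prediction_head <- function(x, head = NULL, seed = NULL) {
  xin <- as_fmap(x)
  if (is.null(head)) head <- prediction_head_block(dim(xin)[1], seed)
  out <- nval(t_sigmoid(run_mod(head, xin, FALSE)))
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

#' @rdname prediction_head
#' @param in_channels Input width of the head.
#' @export
prediction_head_block <- function(in_channels, seed = NULL) {
  seed_block(mod_head(in_channels), seed)
}

#' Extract attention maps
#'
#' Returns the row-stochastic attention matrices actually used by a block
#' on the given input(s): one `n x n` matrix per batch sample (and per
#' head for TSA).
#'
#' @param x Feature map `(C, H, W)` or `(C, H, W, B)`.
#' @param block A `tsa_block()` / `gsa_block()` / `casc_block()`.
#' @return List of attention matrices.
#' @export
tsa_attention <- function(x, block) {
  xin <- as_fmap(x)
  d <- dim(xin)
  C <- d[1]; n <- d[2] * d[3]; B <- d[4]
  heads <- block$meta$heads
  ch <- C %/% heads
  maps <- list()
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * ch + 1L):(h * ch)
    Q <- nval(t_reshape(t_conv1x1(xin, block$params$wq), c(C, n, B)))[idx, , , drop = FALSE]
    K <- nval(t_reshape(t_conv1x1(xin, block$params$wk), c(C, n, B)))[idx, , , drop = FALSE]
    V <- K
    sc <- if (block$meta$scale == "sqrt") sqrt(ch) else ch
    res <- t_attn(ad_node(Q), ad_node(K), ad_node(V), scale = sc, keep_attn = TRUE)
    maps <- c(maps, res$attn)
  }
  maps
}

#' @rdname tsa_attention
#' @export
gsa_attention <- function(x, block) {
  xin <- as_fmap(x)
  d <- dim(xin)
  n <- d[2] * d[3]; B <- d[4]
  cr <- nrow(block$params$w_reduce$value)
  red <- nval(t_reshape(t_conv1x1(xin, block$params$w_reduce), c(cr, n, B)))
  res <- t_attn(ad_node(red), ad_node(red), ad_node(red), scale = 1, keep_attn = TRUE)
  res$attn
}

#' @rdname tsa_attention
#' @param low,high Encoder/decoder maps for the cross-attention skip.
#' @export
casc_attention <- function(low, high, block) {
  lo <- as_fmap(low)
  hi <- as_fmap(high)
  d <- dim(lo)
  C <- d[1]; H <- d[2]; B <- d[4]
  lo_g <- run_mod(block$children$select_low, ad_node(lo), FALSE)
  hi_g <- run_mod(block$children$select_high, ad_node(hi), FALSE)
  f <- pool_factor(H, block$meta$grid)
  lo_p <- t_avgpool(lo_g, f)
  hi_p <- t_avgpool(hi_g, f)
  hg <- H %/% f
  n <- hg * hg
  Q <- t_reshape(t_conv1x1(hi_p, block$params$wq), c(C, n, B))
  K <- t_reshape(t_conv1x1(lo_p, block$params$wk), c(C, n, B))
  res <- t_attn(Q, K, K, scale = sqrt(C), keep_attn = TRUE)
  res$attn
}
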