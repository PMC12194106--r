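# Shared fixtures: tiny configurations and brute-force reference
# implementations used as oracles across the suite.

tiny_cfg <- function(input_size = 64L, skip = "CASC", bottleneck = "DTA",
                     encoder = "RDI") {
  model_config(stage_widths = c(8L, 8L, 8L, 16L), bottleneck_width = 16L,
               encoder_variant = encoder, bottleneck_variant = bottleneck,
               skip_variant = skip, input_size = input_size, casc_grid = 8L)
}

rand_fmap <- function(C, H, W, B = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(B)) array(rnorm(C * H * W), dim = c(C, H, W))
  else array(rnorm(C * H * W * B), dim = c(C, H, W, B))
}

# row softmax by explicit exp/sum loops
ref_softmax_rows <- function(S) {
  A <- matrix(0, nrow(S), ncol(S))
  for (i in seq_len(nrow(S))) {
    e <- exp(S[i, ] - max(S[i, ]))
    A[i, ] <- e / sum(e)
  }
  A
}

# brute-force scaled dot-product attention: Q, K (cq x n), V (cv x n)
ref_attention <- function(Q, K, V, scale) {
  n <- ncol(Q)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) S[i, j] <- sum(Q[, i] * K[, j]) / scale
  A <- ref_softmax_rows(S)
  O <- matrix(0, nrow(V), n)
  for (i in seq_len(n)) for (j in seq_len(n)) O[, i] <- O[, i] + A[i, j] * V[, j]
  list(O = O, A = A)
}

# plain dense 2-D convolution by nested loops (same padding, stride 1)
ref_conv2d <- function(x, w, dilation = 1L) {
  if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x))  # re-add dropped channel
  d <- dim(x)  # (C, H, W)
  kd <- dim(w) # (cout, cin, k, k)
  k <- kd[3]
  p <- dilation * (k - 1) / 2
  y <- array(0, dim = c(kd[1], d[2], d[3]))
  for (co in seq_len(kd[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    acc <- 0
    for (ci in seq_len(kd[2])) for (a in seq_len(k)) for (b in seq_len(k)) {
      ii <- i + (a - 1) * dilation - p
      jj <- j + (b - 1) * dilation - p
      if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3])
        acc <- acc + w[co, ci, a, b] * x[ci, ii, jj]
    }
    y[co, i, j] <- acc
  }
  y
}

rel_err <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  max(abs(a - b)) / max(1e-12, max(abs(b)))
}

tiny_scene_set <- function(n = 4, canvas = 64L, seed = 10) {
  styles <- c("leaf_stripes", "soil_texture", "clutter")
  lapply(seq_len(n), function(i)
    generate_pest_scene(scene_params(canvas_size = canvas,
                                     background_style = styles[(i - 1) %% 3 + 1],
                                     class_id = (i - 1) %% 3 + 1),
                        seed = seed + i))
}

# cheap content fingerprint for distinctness checks
digest_num <- function(x) {
  paste(format(c(length(x), sum(x), sum(x * seq_along(x)), sum(x^2)),
               digits = 15), collapse = "|")
}
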