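#' Model configuration
#'
#' Describes the full CATransU-Net architecture: the four encoder stage
#' widths, the bottleneck width, the dilation rates of the residual dilated
#' Inception (RDI) blocks, the attention settings, and the variant selectors
#' used for ablation studies (encoder, bottleneck and skip-connection
#' substitutions).
#'
#' The default stage widths are the package's calibrated capacity family:
#' slim shallow stages and a wide bottleneck, chosen once so that the full
#' model carries about 14.6 M trainable parameters and about 18.9 GFLOPs per
#' 256x256 forward pass (see the methods vignette).
#'
#' @param in_channels Number of input image channels (3 for RGB).
#' @param stage_widths Integer vector of 4 encoder stage output widths.
#' @param bottleneck_width Channel width of the bottleneck.
#' @param dilation_rates Four dilation rates for the RDI branches.
#' @param attention_heads Number of self-attention heads in the bottleneck.
#' @param gsa_reduction Channel reduction factor of the position-attention
#'   branch (the reduced width is `bottleneck_width / gsa_reduction`).
#' @param encoder_variant One of `"RDI"`, `"inception"`,
#'   `"dilated_inception"`, `"plain_conv"`.
#' @param bottleneck_variant One of `"DTA"`, `"ASPP"`, `"TSA_only"`,
#'   `"GSA_only"`, `"none"`.
#' @param skip_variant One of `"CASC"`, `"plain_skip"`, `"none"`.
#' @param input_size Input image side length in pixels (divisible by 16).
#' @param casc_grid Maximum attention grid side for the cross-attention
#'   skips; larger skip resolutions are average-pooled to this grid.
#' @param attn_scale `"sqrt"` divides attention logits by sqrt(d_k)
#'   (standard scaled dot-product); `"linear"` divides by d_k.
#' @param upsample_mode `"deconv"` (2x2 transposed convolution) or
#'   `"bilinear"` (nearest upsampling + 1x1 projection).
#' @return An object of class `catu_config`.
#' @export
model_config <- function(in_channels = 3L,
                         stage_widths = c(24L, 52L, 104L, 256L),
                         bottleneck_width = 840L,
                         dilation_rates = c(1L, 3L, 5L, 7L),
                         attention_heads = 1L,
                         gsa_reduction = 8L,
                         encoder_variant = c("RDI", "inception", "dilated_inception", "plain_conv"),
                         bottleneck_variant = c("DTA", "ASPP", "TSA_only", "GSA_only", "none"),
                         skip_variant = c("CASC", "plain_skip", "none"),
                         input_size = 256L,
                         casc_grid = 32L,
                         attn_scale = c("sqrt", "linear"),
                         upsample_mode = c("deconv", "bilinear")) {
  encoder_variant <- match.arg(encoder_variant)
  bottleneck_variant <- match.arg(bottleneck_variant)
  skip_variant <- match.arg(skip_variant)
  attn_scale <- match.arg(attn_scale)
  upsample_mode <- match.arg(upsample_mode)
  stage_widths <- as.integer(stage_widths)
  if (length(stage_widths) != 4L || any(stage_widths <= 0L))
    stop("stage_widths must be 4 strictly positive integers")
  if (length(dilation_rates) != 4L || any(dilation_rates < 1L))
    stop("dilation_rates must be 4 positive integers")
  if (bottleneck_width %% gsa_reduction != 0L)
    stop("gsa_reduction must divide bottleneck_width")
  if (input_size %% 16L != 0L)
    stop("input_size must be divisible by 16 (four downsampling stages)")
  if (any(stage_widths %% 4L != 0L) && encoder_variant != "plain_conv")
    stop("stage_widths must be divisible by 4 for Inception-style encoders")
  cfg <- list(in_channels = as.integer(in_channels),
              stage_widths = stage_widths,
              bottleneck_width = as.integer(bottleneck_width),
              dilation_rates = as.integer(dilation_rates),
              attention_heads = as.integer(attention_heads),
              gsa_reduction = as.integer(gsa_reduction),
              encoder_variant = encoder_variant,
              bottleneck_variant = bottleneck_variant,
              skip_variant = skip_variant,
              input_size = as.integer(input_size),
              casc_grid = as.integer(casc_grid),
              attn_scale = attn_scale,
              upsample_mode = upsample_mode)
  class(cfg) <- "catu_config"
  cfg
}

#' Default calibrated configuration
#'
#' The frozen default CATransU-Net configuration (RDI encoder, dual
#' Transformer-attention bottleneck, cross-attention skips) with the
#' calibrated width family.
#'
#' @return A `catu_config`.
#' @export
default_config <- function() model_config()

#' A small configuration for desk-scale experiments
#'
#' Same topology as the default model with slim widths, suitable for
#' CPU training on small synthetic scenes.
#'
#' @param input_size Input side length (divisible by 16).
#' @return A `catu_config`.
#' @export
small_config <- function(input_size = 128L) {
  model_config(stage_widths = c(8L, 16L, 32L, 64L), bottleneck_width = 64L,
               input_size = input_size, casc_grid = 16L)
}

#' @export
print.catu_config <- function(x, ...) {
  cat("CATransU-Net configuration\n")
  cat(sprintf("  input: %d x %d x %d\n", x$in_channels, x$input_size, x$input_size))
  cat(sprintf("  stage widths: %s | bottleneck: %d\n",
              paste(x$stage_widths, collapse = "/"), x$bottleneck_width))
  cat(sprintf("  encoder: %s (rates %s) | bottleneck: %s | skip: %s\n",
              x$encoder_variant, paste(x$dilation_rates, collapse = ","),
              x$bottleneck_variant, x$skip_variant))
  cat(sprintf("  heads: %d | GSA reduction: %d | CASC grid: %d | upsampling: %s\n",
              x$attention_heads, x$gsa_reduction, x$casc_grid, x$upsample_mode))
  invisible(x)
}

#' Build a CATransU-Net model
#'
#' Wires the four encoder stages (each followed by 2x2 max pooling), the
#' bottleneck (a double 3x3 convolution raising to the bottleneck width,
#' then the configured attention variant), four decoder stages fused with
#' the matching encoder skip, and a 1x1 convolution + sigmoid head.
#' Ablation variants substitute blocks without changing the topology.
#'
#' @param cfg A `catu_config`.
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `catu_model`.
#' @export
build_model <- function(cfg = default_config(), seed = NULL) {
  stopifnot(inherits(cfg, "catu_config"))
  w <- cfg$stage_widths
  bw <- cfg$bottleneck_width
  blocks <- list()
  cin <- cfg$in_channels
  for (i in 1:4) {
    blocks[[paste0("encoder", i)]] <-
      encoder_stage(cfg$encoder_variant, cin, w[i], cfg$dilation_rates)
    cin <- w[i]
  }
  blocks$bottleneck_conv <- mod_double_conv(w[4], bw)
  blocks$bottleneck_attn <- bottleneck_module(cfg$bottleneck_variant, bw,
                                              cfg$attention_heads, cfg$gsa_reduction,
                                              cfg$attn_scale, cfg$dilation_rates)
  dec_in <- c(w[2], w[3], w[4], bw)  # input width of decoder stage i (deep side)
  for (i in 4:1) {
    blocks[[paste0("decoder", i, "_up")]] <-
      mod_upsample_stage(dec_in[i], w[i], cfg$upsample_mode)
    if (cfg$skip_variant == "CASC") {
      blocks[[paste0("decoder", i, "_skip")]] <- mod_casc(w[i], cfg$casc_grid, cfg$attn_scale)
    } else if (cfg$skip_variant == "plain_skip") {
      blocks[[paste0("decoder", i, "_skip")]] <- mod_plain_skip(w[i])
    }
    blocks[[paste0("decoder", i, "_refine")]] <- mod_residual_pair(w[i])
  }
  blocks$head <- mod_head(w[1])
  model <- structure(list(config = cfg, blocks = blocks), class = "catu_model")
  model$params <- model_params(model)
  init_weights(model, seed)
  model
}

model_params <- function(model) {
  out <- list()
  for (nm in names(model$blocks)) {
    out <- c(out, collect_params(model$blocks[[nm]], paste0(nm, ".")))
  }
  out
}

model_buffers <- function(model) {
  out <- list()
  for (nm in names(model$blocks)) {
    out <- c(out, collect_buffers(model$blocks[[nm]], paste0(nm, ".")))
  }
  out
}

#' Initialize model weights
#'
#' Kaiming (He) initialization for all convolution and projection weights,
#' zeros for biases and attention gates, unit scale for normalization
#' layers; batch-normalization running statistics are reset. Reproducible
#' given a seed.
#'
#' @param model A `catu_model`.
#' @param seed Optional integer seed.
#' @return The model, invisibly (parameters are updated in place).
#' @export
init_weights <- function(model, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  for (p in model$params) {
    d <- dim(p$value) %||% length(p$value)
    p$value <- switch(p$init,
      kaiming = array(stats::rnorm(prod(d), sd = sqrt(2 / p$fan_in)), dim = d),
      zero = array(0, dim = d),
      one = array(1, dim = d)
    )
    p$grad <- NULL
  }
  for (st in model_buffers(model)) {
    st$mean[] <- 0
    st$var[] <- 1
  }
  invisible(model)
}

# Core forward wiring shared by forward_pass() and the trainer.
model_forward <- function(model, x, training = FALSE, logits = FALSE) {
  cfg <- model$config
  b <- model$blocks
  skips <- vector("list", 4L)
  h <- x
  for (i in 1:4) {
    h <- run_mod(b[[paste0("encoder", i)]], h, training)
    skips[[i]] <- h
    h <- t_maxpool2(h)
  }
  h <- run_mod(b$bottleneck_conv, h, training)
  h <- run_mod(b$bottleneck_attn, h, training)
  for (i in 4:1) {
    h <- run_mod(b[[paste0("decoder", i, "_up")]], h, training)
    sk <- b[[paste0("decoder", i, "_skip")]]
    if (!is.null(sk)) h <- sk$forward(sk, skips[[i]], h, training)
    h <- run_mod(b[[paste0("decoder", i, "_refine")]], h, training)
  }
  z <- run_mod(b$head, h, training)
  if (logits) z else t_sigmoid(z)
}

#' Forward pass
#'
#' Maps a batch of images to per-pixel pest probability maps. The batch may
#' be a single `(C, H, W)` array or a `(C, H, W, B)` array; spatial size
#' must equal the configured input size (there is no silent resizing).
#'
#' @param model A `catu_model`.
#' @param batch Image array, channel-first, values typically in `[0, 1]`.
#' @param training Logical; use batch statistics in normalization layers.
#' @return Probability maps `(1, H, W)` or `(1, H, W, B)`, values in (0, 1).
#' @export
forward_pass <- function(model, batch, training = FALSE) {
  x <- as_batch(batch)
  d <- dim(x)
  cfg <- model$config
  if (d[1] != cfg$in_channels)
    stop("forward_pass: expected ", cfg$in_channels, " channels, got ", d[1])
  if (d[2] != cfg$input_size || d[3] != cfg$input_size)
    stop("forward_pass: expected spatial size ", cfg$input_size, "x", cfg$input_size,
         ", got ", d[2], "x", d[3], " (the model does not resize inputs)")
  out <- nval(model_forward(model, x, training = training))
  if (length(dim(batch)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("batch must be a (C, H, W) or (C, H, W, B) array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' Predict pest probability maps for a dataset
#'
#' @param object A `catu_model`.
#' @param dataset A `catu_dataset`, a single sample, or an image array
#'   (`H x W x 3` or channel-first).
#' @param threshold If non-NULL, also return binary masks at this threshold.
#' @param ... Unused.
#' @return A list with `prob` (list of H x W probability maps) and
#'   optionally `mask` (list of binary masks).
#' @export
predict.catu_model <- function(object, dataset, threshold = NULL, ...) {
  samples <- as_sample_list(dataset)
  probs <- lapply(samples, function(s) {
    x <- image_to_tensor(s$image)
    p <- forward_pass(object, x)
    p[1, , ]
  })
  out <- list(prob = probs)
  if (!is.null(threshold)) out$mask <- lapply(probs, binarize, threshold = threshold)
  out
}

#' @export
print.catu_model <- function(x, ...) {
  rep <- count_parameters(x)
  cat("CATransU-Net model\n")
  print(x$config)
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(rep$total_params, big.mark = ","), rep$total_params / 1e6))
  invisible(x)
}

#' @export
summary.catu_model <- function(object, ...) {
  rep <- count_parameters(object)
  print(object$config)
  cat("\nPer-block parameter counts:\n")
  df <- data.frame(block = names(rep$per_block_params),
                   params = unname(rep$per_block_params))
  print(df, row.names = FALSE)
  cat(sprintf("\nTotal: %s trainable parameters (%.2f M)\n",
              format(rep$total_params, big.mark = ","), rep$total_params / 1e6))
  invisible(rep)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  force(expr)
}
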