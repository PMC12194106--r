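#' Training configuration
#'
#' Optimization protocol: Adam with learning rate 0.001, weight decay
#' 0.0001 and first-moment decay 0.9, mini-batches of 32, 3000 iterations,
#' and a reduce-on-plateau schedule that multiplies the learning rate by
#' 0.1 when the monitored loss has not improved for `plateau_patience`
#' iterations.
#'
#' @param learning_rate Initial Adam step size.
#' @param weight_decay L2 penalty added to the gradients.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size Mini-batch size (capped at the dataset size).
#' @param total_iterations Number of optimizer steps.
#' @param plateau_factor Learning-rate multiplier on plateau.
#' @param plateau_patience Iterations without improvement before decay.
#' @param eval_every Iterations between validation evaluations.
#' @param val_fraction Fraction of the training set held out for
#'   validation (0 disables; the training loss is then monitored).
#' @param pos_weight Foreground weighting passed to the loss
#'   (NULL, a number, or `"balanced"`).
#' @param seed Seed controlling shuffling and any validation split.
#' @param checkpoint_path Optional path to write the final checkpoint.
#' @param verbose Print progress every `eval_every` iterations.
#' @return A `catu_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.0001,
                         beta1 = 0.9, beta2 = 0.999, batch_size = 32L,
                         total_iterations = 3000L, plateau_factor = 0.1,
                         plateau_patience = 200L, eval_every = 25L,
                         val_fraction = 0.1, pos_weight = NULL, seed = 1L,
                         checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            total_iterations >= 1, plateau_factor > 0, plateau_factor < 1,
            plateau_patience >= 1)
  cfg <- list(learning_rate = learning_rate, weight_decay = weight_decay,
              beta1 = beta1, beta2 = beta2, batch_size = as.integer(batch_size),
              total_iterations = as.integer(total_iterations),
              plateau_factor = plateau_factor,
              plateau_patience = as.integer(plateau_patience),
              eval_every = as.integer(eval_every), val_fraction = val_fraction,
              pos_weight = pos_weight, seed = as.integer(seed),
              checkpoint_path = checkpoint_path, verbose = isTRUE(verbose))
  class(cfg) <- "catu_train_config"
  cfg
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value))),
       v = lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value))),
       t = 0L)
}

adam_step <- function(params, state, lr, beta1, beta2, weight_decay, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    p$value <- p$value - lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    p$grad <- NULL
  }
  state
}

samples_to_tensors <- function(samples) {
  imgs <- lapply(samples, function(s) image_to_tensor(s$image))
  masks <- lapply(samples, function(s) {
    m <- s$mask
    dim(m) <- c(1L, dim(s$mask))
    m
  })
  list(x = abind4(imgs), y = abind4(masks))
}

abind4 <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, dim = c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

#' Convert an H x W x 3 image to a channel-first tensor
#' @param image Image array, `H x W x C` or already channel-first.
#' @return `(C, H, W)` array.
#' @export
image_to_tensor <- function(image) {
  d <- dim(image)
  if (length(d) == 2L) {
    dim(image) <- c(1L, d)
    return(image)
  }
  if (d[3] <= 4L && d[1] > 4L) return(aperm(image, c(3L, 1L, 2L)))
  image
}

#' Train a model
#'
#' Runs the Adam optimization loop with balanced binary cross-entropy on
#' mini-batches drawn from the dataset (shuffled epochs, seeded). The
#' monitored loss (validation if a split is configured, otherwise the
#' running training loss) drives the reduce-on-plateau schedule. A NaN
#' loss aborts with a diagnostic.
#'
#' @param model A `catu_model`.
#' @param dataset A `catu_dataset` or list of samples (each with `image`
#'   `H x W x 3` and binary `mask`).
#' @param config A [train_config()].
#' @return A `catu_fit`: the trained model, a per-iteration history data
#'   frame, the evaluation log, and the configuration.
#' @export
train_model <- function(model, dataset, config = train_config()) {
  samples <- as_sample_list(dataset)
  n <- length(samples)
  if (n == 0L) stop("train_model: empty dataset")
  cfg <- config
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  n_val <- if (cfg$val_fraction > 0) floor(cfg$val_fraction * n) else 0L
  idx <- sample.int(n)
  val_idx <- if (n_val >= 1L) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)
  if (length(tr_idx) == 0L) stop("train_model: no training samples after validation split")
  tr <- samples_to_tensors(samples[tr_idx])
  va <- if (n_val >= 1L) samples_to_tensors(samples[val_idx]) else NULL

  params <- model$params
  opt <- adam_state(params)
  lr <- cfg$learning_rate
  bs <- min(cfg$batch_size, length(tr_idx))
  order_pool <- integer(0)
  h_loss <- numeric(cfg$total_iterations)
  h_lr <- numeric(cfg$total_iterations)
  ev_it <- integer(0); ev_loss <- numeric(0); ev_lr <- numeric(0)
  best <- Inf
  last_improve <- 0L
  run_mean <- NULL

  for (it in seq_len(cfg$total_iterations)) {
    if (length(order_pool) < bs) order_pool <- c(order_pool, sample.int(dim(tr$x)[4]))
    take <- order_pool[seq_len(bs)]
    order_pool <- order_pool[-seq_len(bs)]
    xb <- tr$x[, , , take, drop = FALSE]
    yb <- tr$y[, , , take, drop = FALSE]
    w <- resolve_pos_weight(cfg$pos_weight, yb)
    tp <- with_tape({
      z <- model_forward(model, xb, training = TRUE, logits = TRUE)
      t_bce_logits(z, yb, w)
    })
    loss <- as.numeric(nval(tp$result))
    if (!is.finite(loss))
      stop("train_model: non-finite loss at iteration ", it,
           " (lr = ", lr, "); aborting")
    backward(tp$result, tp$tape)
    opt <- adam_step(params, opt, lr, cfg$beta1, cfg$beta2, cfg$weight_decay)
    h_loss[it] <- loss
    h_lr[it] <- lr
    run_mean <- if (is.null(run_mean)) loss else 0.9 * run_mean + 0.1 * loss

    if (it %% cfg$eval_every == 0L || it == cfg$total_iterations) {
      mon <- if (!is.null(va)) {
        vz <- nval(model_forward(model, va$x, training = FALSE, logits = TRUE))
        balanced_bce_loss(vz, va$y, if (is.null(cfg$pos_weight)) NULL else w)
      } else run_mean
      ev_it <- c(ev_it, it); ev_loss <- c(ev_loss, mon); ev_lr <- c(ev_lr, lr)
      if (mon < best - 1e-6) {
        best <- mon
        last_improve <- it
      } else if (it - last_improve >= cfg$plateau_patience) {
        lr <- lr * cfg$plateau_factor
        last_improve <- it
        if (cfg$verbose) message(sprintf("iter %d: plateau, lr -> %g", it, lr))
      }
      if (cfg$verbose)
        message(sprintf("iter %4d  loss %.4f  monitored %.4f  lr %g", it, loss, mon, lr))
    }
  }

  recalibrate_bn(model, tr$x)
  history <- data.frame(iteration = seq_len(cfg$total_iterations),
                        loss = h_loss, lr = h_lr)
  evals <- data.frame(iteration = ev_it, monitored_loss = ev_loss, lr = ev_lr)
  fit <- structure(list(model = model, history = history, evals = evals,
                        config = cfg, final_lr = lr), class = "catu_fit")
  if (!is.null(cfg$checkpoint_path)) save_checkpoint(fit, cfg$checkpoint_path)
  fit
}

#' Recalibrate batch-normalization statistics
#'
#' Replaces every BN layer's running mean/variance with the statistics of
#' one training-mode pass over the given batch (the whole training set
#' during [train_model()]), so that evaluation-mode normalization matches
#' the data the model was fit on. This is the standard "precise BN"
#' finishing step.
#'
#' @param model A `catu_model`.
#' @param x A `(C, H, W, B)` image batch (typically the training tensors).
#' @return The model, invisibly.
#' @export
recalibrate_bn <- function(model, x) {
  old <- .ad$bn_momentum
  .ad$bn_momentum <- 1
  on.exit(.ad$bn_momentum <- old)
  invisible(model_forward(model, x, training = TRUE))
  invisible(model)
}

#' Reduce-on-plateau schedule step
#'
#' Pure helper implementing the learning-rate schedule contract: given the
#' sequence of monitored losses, returns the learning rate after each
#' evaluation (decayed by `factor` whenever `patience` evaluations pass
#' without improvement).
#'
#' @param losses Numeric vector of monitored losses (one per evaluation).
#' @param lr0 Initial learning rate.
#' @param factor Decay factor in (0, 1).
#' @param patience Number of evaluations without improvement tolerated.
#' @return Numeric vector of learning rates, same length as `losses`.
#' @export
plateau_schedule <- function(losses, lr0 = 0.001, factor = 0.1, patience = 2L) {
  lr <- lr0
  best <- Inf
  stall <- 0L
  out <- numeric(length(losses))
  for (i in seq_along(losses)) {
    if (losses[i] < best - 1e-6) {
      best <- losses[i]
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) {
        lr <- lr * factor
        stall <- 0L
      }
    }
    out[i] <- lr
  }
  out
}

#' Five-fold cross-validation split
#'
#' Partitions `1..n` into 5 disjoint folds whose sizes differ by at most
#' one, reproducibly for a given seed.
#'
#' @param n Dataset size (or a dataset / list of samples).
#' @param seed Integer seed.
#' @return List of 5 integer index vectors.
#' @export
five_fold_split <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) > 1L) n <- length(as_sample_list(n))
  n <- as.integer(n)
  if (n < 5L) stop("five_fold_split: need at least 5 samples")
  idx <- with_seed(seed, sample.int(n))
  fold_of <- rep(1:5, length.out = n)
  lapply(1:5, function(f) sort(idx[fold_of == f]))
}

#' @export
print.catu_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("CATransU-Net fit: %d iterations, loss %.4f -> %.4f (final lr %g)\n",
              nrow(h), h$loss[1], h$loss[nrow(h)], x$final_lr))
  invisible(x)
}

#' @export
plot.catu_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$iteration, h$loss, type = "l", xlab = "iteration",
                 ylab = "training loss", main = "Training loss", ...)
  if (nrow(x$evals)) {
    graphics::lines(x$evals$iteration, x$evals$monitored_loss, col = 2, lty = 2)
    graphics::legend("topright", legend = c("train", "monitored"),
                     col = c(1, 2), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' @export
predict.catu_fit <- function(object, dataset, threshold = NULL, ...) {
  predict(object$model, dataset, threshold = threshold, ...)
}
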