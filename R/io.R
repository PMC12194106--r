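# Dataset, configuration and checkpoint I/O. Images are 8-bit PNG; masks
# are 8-bit PNG with 0/255 semantics; datasets carry a JSON manifest.

#' Save a dataset as paired PNG files with a manifest
#'
#' @param dataset A `catu_dataset` or list of samples.
#' @param root Output directory (`images/`, `masks/`, `manifest.json`).
#' @return `root`, invisibly.
#' @export
save_dataset <- function(dataset, root) {
  samples <- as_sample_list(dataset)
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "masks"), recursive = TRUE, showWarnings = FALSE)
  man <- if (inherits(dataset, "catu_dataset")) dataset$manifest else
    data.frame(id = seq_along(samples),
               class_id = vapply(samples, function(s) s$class_id %||% 1L, numeric(1)),
               seed = NA_integer_, augmented_from = NA_integer_)
  man$file <- sprintf("sample_%05d.png", man$id)
  for (i in seq_along(samples)) {
    png::writePNG(samples[[i]]$image, file.path(root, "images", man$file[i]))
    png::writePNG(samples[[i]]$mask * 1.0, file.path(root, "masks", man$file[i]))
  }
  jsonlite::write_json(man, file.path(root, "manifest.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(root)
}

#' Load a dataset of paired image/mask PNGs
#'
#' Reads `images/*.png` with matching `masks/*.png` (and the manifest when
#' present). Masks are coerced to \{0, 1\}; images lacking a mask are
#' skipped with a warning.
#'
#' @param root Dataset directory.
#' @return A `catu_dataset`.
#' @export
load_dataset <- function(root) {
  imgdir <- file.path(root, "images")
  mskdir <- file.path(root, "masks")
  if (!dir.exists(imgdir)) stop("load_dataset: no images/ directory under ", root)
  files <- sort(list.files(imgdir, pattern = "\\.(png|PNG|jpg|jpeg)$"))
  if (length(files) == 0L) stop("load_dataset: empty dataset at ", root)
  man <- NULL
  manpath <- file.path(root, "manifest.json")
  if (file.exists(manpath)) {
    man <- jsonlite::fromJSON(manpath)
  }
  samples <- list()
  skipped <- character(0)
  for (f in files) {
    mpath <- file.path(mskdir, f)
    if (!file.exists(mpath)) {
      skipped <- c(skipped, f)
      next
    }
    img <- png::readPNG(file.path(imgdir, f))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    msk <- png::readPNG(mpath)
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    msk <- (msk > 0.5) + 0L
    cl <- 1L
    sd <- NA_integer_
    if (!is.null(man)) {
      row <- which(man$file == f)
      if (length(row) == 1L) {
        cl <- man$class_id[row]
        sd <- man$seed[row]
      }
    }
    samples[[length(samples) + 1L]] <-
      new_sample(img, msk, cl, provenance = list(file = f, seed = sd))
  }
  if (length(skipped))
    warning("load_dataset: skipped ", length(skipped), " image(s) without a mask: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  if (length(samples) == 0L) stop("load_dataset: no valid image/mask pairs at ", root)
  manifest <- data.frame(
    id = seq_along(samples),
    class_id = vapply(samples, function(s) s$class_id, numeric(1)),
    seed = vapply(samples, function(s) s$provenance$seed %||% NA_integer_, numeric(1)),
    augmented_from = NA_integer_,
    file = vapply(samples, function(s) s$provenance$file, character(1)))
  structure(list(samples = samples, manifest = manifest, seed = NA_integer_),
            class = "catu_dataset")
}

#' Write / read a model configuration as YAML
#'
#' @param cfg A `catu_config`.
#' @param path YAML file path.
#' @export
write_model_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "catu_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(model_config, lst)
}

#' Save / load a model or fit checkpoint
#'
#' A checkpoint stores the configuration, every parameter value, the
#' normalization running statistics, and (for a fit) the training history,
#' so that evaluation can be reproduced bit-identically.
#'
#' @param object A `catu_model` or `catu_fit`.
#' @param path Output file.
#' @export
save_checkpoint <- function(object, path) {
  fit <- NULL
  model <- object
  if (inherits(object, "catu_fit")) {
    fit <- object
    model <- object$model
  }
  stopifnot(inherits(model, "catu_model"))
  bufs <- model_buffers(model)
  state <- list(
    config = unclass(model$config),
    params = lapply(model$params, function(p) p$value),
    buffers = lapply(bufs, function(st) list(mean = st$mean, var = st$var)),
    history = fit$history, evals = fit$evals,
    train_config = if (!is.null(fit)) unclass(fit$config) else NULL)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the restored `catu_model` (with `history`
#'   attached as an attribute when present).
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  cfg <- do.call(model_config, state$config)
  model <- build_model(cfg)
  for (nm in names(state$params)) {
    p <- model$params[[nm]]
    if (is.null(p)) stop("load_checkpoint: unknown parameter ", nm)
    stopifnot(length(p$value) == length(state$params[[nm]]))
    p$value <- state$params[[nm]]
  }
  bufs <- model_buffers(model)
  for (nm in names(state$buffers)) {
    bufs[[nm]]$mean <- state$buffers[[nm]]$mean
    bufs[[nm]]$var <- state$buffers[[nm]]$var
  }
  if (!is.null(state$history)) attr(model, "history") <- state$history
  model
}
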