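#' Count trainable parameters
#'
#' Enumerates every learnable weight of the model and reports the total and
#' a per-block breakdown.
#'
#' @param model A `catu_model`.
#' @return A `catu_param_report` with `total_params` and `per_block_params`.
#' @export
count_parameters <- function(model) {
  per_block <- vapply(names(model$blocks), function(nm) {
    ps <- collect_params(model$blocks[[nm]])
    sum(vapply(ps, function(p) length(p$value), numeric(1)))
  }, numeric(1))
  rep <- list(total_params = sum(per_block), per_block_params = per_block)
  class(rep) <- "catu_param_report"
  rep
}

#' @export
print.catu_param_report <- function(x, ...) {
  cat("Trainable parameters by block:\n")
  for (nm in names(x$per_block_params)) {
    cat(sprintf("  %-22s %12s\n", nm,
                format(x$per_block_params[[nm]], big.mark = ",")))
  }
  cat(sprintf("  %-22s %12s  (%.2f M)\n", "total",
              format(x$total_params, big.mark = ","), x$total_params / 1e6))
  if (!is.null(x$gflops))
    cat(sprintf("  forward GFLOPs @ %d: %.2f\n", x$input_size, x$gflops))
  invisible(x)
}

#' Export a parameter report as JSON
#'
#' @param report A `catu_param_report`.
#' @param path Output file path.
#' @export
write_param_report <- function(report, path) {
  jsonlite::write_json(list(total_params = report$total_params,
                            per_block_params = as.list(report$per_block_params),
                            gflops = report$gflops),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Estimate forward-pass FLOPs
#'
#' Runs one forward pass on a zero image of the given size with the FLOP
#' meter enabled and reports the count in GFLOPs (1e9). A
#' multiply-accumulate counts as 2 FLOPs; convolutions, normalizations,
#' activations and attention matrix products are all metered (see the
#' convention note in the methods vignette).
#'
#' @param model A `catu_model`.
#' @param input_size Input side length (defaults to the configured size).
#' @return GFLOPs as a single number.
#' @export
estimate_flops <- function(model, input_size = NULL) {
  cfg <- model$config
  input_size <- as.integer(input_size %||% cfg$input_size)
  if (input_size %% 16L != 0L) stop("input_size must be divisible by 16")
  x <- array(0, dim = c(cfg$in_channels, input_size, input_size, 1L))
  res <- with_flop_meter(model_forward(model, x, training = FALSE))
  res$flops / 1e9
}
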