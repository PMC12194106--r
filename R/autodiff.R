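# Minimal reverse-mode automatic differentiation on dense R arrays.
#
# A tensor node is an environment holding $value (a numeric array), $grad
# (accumulated during the backward sweep), the $parents it was computed from
# and a $backward closure that pushes its gradient onto those parents.
# During a taped forward pass every differentiable op appends its node to the
# active tape; backward() walks the tape in reverse. Feature maps are stored
# channel-first with dimensions (C, H, W, B) so that flattening the spatial
# and batch axes onto BLAS matrix products is a zero-copy `dim<-`.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL   # NULL = gradients disabled
.ad$flops <- NULL  # NULL = FLOP metering disabled

ad_node <- function(value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  class(nd) <- "ad_node"
  tp <- .ad$tape
  if (!is.null(tp) && !is.null(backward)) {
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes)) length(tp$nodes) <- 2L * length(tp$nodes)
    tp$nodes[[tp$n]] <- nd
  }
  nd
}

#' @keywords internal
ad_param <- function(dim, init = c("kaiming", "zero", "one"), fan_in = NULL) {
  init <- match.arg(init)
  nd <- ad_node(array(0, dim = dim))
  nd$is_param <- TRUE
  nd$init <- init
  nd$fan_in <- fan_in
  nd
}

nval <- function(x) if (inherits(x, "ad_node")) x$value else x

recording <- function() !is.null(.ad$tape)

acc_grad <- function(x, g) {
  if (!inherits(x, "ad_node")) return(invisible(NULL))
  if (is.null(x$grad)) x$grad <- g else x$grad <- x$grad + g
  invisible(NULL)
}

count_flops <- function(n) {
  fl <- .ad$flops
  if (!is.null(fl)) fl$total <- fl$total + n
  invisible(NULL)
}

# Run expr with a fresh tape; returns list(result, tape).
with_tape <- function(expr) {
  old <- .ad$tape
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  .ad$tape <- tp
  on.exit(.ad$tape <- old)
  res <- force(expr)
  list(result = res, tape = tp)
}

# Reverse sweep from a scalar loss node.
backward <- function(loss, tape) {
  stopifnot(inherits(loss, "ad_node"))
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  if (is.null(dim(loss$value))) loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad)) nd$backward(nd)
    # free intermediate state early; parameters keep their grads
    if (is.null(nd$is_param)) {
      nd$value <- NULL
      nd$grad <- NULL
      nd$backward <- NULL
      nd$parents <- NULL
    }
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Meter FLOPs of expr (forward only); returns list(result, flops).
with_flop_meter <- function(expr) {
  old <- .ad$flops
  fl <- new.env(parent = emptyenv())
  fl$total <- 0
  .ad$flops <- fl
  on.exit(.ad$flops <- old)
  res <- force(expr)
  list(result = res, flops = fl$total)
}
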