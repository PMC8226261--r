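# Minimal reverse-mode tape. Forward ops append nodes holding their output
# value and a backward closure; ag_backward replays the tape in reverse,
# accumulating gradients into upstream nodes and into layer parameters.
# This is deliberately small: the network topology is fixed, tensors are
# plain R arrays, and the heavy kernels live in src/kernels.cpp.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

# A node: $v value array, $g accumulated gradient (NULL until touched),
# $backward closure(g) propagating to inputs, $leaf marks network inputs
# whose gradient is never needed.
ag_node <- function(tape, value, backward = NULL, leaf = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$backward <- backward
  nd$leaf <- leaf
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * tape$n
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

ag_accum <- function(nd, g) {
  if (is.null(nd) || isTRUE(nd$leaf)) return(invisible(NULL))
  if (is.null(nd$g)) {
    # First contribution: keep a reference (may alias the caller's array).
    nd$g <- g
    nd$g_owned <- FALSE
  } else if (isTRUE(nd$g_owned)) {
    add_into_cpp(nd$g, g)   # uniquely owned: accumulate in place
  } else {
    nd$g <- nd$g + g        # allocate once; now uniquely owned
    nd$g_owned <- TRUE
  }
  invisible(NULL)
}

# Seed one or more node $g fields, then call this.
ag_backward <- function(tape) {
  if (tape$n == 0L) return(invisible(NULL))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$backward)) nd$backward(nd$g)
  }
  invisible(NULL)
}

# ---- parameters -----------------------------------------------------------

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$v <- value
  p$g <- NULL
  p$m <- NULL   # SGD momentum buffer
  p
}

param_accum <- function(p, g) {
  p$g <- if (is.null(p$g)) g else p$g + g
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# Classic momentum SGD: m <- mu*m + g ; w <- w - lr*m
sgd_update <- function(params, lr, momentum) {
  for (p in params) {
    if (is.null(p$g)) next
    if (is.null(p$m)) p$m <- p$g else p$m <- momentum * p$m + p$g
    p$v <- p$v - lr * p$m
  }
  invisible(NULL)
}
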