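# Minimal reverse-mode automatic differentiation over dense R arrays.
#
# A tensor is an environment holding a numeric array (`value`), an optional
# accumulated gradient (`grad`), the parent tensors it was computed from and
# a backward closure mapping the output gradient to a list of parent
# gradients. Tensors are created in topological order, so the strictly
# increasing `id` doubles as a topological key for the backward sweep.

.ng <- new.env(parent = emptyenv())
.ng$counter <- 0
.ng$grad_enabled <- TRUE

#' Create an autodiff tensor
#'
#' Wraps a numeric array (or matrix/scalar) in a node of the computation
#' graph. Users normally only create leaf tensors; operations build interior
#' nodes themselves.
#'
#' @param value numeric array, matrix or scalar.
#' @param requires_grad should gradients be accumulated into this leaf?
#' @param parents list of parent tensors (internal).
#' @param backward function(grad) -> list of parent gradients (internal).
#' @param name optional label used in error messages.
#' @return an object of class `ng_tensor`.
#' @export
ng_tensor <- function(value, requires_grad = FALSE, parents = list(),
                      backward = NULL, name = "") {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$parents <- parents
  t$backward <- backward
  t$name <- name
  t$requires_grad <- isTRUE(requires_grad) ||
    any(vapply(parents, function(p) isTRUE(p$requires_grad), logical(1)))
  .ng$counter <- .ng$counter + 1
  t$id <- .ng$counter
  class(t) <- "ng_tensor"
  t
}

is_tensor <- function(x) inherits(x, "ng_tensor")

#' @export
print.ng_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ng_tensor",
      if (is.null(d)) paste0("len=", length(x$value))
      else paste0("dim=[", paste(d, collapse = "x"), "]"),
      if (x$requires_grad) "grad" else "", ">\n")
  invisible(x)
}

# Internal node constructor used by every op. Under ng_no_grad() the graph is
# not recorded, which makes pure-inference forward passes cheap.
ng_node <- function(value, parents, backward, name = "") {
  if (!.ng$grad_enabled ||
      !any(vapply(parents, function(p) isTRUE(p$requires_grad), logical(1)))) {
    return(ng_tensor(value, requires_grad = FALSE, name = name))
  }
  ng_tensor(value, parents = parents, backward = backward, name = name)
}

#' Evaluate an expression without recording the autodiff graph
#'
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
ng_no_grad <- function(expr) {
  old <- .ng$grad_enabled
  .ng$grad_enabled <- FALSE
  on.exit(.ng$grad_enabled <- old)
  force(expr)
}

#' Detach a tensor from the graph
#'
#' Returns a new leaf tensor sharing the same value but receiving no
#' gradient; used e.g. for the critic update, where the generator output is
#' treated as a constant.
#'
#' @param x a tensor.
#' @return a gradient-free leaf tensor.
#' @export
ng_detach <- function(x) ng_tensor(x$value, requires_grad = FALSE)

accumulate_grad <- function(t, g) {
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(t)
}

#' Reverse-mode backward sweep
#'
#' Accumulates gradients of a scalar-valued tensor into every reachable leaf
#' with `requires_grad = TRUE`.
#'
#' @param loss a scalar tensor.
#' @param grad seed gradient, defaults to 1.
#' @export
ng_backward <- function(loss, grad = 1) {
  stopifnot(is_tensor(loss))
  if (length(loss$value) != 1)
    stop("ng_backward() expects a scalar loss tensor")
  # Collect the reachable subgraph that requires grad.
  nodes <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- format(nd$id, scientific = FALSE)
    if (!is.null(nodes[[key]])) next
    nodes[[key]] <- nd
    for (p in nd$parents) if (isTRUE(p$requires_grad)) stack[[length(stack) + 1]] <- p
  }
  ord <- ls(nodes)
  ids <- as.numeric(ord)
  ord <- ord[order(ids, decreasing = TRUE)]
  accumulate_grad(loss, grad)
  for (key in ord) {
    nd <- nodes[[key]]
    if (is.null(nd$backward) || is.null(nd$grad)) next
    pgrads <- nd$backward(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (isTRUE(p$requires_grad) && !is.null(pgrads[[i]]))
        accumulate_grad(p, pgrads[[i]])
    }
    # free interior gradients unless explicitly retained for inspection
    if (length(nd$parents) && !isTRUE(nd$retain)) nd$grad <- NULL
  }
  invisible(loss)
}

#' Clear accumulated gradients
#'
#' @param params list of tensors.
#' @export
ng_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
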