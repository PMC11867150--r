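# Generic dynamic programming over a history sDAG for edge-decomposable
# history weights.  A history weight g_f is the sum over a history's edges
# of an edge weight f(parent, child); since child clades of a node are
# independent choices, optima, counts and marginals all decompose as one
# bottom-up pass with O(|E|) evaluations of f.

#' Edge weight functions and ranking criteria
#'
#' An edge weight function maps a (parent, child) pair of sDAG node records
#' to a numeric value; for edges out of the UA node the parent is `NULL`.
#' A ranking criterion pairs an edge weight function with an optimization
#' direction.
#'
#' @param weight_fn Function `(parent, child) -> numeric`, where `parent`
#'   and `child` are node records (lists with `label` and `clades`) and
#'   `parent` is `NULL` on UA edges.
#' @param direction `"min"` or `"max"`.
#' @param name Optional display name.
#' @return An object of class `ranking_criterion`.
#' @export
ranking_criterion <- function(weight_fn, direction = c("min", "max"),
                              name = NULL) {
  direction <- match.arg(direction)
  structure(list(weight_fn = weight_fn, direction = direction,
                 name = if (is.null(name)) "criterion" else name),
            class = "ranking_criterion")
}

#' @export
print.ranking_criterion <- function(x, ...) {
  cat(sprintf("<ranking criterion: %s (%simize)>\n", x$name, x$direction))
  invisible(x)
}

# evaluate the per-node DP table: for each node key, the optimal total
# weight of any subtree (partial history) rooted there.
.dp_optimal <- function(dag, criterion) {
  f <- criterion$weight_fn
  best <- if (criterion$direction == "min") min else max
  val <- new.env(hash = TRUE, parent = emptyenv())
  for (k in .topo_keys(dag)) {
    node <- dag$nodes[[k]]
    if (length(node$clades) == 0L) {
      val[[k]] <- 0
      next
    }
    total <- 0
    for (i in seq_along(node$clades)) {
      childs <- dag$edges[[k]][[i]]
      w <- vapply(childs, function(c) {
        f(node, dag$nodes[[c]]) + val[[c]]
      }, numeric(1L))
      total <- total + best(w)
    }
    val[[k]] <- total
  }
  val
}

#' Optimal history weight in a history sDAG
#'
#' Computes the minimum (or maximum) over all expressed histories of the
#' edge-decomposable history weight, in one bottom-up pass.
#'
#' @param dag A `history_sdag`.
#' @param criterion A [ranking_criterion()].
#' @return Numeric scalar.
#' @export
optimal_weight <- function(dag, criterion) {
  stopifnot(inherits(criterion, "ranking_criterion"))
  if (length(dag$nodes) == 0L || length(dag$ua) == 0L) {
    stop("empty DAG", call. = FALSE)
  }
  val <- .dp_optimal(dag, criterion)
  f <- criterion$weight_fn
  best <- if (criterion$direction == "min") min else max
  best(vapply(dag$ua, function(k) f(NULL, dag$nodes[[k]]) + val[[k]],
              numeric(1L)))
}

#' Count the histories expressed by a history sDAG
#'
#' Exact count by dynamic programming: a node's subtree count is the
#' product over its child clades of the sum of its children's counts, and
#' the DAG's count is the sum over UA children.
#'
#' @param dag A `history_sdag`.
#' @return Numeric scalar (counts can exceed integer range).
#' @export
count_histories <- function(dag) {
  cnt <- new.env(hash = TRUE, parent = emptyenv())
  for (k in .topo_keys(dag)) {
    e <- dag$edges[[k]]
    if (length(e) == 0L) {
      cnt[[k]] <- 1
      next
    }
    cnt[[k]] <- prod(vapply(e, function(childs) {
      sum(vapply(childs, function(c) cnt[[c]], numeric(1L)))
    }, numeric(1L)))
  }
  sum(vapply(dag$ua, function(k) cnt[[k]], numeric(1L)))
}

#' Log marginal (sum over histories) of an edge-decomposed log weight
#'
#' Computes `log( sum_histories exp( sum_edges log_edge_fn(edge) ) )` by
#' sum-product dynamic programming with log-sum-exp stabilization.  With
#' `log_edge_fn` returning per-edge log-likelihoods this is the log
#' marginal likelihood over all histories in the DAG.
#'
#' @param dag A `history_sdag`.
#' @param log_edge_fn Function `(parent, child) -> numeric` (log scale);
#'   `parent` is `NULL` on UA edges.
#' @return Numeric scalar (log scale).
#' @export
marginalize <- function(dag, log_edge_fn) {
  lse <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
  }
  val <- new.env(hash = TRUE, parent = emptyenv())
  for (k in .topo_keys(dag)) {
    node <- dag$nodes[[k]]
    if (length(node$clades) == 0L) {
      val[[k]] <- 0
      next
    }
    total <- 0
    for (i in seq_along(node$clades)) {
      childs <- dag$edges[[k]][[i]]
      total <- total + lse(vapply(childs, function(c) {
        log_edge_fn(node, dag$nodes[[c]]) + val[[c]]
      }, numeric(1L)))
    }
    val[[k]] <- total
  }
  lse(vapply(dag$ua, function(k) log_edge_fn(NULL, dag$nodes[[k]]) + val[[k]],
             numeric(1L)))
}

#' Trim a history sDAG to weight-optimal histories
#'
#' Keeps exactly the edges participating in histories that attain the
#' optimal history weight: for each child clade of each node, edges whose
#' `f(edge) + subtree optimum` is within tolerance of the clade's optimum
#' survive, as do UA edges attaining the global optimum.  Ties keep all
#' tied edges.
#'
#' @param dag A `history_sdag`.
#' @param criterion A [ranking_criterion()].
#' @param tol Relative tolerance for treating real-valued weights as tied
#'   (`abs(w - opt) <= tol * max(1, abs(opt))`); keeps likelihood ties from
#'   being pruned by rounding noise.
#' @return A trimmed `history_sdag`.
#' @export
trim <- function(dag, criterion, tol = 1e-9) {
  stopifnot(inherits(criterion, "ranking_criterion"))
  f <- criterion$weight_fn
  best <- if (criterion$direction == "min") min else max
  val <- .dp_optimal(dag, criterion)
  tied <- function(w, opt) abs(w - opt) <= tol * max(1, abs(opt))
  edges <- lapply(names(dag$nodes), function(k) {
    node <- dag$nodes[[k]]
    lapply(seq_along(node$clades), function(i) {
      childs <- dag$edges[[k]][[i]]
      w <- vapply(childs, function(c) f(node, dag$nodes[[c]]) + val[[c]],
                  numeric(1L))
      childs[tied(w, best(w))]
    })
  })
  names(edges) <- names(dag$nodes)
  w_ua <- vapply(dag$ua, function(k) f(NULL, dag$nodes[[k]]) + val[[k]],
                 numeric(1L))
  ua <- dag$ua[tied(w_ua, best(w_ua))]
  .prune_sdag(.new_sdag(dag$nodes, edges, ua, dag$leaves, dag$seq_length))
}

#' Trim by several criteria in lexicographic order
#'
#' Equivalent to sequential [trim()] calls in descending order of
#' importance: the surviving histories are lexicographic optima.
#'
#' @param dag A `history_sdag`.
#' @param criteria List of [ranking_criterion()] objects, most important
#'   first.
#' @param tol Passed to [trim()].
#' @return A trimmed `history_sdag`.
#' @export
lexicographic_trim <- function(dag, criteria, tol = 1e-9) {
  stopifnot(length(criteria) >= 1L)
  for (cr in criteria) dag <- trim(dag, cr, tol = tol)
  dag
}

#' Linear combination of real edge weight functions
#'
#' Returns the edge weight function `f'(e) = sum_i coeffs[i] * fns[i](e)`;
#' the induced history weight is the same linear combination of the
#' individual history weights.
#'
#' @param fns List of edge weight functions.
#' @param coeffs Numeric vector, one coefficient per function.
#' @return An edge weight function.
#' @export
linear_combination <- function(fns, coeffs) {
  if (length(fns) != length(coeffs)) {
    stop("fns and coeffs must have equal length", call. = FALSE)
  }
  stopifnot(all(is.finite(coeffs)))
  force(fns); force(coeffs)
  function(parent, child) {
    sum(coeffs * vapply(fns, function(f) f(parent, child), numeric(1L)))
  }
}

#' History weight of a single history under an edge weight function
#'
#' Sums `f` over the history's edges, including the UA edge to the root
#' (with `parent = NULL`).  The tree is converted through a single-history
#' DAG so node records carry clade information.
#'
#' @param h A `history`.
#' @param weight_fn Edge weight function as in [ranking_criterion()].
#' @return Numeric scalar.
#' @export
history_weight <- function(h, weight_fn) {
  dag <- from_histories(list(h))
  total <- 0
  for (k in names(dag$nodes)) {
    node <- dag$nodes[[k]]
    for (childs in dag$edges[[k]]) {
      for (c in childs) total <- total + weight_fn(node, dag$nodes[[c]])
    }
  }
  total + weight_fn(NULL, dag$nodes[[dag$ua]])
}
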