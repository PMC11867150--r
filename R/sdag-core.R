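# Core data structures: histories (rooted trees with sequence-labelled
# nodes) and the history sDAG that stores collections of them.
#
# A history node is identified by the pair (label, child clade set): the
# label is a nucleotide sequence, and each child clade is the set of leaf
# labels reachable beneath one of the node's children.  A history sDAG is
# the graph union of histories over a shared leaf set, rooted below a
# formal universal-ancestor (UA) node so that the choice of history root is
# itself an edge choice.

# ---------------------------------------------------------------------------
# internal key helpers: node identity is (label, child clades) with clades
# canonically sorted.  Labels are DNA strings, so "," and ";" are safe
# separators.

.clade_key <- function(labels) paste(sort(labels), collapse = ",")

.node_key <- function(label, clade_keys) {
  paste0(label, "|", paste(sort(clade_keys), collapse = ";"))
}

.LEAF_CLADES <- list()

#' Create a history node
#'
#' A history is a rooted tree in which every node carries a full nucleotide
#' sequence as its label.  Leaves carry observed sequences; internal nodes
#' carry inferred ancestral sequences.  Nodes are plain nested lists; the
#' root carries class `"history"`.
#'
#' @param label Character scalar, the node's nucleotide sequence.
#' @param children List of child history nodes (empty for a leaf).
#' @return A history node; pass the root through [as_history()] to obtain a
#'   classed history object.
#' @export
history_node <- function(label, children = list()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  list(label = label, children = children)
}

#' Mark the root of a node tree as a history
#' @param x A history node (root of a tree built with [history_node()]).
#' @return `x` with class `"history"`.
#' @export
as_history <- function(x) {
  stopifnot(is.list(x), !is.null(x$label))
  class(x) <- "history"
  x
}

#' @export
print.history <- function(x, ...) {
  nl <- length(history_leaf_labels(x))
  cat(sprintf("<history: %d leaves, %d nodes, sequence length %d>\n",
              nl, .count_nodes(x), nchar(x$label)))
  invisible(x)
}

.count_nodes <- function(node) {
  1L + sum(vapply(node$children, .count_nodes, integer(1L)))
}

#' Leaf labels of a history (or subtree)
#' @param node A history node.
#' @return Character vector of leaf labels, in tree order.
#' @export
history_leaf_labels <- function(node) {
  if (length(node$children) == 0L) return(node$label)
  unlist(lapply(node$children, history_leaf_labels), use.names = FALSE)
}

# canonical string form of a history (children sorted recursively); two
# histories are equal iff their keys are equal
.history_key <- function(node) {
  if (length(node$children) == 0L) return(node$label)
  paste0(node$label, "(",
         paste(sort(vapply(node$children, .history_key, character(1L))),
               collapse = ","), ")")
}

# All (parent, child) label pairs of a history, excluding the implicit
# UA -> root edge.  Returns a list of list(parent=, child=) label pairs.
history_edge_labels <- function(node) {
  out <- list()
  for (ch in node$children) {
    out[[length(out) + 1L]] <- list(parent = node$label, child = ch$label)
    out <- c(out, history_edge_labels(ch))
  }
  out
}

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.is_unambiguous <- function(seqs) {
  !grepl("[^ACGT]", seqs)
}

.check_label <- function(label) {
  if (grepl(sprintf("[^%s]", paste(names(.IUPAC), collapse = "")), label)) {
    stop("invalid characters in sequence label: ", label, call. = FALSE)
  }
}

validate_history <- function(h) {
  labs <- .all_labels(h)
  lapply(labs, .check_label)
  if (length(unique(nchar(labs))) != 1L) {
    stop("all labels in a history must have equal length", call. = FALSE)
  }
  lv <- history_leaf_labels(h)
  if (anyDuplicated(lv)) {
    stop("leaf labels must be unique within a history", call. = FALSE)
  }
  if (!all(.is_unambiguous(lv))) {
    stop("leaf labels must not contain ambiguity codes", call. = FALSE)
  }
  .check_arity <- function(node) {
    if (length(node$children) == 1L) {
      stop("internal history nodes must have >= 2 children (no unary nodes)",
           call. = FALSE)
    }
    lapply(node$children, .check_arity)
    invisible(NULL)
  }
  .check_arity(h)
  invisible(h)
}

.all_labels <- function(node) {
  c(node$label, unlist(lapply(node$children, .all_labels), use.names = FALSE))
}

# ---------------------------------------------------------------------------
# history sDAG object

.new_sdag <- function(nodes, edges, ua, leaves, seq_length) {
  structure(
    list(nodes = nodes, edges = edges, ua = ua,
         leaves = leaves, seq_length = seq_length),
    class = "history_sdag"
  )
}

#' @export
print.history_sdag <- function(x, ...) {
  cat(sprintf(
    "<history sDAG: %d leaves, %d nodes, %d edges, %s histories>\n",
    length(x$leaves), length(x$nodes), .n_edges(x),
    format(count_histories(x))))
  invisible(x)
}

.n_edges <- function(dag) {
  length(dag$ua) +
    sum(vapply(dag$edges, function(e) sum(lengths(e)), numeric(1L)))
}

#' Clade union of a history-sDAG node
#'
#' The clade union CU(v) of a node is the set of all leaf labels reachable
#' below it: the node's own label for a leaf, and the union of its child
#' clades for an internal node.
#'
#' @param node A node record from `dag$nodes`, or any list with `label` and
#'   `clades` fields (`clades` a list of character vectors; empty for a
#'   leaf).
#' @return Character vector of leaf labels (sorted).
#' @export
clade_union <- function(node) {
  if (length(node$clades) == 0L) return(node$label)
  sort(unique(unlist(node$clades, use.names = FALSE)))
}

# build a node record and register it (env-based builders used internally)
.make_node_record <- function(label, clades) {
  ck <- vapply(clades, .clade_key, character(1L))
  ord <- order(ck)
  clades <- clades[ord]
  ck <- ck[ord]
  list(label = label, clades = clades, clade_keys = ck,
       key = .node_key(label, ck))
}

#' Build a history sDAG as the graph union of histories
#'
#' The node set of the result is the union of the input histories' node
#' sets, and likewise for edges; node identity is the (label, child clades)
#' pair, so substructure shared between histories is stored once.  Every
#' input history can be extracted from the result, and recombination of
#' shared substructure typically makes additional histories extractable.
#'
#' @param histories A list of history objects (or a single history) sharing
#'   one leaf label set, with equal-length sequences.
#' @return A `history_sdag`.
#' @export
from_histories <- function(histories) {
  if (inherits(histories, "history")) histories <- list(histories)
  stopifnot(length(histories) >= 1L)
  for (h in histories) validate_history(h)
  leaf_sets <- lapply(histories, function(h) sort(history_leaf_labels(h)))
  if (length(unique(vapply(leaf_sets, paste, character(1L),
                           collapse = ","))) != 1L) {
    stop("all histories must share the same leaf label set", call. = FALSE)
  }
  lens <- vapply(histories, function(h) nchar(h$label), integer(1L))
  if (length(unique(lens)) != 1L) {
    stop("all histories must have equal sequence length", call. = FALSE)
  }
  nodes <- new.env(hash = TRUE, parent = emptyenv())
  edges <- new.env(hash = TRUE, parent = emptyenv())
  ua <- character(0L)

  add_node <- function(tree_node) {
    if (length(tree_node$children) == 0L) {
      rec <- .make_node_record(tree_node$label, .LEAF_CLADES)
      if (is.null(nodes[[rec$key]])) {
        nodes[[rec$key]] <- rec
        edges[[rec$key]] <- list()
      }
      return(list(key = rec$key, cu = tree_node$label))
    }
    kids <- lapply(tree_node$children, add_node)
    clades <- lapply(kids, function(k) sort(k$cu))
    ck <- vapply(clades, .clade_key, character(1L))
    if (anyDuplicated(ck)) {
      stop("child clades of a node must be disjoint (duplicate leaf sets)",
           call. = FALSE)
    }
    rec <- .make_node_record(tree_node$label, clades)
    if (is.null(nodes[[rec$key]])) {
      nodes[[rec$key]] <- rec
      edges[[rec$key]] <- rep(list(character(0L)), length(rec$clades))
    }
    # attach child edges in canonical clade order
    e <- edges[[rec$key]]
    for (i in seq_along(kids)) {
      slot <- match(.clade_key(clades[[i]]), rec$clade_keys)
      if (!kids[[i]]$key %in% e[[slot]]) {
        e[[slot]] <- c(e[[slot]], kids[[i]]$key)
      }
    }
    edges[[rec$key]] <- e
    list(key = rec$key, cu = sort(unique(unlist(clades, use.names = FALSE))))
  }

  for (h in histories) {
    r <- add_node(h)
    ua <- union(ua, r$key)
  }
  .new_sdag(as.list(nodes), as.list(edges), sort(ua),
            leaf_sets[[1L]], nchar(histories[[1L]]$label))
}

#' Number of leaves / nodes helpers
#' @param dag A `history_sdag`.
#' @return `sdag_node_keys`: character vector of node keys.
#' @keywords internal
sdag_node_keys <- function(dag) names(dag$nodes)

.is_leaf_key <- function(dag, key) length(dag$nodes[[key]]$clades) == 0L

# topological order: children before parents.  Every edge strictly
# decreases clade-union size (unary internal nodes are disallowed), so
# ordering node keys by |CU| ascending is a valid topological order.
.topo_keys <- function(dag) {
  sz <- vapply(dag$nodes, function(n) {
    if (length(n$clades) == 0L) 1L else length(unlist(n$clades))
  }, integer(1L))
  names(sort(sz))
}

#' Enumerate all histories expressed by a history sDAG
#'
#' A history is extracted by choosing one child of the UA node, then one
#' outgoing edge for each child clade of each chosen node, recursively.
#' Each distinct history is produced exactly once.
#'
#' @param dag A `history_sdag`.
#' @param max_histories Abort with an error if more than this many
#'   histories would be produced (guards combinatorial blow-up).
#' @return List of `history` objects.
#' @export
enumerate_histories <- function(dag, max_histories = 1e6) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  expand <- function(key) {
    if (!is.null(memo[[key]])) return(memo[[key]])
    node <- dag$nodes[[key]]
    if (length(node$clades) == 0L) {
      res <- list(history_node(node$label))
    } else {
      per_clade <- lapply(dag$edges[[key]], function(childs) {
        do.call(c, lapply(childs, expand))
      })
      counts <- lengths(per_clade)
      if (any(counts == 0L)) stop("malformed DAG: dead-end clade at ", key)
      if (prod(counts) > max_histories) {
        stop("history enumeration exceeds max_histories cap", call. = FALSE)
      }
      idx <- do.call(expand.grid, lapply(counts, seq_len))
      res <- lapply(seq_len(nrow(idx)), function(r) {
        history_node(node$label,
                     lapply(seq_along(per_clade),
                            function(i) per_clade[[i]][[idx[r, i]]]))
      })
    }
    memo[[key]] <- res
    res
  }
  out <- list()
  for (k in dag$ua) {
    out <- c(out, lapply(expand(k), as_history))
    if (length(out) > max_histories) {
      stop("history enumeration exceeds max_histories cap", call. = FALSE)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# ambiguity expansion

.disambiguate_label <- function(label, cap) {
  chars <- strsplit(label, "", fixed = TRUE)[[1L]]
  alts <- .IUPAC[chars]
  n <- prod(lengths(alts))
  if (n > cap) {
    stop("ambiguity expansion of one node exceeds cap (", format(n), " > ",
         format(cap), ")", call. = FALSE)
  }
  if (n == 1L) return(label)
  amb <- which(lengths(alts) > 1L)
  grid <- do.call(expand.grid, c(alts[amb], list(stringsAsFactors = FALSE)))
  vapply(seq_len(nrow(grid)), function(r) {
    chars[amb] <- as.character(grid[r, ])
    paste(chars, collapse = "")
  }, character(1L))
}

#' Expand ambiguity codes in internal node labels
#'
#' Every internal node whose label contains IUPAC ambiguity codes is
#' replaced by one node per concrete disambiguation (per-site Cartesian
#' product over the code's alternatives), each inheriting all incident
#' edges.  Leaf labels must already be unambiguous.  After expansion the
#' DAG expresses every input history under every possible disambiguation of
#' its ancestral labels; trimming to maximum parsimony afterwards restores
#' the maximally parsimonious subset.
#'
#' @param dag A `history_sdag`.
#' @param max_expansion Per-node cap on the number of disambiguations;
#'   exceeding it raises an error (combinatorial blow-up) rather than
#'   silently truncating.
#' @return A `history_sdag` with unambiguous labels.
#' @export
expand_ambiguities <- function(dag, max_expansion = 1e5) {
  key_map <- new.env(hash = TRUE, parent = emptyenv())
  nodes <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(dag$nodes)) {
    node <- dag$nodes[[k]]
    if (length(node$clades) == 0L) {
      nodes[[k]] <- node
      key_map[[k]] <- k
      next
    }
    labs <- .disambiguate_label(node$label, max_expansion)
    new_keys <- character(length(labs))
    for (i in seq_along(labs)) {
      rec <- .make_node_record(labs[[i]], node$clades)
      nodes[[rec$key]] <- rec
      new_keys[[i]] <- rec$key
    }
    key_map[[k]] <- new_keys
  }
  edges <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(dag$nodes)) {
    for (nk in key_map[[k]]) {
      e_new <- lapply(dag$edges[[k]], function(childs) {
        sort(unique(unlist(lapply(childs, function(c) key_map[[c]]),
                           use.names = FALSE)))
      })
      if (is.null(edges[[nk]])) {
        edges[[nk]] <- e_new
      } else if (length(e_new) > 0L) {
        edges[[nk]] <- lapply(seq_along(e_new), function(i) {
          sort(union(edges[[nk]][[i]], e_new[[i]]))
        })
      }
    }
  }
  ua <- sort(unique(unlist(lapply(dag$ua, function(k) key_map[[k]]),
                           use.names = FALSE)))
  .new_sdag(as.list(nodes), as.list(edges), ua, dag$leaves, dag$seq_length)
}

# ---------------------------------------------------------------------------
# completion

#' Add all structurally allowed edges to a history sDAG
#'
#' An edge from parent `vp` to child `vc` is allowed exactly when the clade
#' union of `vc` equals one of the child clades of `vp`; completion installs
#' every such edge, and connects the UA node to every node whose clade
#' union is the full leaf set.  The node set is unchanged; nodes left with
#' an empty clade or unreachable from the UA node are pruned.
#'
#' @param dag A `history_sdag`.
#' @return A completed `history_sdag`.
#' @export
complete <- function(dag) {
  cu_index <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(dag$nodes)) {
    cu <- .clade_key(clade_union(dag$nodes[[k]]))
    cu_index[[cu]] <- c(cu_index[[cu]], k)
  }
  edges <- lapply(names(dag$nodes), function(k) {
    node <- dag$nodes[[k]]
    lapply(node$clade_keys, function(ck) {
      cand <- cu_index[[ck]]
      if (is.null(cand)) character(0L) else sort(cand)
    })
  })
  names(edges) <- names(dag$nodes)
  full <- cu_index[[.clade_key(dag$leaves)]]
  ua <- if (is.null(full)) character(0L) else sort(full)
  .prune_sdag(.new_sdag(dag$nodes, edges, ua, dag$leaves, dag$seq_length))
}

# remove dead-end nodes (a clade with no outgoing edge) and nodes
# unreachable from the UA node; iterate to a fixed point.
.prune_sdag <- function(dag) {
  nodes <- dag$nodes
  edges <- dag$edges
  ua <- dag$ua
  repeat {
    bad <- names(nodes)[vapply(names(nodes), function(k) {
      e <- edges[[k]]
      length(e) > 0L && any(lengths(e) == 0L)
    }, logical(1L))]
    if (length(bad) == 0L) break
    nodes[bad] <- NULL
    edges[bad] <- NULL
    ua <- setdiff(ua, bad)
    edges <- lapply(edges, function(e) lapply(e, function(ch) setdiff(ch, bad)))
  }
  if (length(ua) == 0L) {
    stop("DAG expresses no histories after pruning", call. = FALSE)
  }
  # reachability from UA
  seen <- new.env(hash = TRUE, parent = emptyenv())
  stack <- ua
  while (length(stack) > 0L) {
    k <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (!is.null(seen[[k]])) next
    seen[[k]] <- TRUE
    stack <- c(stack, unlist(edges[[k]], use.names = FALSE))
  }
  keep <- intersect(names(nodes), ls(seen))
  .new_sdag(nodes[keep], edges[keep], ua, dag$leaves, dag$seq_length)
}

# ---------------------------------------------------------------------------
# collapse

#' Collapse zero-mutation internal edges
#'
#' Removes internal edges whose parent and child carry identical labels, by
#' merging the child's clades into the parent, so that multifurcations
#' unsupported by the data are not stored as arbitrary resolutions.  Edges
#' from a node to a same-labelled *leaf* are retained: they record that an
#' ancestral genotype was itself observed.  Labels must be unambiguous.
#'
#' The construction is a memoized bottom-up rewrite: each original node
#' maps to the set of collapsed nodes it can become (one per combination of
#' merge/keep decisions across its clades), and the resulting DAG expresses
#' exactly the collapses of the original DAG's histories.
#'
#' @param dag A `history_sdag` with unambiguous labels.
#' @return A collapsed `history_sdag`.
#' @export
collapse_sdag <- function(dag) {
  labs <- vapply(dag$nodes, `[[`, character(1L), "label")
  if (!all(.is_unambiguous(labs))) {
    stop("collapse requires unambiguous labels; run expand_ambiguities first",
         call. = FALSE)
  }
  nodes <- new.env(hash = TRUE, parent = emptyenv())
  edges <- new.env(hash = TRUE, parent = emptyenv())
  memo <- new.env(hash = TRUE, parent = emptyenv())

  register <- function(rec, e) {
    if (is.null(nodes[[rec$key]])) {
      nodes[[rec$key]] <- rec
      edges[[rec$key]] <- e
    } else if (length(e) > 0L) {
      edges[[rec$key]] <- lapply(seq_along(e), function(i) {
        sort(union(edges[[rec$key]][[i]], e[[i]]))
      })
    }
    rec$key
  }

  collapse_node <- function(key) {
    if (!is.null(memo[[key]])) return(memo[[key]])
    node <- dag$nodes[[key]]
    if (length(node$clades) == 0L) {
      res <- register(node, list())
      memo[[key]] <- res
      return(res)
    }
    # per-clade options: each option is a fragment contributing one or more
    # (clade, child-set) slots to the merged node
    options_per_clade <- lapply(seq_along(node$clades), function(i) {
      alt <- unique(unlist(lapply(dag$edges[[key]][[i]], collapse_node),
                           use.names = FALSE))
      is_mergeable <- vapply(alt, function(a) {
        rec <- nodes[[a]]
        length(rec$clades) > 0L && rec$label == node$label
      }, logical(1L))
      opts <- list()
      keepers <- alt[!is_mergeable]
      if (length(keepers) > 0L) {
        opts[[length(opts) + 1L]] <- list(
          clades = node$clades[i], targets = list(sort(keepers)))
      }
      for (m in alt[is_mergeable]) {
        opts[[length(opts) + 1L]] <- list(
          clades = nodes[[m]]$clades, targets = edges[[m]])
      }
      opts
    })
    counts <- lengths(options_per_clade)
    idx <- do.call(expand.grid, lapply(counts, seq_len))
    res <- character(0L)
    for (r in seq_len(nrow(idx))) {
      frags <- lapply(seq_along(options_per_clade), function(i) {
        options_per_clade[[i]][[idx[r, i]]]
      })
      clades <- do.call(c, lapply(frags, `[[`, "clades"))
      targets <- do.call(c, lapply(frags, `[[`, "targets"))
      ck <- vapply(clades, .clade_key, character(1L))
      ord <- order(ck)
      rec <- .make_node_record(node$label, clades)
      res <- c(res, register(rec, targets[ord]))
    }
    res <- unique(res)
    memo[[key]] <- res
    res
  }

  ua <- sort(unique(unlist(lapply(dag$ua, collapse_node), use.names = FALSE)))
  .prune_sdag(.new_sdag(as.list(nodes), as.list(edges), ua,
                        dag$leaves, dag$seq_length))
}

#' Collapse zero-mutation internal edges of a single history
#'
#' Tree-level counterpart of [collapse_sdag()]: contracts every internal
#' edge whose endpoints share a label, iterating to the (unique) fixed
#' point.
#'
#' @param h A `history` with unambiguous labels.
#' @return A collapsed `history`.
#' @export
collapse_history <- function(h) {
  walk <- function(node) {
    kids <- lapply(node$children, walk)
    out <- list()
    for (ch in kids) {
      if (length(ch$children) > 0L && ch$label == node$label) {
        out <- c(out, ch$children)
      } else {
        out[[length(out) + 1L]] <- ch
      }
    }
    history_node(node$label, out)
  }
  as_history(walk(h))
}

# ---------------------------------------------------------------------------
# validation used by tests

#' Check history-sDAG structural invariants
#'
#' Asserts acyclicity (via the strict clade-union-size decrease along
#' edges), the clade-consistency condition that every edge's child clade
#' union matches one of its parent's child clades, absence of dead-end
#' clades, and that every UA child spans the full leaf set.
#'
#' @param dag A `history_sdag`.
#' @return Invisibly, `dag`; errors describe the violated invariant.
#' @export
validate_sdag <- function(dag) {
  stopifnot(inherits(dag, "history_sdag"))
  if (length(dag$ua) == 0L) stop("DAG has no UA edges")
  full <- .clade_key(dag$leaves)
  for (k in dag$ua) {
    if (.clade_key(clade_union(dag$nodes[[k]])) != full) {
      stop("UA child does not span the full leaf set: ", k)
    }
  }
  for (k in names(dag$nodes)) {
    node <- dag$nodes[[k]]
    e <- dag$edges[[k]]
    if (length(e) != length(node$clades)) stop("edge/clade arity mismatch: ", k)
    if (length(node$clades) == 1L) stop("unary internal node: ", k)
    for (i in seq_along(e)) {
      if (length(e[[i]]) == 0L) stop("dead-end clade at node ", k)
      for (c in e[[i]]) {
        child <- dag$nodes[[c]]
        if (is.null(child)) stop("edge to unknown node from ", k)
        if (.clade_key(clade_union(child)) != node$clade_keys[[i]]) {
          stop("edge violates clade consistency at node ", k)
        }
      }
    }
  }
  invisible(dag)
}
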