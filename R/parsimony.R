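# Parsimony: Hamming edge weights, small-parsimony ancestral state
# reconstruction (per-site 0/1-cost Sankoff with an up-down pass, encoded
# as IUPAC ambiguity codes), and an exhaustive maximum-parsimony tree
# generator for tiny leaf sets, standing in for an external parsimony
# search at desk scale.

.BIT_OF <- c(A = 1L, C = 2L, G = 4L, T = 8L,
             R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
             B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)
.CODE_OF <- character(15L)
.CODE_OF[.BIT_OF] <- names(.BIT_OF)

.seq_bits <- function(s) {
  unname(.BIT_OF[strsplit(s, "", fixed = TRUE)[[1L]]])
}

.bits_seq <- function(bits) paste(.CODE_OF[bits], collapse = "")

#' Hamming distance between two equal-length sequences
#'
#' The parsimony weight of an edge: the number of sites at which the
#' parent and child labels differ.
#'
#' @param parent,child Character scalars (unambiguous, equal length).
#' @return Non-negative integer.
#' @export
hamming_edge_weight <- function(parent, child) {
  if (nchar(parent) != nchar(child)) {
    stop("sequence length mismatch", call. = FALSE)
  }
  a <- utf8ToInt(parent)
  sum(a != utf8ToInt(child))
}

#' Parsimony ranking criterion
#'
#' Edge-decomposed parsimony: each edge weighs the Hamming distance between
#' its endpoint labels, UA edges weigh 0, and the history weight is the
#' parsimony score.  Direction is minimization.
#'
#' @return A [ranking_criterion()].
#' @export
parsimony_criterion <- function() {
  ranking_criterion(
    function(parent, child) {
      if (is.null(parent)) 0 else hamming_edge_weight(parent$label, child$label)
    },
    direction = "min", name = "parsimony"
  )
}

#' Parsimony score of a history
#' @param h A `history`.
#' @return Total Hamming distance summed over edges.
#' @export
parsimony_score <- function(h) {
  total <- 0L
  for (e in history_edge_labels(h)) {
    total <- total + hamming_edge_weight(e$parent, e$child)
  }
  total
}

# ---------------------------------------------------------------------------
# small parsimony on a fixed topology

# Topologies are nested lists whose leaves are character scalars naming
# entries of a named sequence vector; internal nodes are lists of >= 2
# subtopologies.

#' Maximum-parsimony ancestral states on a fixed topology
#'
#' Runs per-site 0/1-cost Sankoff dynamic programming up and down the tree
#' and assigns to every internal node, at every site, the set of states
#' that occur in at least one maximally parsimonious labelling of the
#' topology, encoded as an IUPAC ambiguity code.  Expanding these codes and
#' trimming to minimum parsimony therefore yields exactly the MP labellings
#' of the topology.
#'
#' @param topology Nested list; leaves are names into `leaf_sequences`,
#'   internal nodes are lists of two or more subtopologies.
#' @param leaf_sequences Named character vector of equal-length unambiguous
#'   sequences.
#' @return A `history` with ambiguity-coded internal labels; attribute
#'   `"score"` carries the parsimony score of the topology.
#' @export
fitch_ancestors <- function(topology, leaf_sequences) {
  if (!all(.is_unambiguous(leaf_sequences))) {
    stop("leaf sequences must be unambiguous A/C/G/T", call. = FALSE)
  }
  if (length(unique(nchar(leaf_sequences))) != 1L) {
    stop("leaf sequences must have equal length", call. = FALSE)
  }
  L <- nchar(leaf_sequences[[1L]])
  BIG <- 1e9

  # cost_up[[node]]: 4 x L matrix of minimal subtree cost given state
  up <- function(node) {
    if (is.character(node)) {
      if (!node %in% names(leaf_sequences)) stop("unknown leaf name: ", node)
      s <- leaf_sequences[[node]]
      bits <- .seq_bits(s)
      cost <- matrix(BIG, 4L, L)
      for (b in 1:4) cost[b, bitwAnd(bits, bitwShiftL(1L, b - 1L)) != 0L] <- 0
      return(list(leaf = node, cost = cost))
    }
    kids <- lapply(node, up)
    cost <- matrix(0, 4L, L)
    for (k in kids) {
      m <- apply(k$cost, 2L, min)
      contrib <- pmin(k$cost, rep(m + 1, each = 4L))
      cost <- cost + contrib
    }
    list(children = kids, cost = cost)
  }

  root <- up(topology)
  score <- sum(apply(root$cost, 2L, min))

  # downward pass: dn[[node]]: 4 x L matrix of minimal cost of the rest of
  # the tree given this node's state
  down <- function(node, dn) {
    node$down <- dn
    total <- node$cost + dn
    site_min <- apply(total, 2L, min)
    viable <- total <= rep(site_min, each = 4L) + 1e-9
    bits <- colSums(viable * c(1L, 2L, 4L, 8L))
    node$bits <- as.integer(bits)
    if (!is.null(node$leaf)) return(node)
    for (i in seq_along(node$children)) {
      # cost of everything above child i given parent state:
      # dn(parent) + sum of sibling contributions
      a <- dn
      for (j in seq_along(node$children)) {
        if (j == i) next
        kc <- node$children[[j]]$cost
        m <- apply(kc, 2L, min)
        a <- a + pmin(kc, rep(m + 1, each = 4L))
      }
      am <- apply(a, 2L, min)
      child_dn <- pmin(a, rep(am + 1, each = 4L))
      node$children[[i]] <- down(node$children[[i]], child_dn)
    }
    node
  }
  root <- down(root, matrix(0, 4L, L))

  build <- function(node) {
    if (!is.null(node$leaf)) return(history_node(leaf_sequences[[node$leaf]]))
    history_node(.bits_seq(node$bits), lapply(node$children, build))
  }
  h <- as_history(build(root))
  attr(h, "score") <- score
  h
}

# ---------------------------------------------------------------------------
# exhaustive topology enumeration

# all rooted binary topologies on leaves 1..n, as nested integer lists;
# there are (2n-3)!! of them
.all_rooted_topologies <- function(n) {
  trees <- list(1L)
  if (n == 1L) return(trees)
  for (k in 2:n) {
    nxt <- vector("list", length(trees) * (2L * (k - 1L) - 1L))
    pos <- 0L
    for (tr in trees) {
      for (variant in .insert_everywhere(tr, k)) {
        pos <- pos + 1L
        nxt[[pos]] <- variant
      }
    }
    trees <- nxt
  }
  trees
}

# insert leaf `k` above every node of `tree` (including the root)
.insert_everywhere <- function(tree, k) {
  out <- list(list(tree, k))
  if (is.list(tree)) {
    for (i in seq_along(tree)) {
      for (sub in .insert_everywhere(tree[[i]], k)) {
        t2 <- tree
        t2[[i]] <- sub
        out[[length(out) + 1L]] <- t2
      }
    }
  }
  out
}

# fast per-topology Fitch score, bit-encoded and vectorized over sites
.fitch_score <- function(tree, bit_list) {
  rec <- function(node) {
    if (!is.list(node)) return(list(mask = bit_list[[node]], steps = 0L))
    acc <- NULL
    steps <- 0L
    for (ch in node) {
      r <- rec(ch)
      steps <- steps + r$steps
      if (is.null(acc)) {
        acc <- r$mask
      } else {
        inter <- bitwAnd(acc, r$mask)
        miss <- inter == 0L
        steps <- steps + sum(miss)
        acc <- ifelse(miss, bitwOr(acc, r$mask), inter)
      }
    }
    list(mask = acc, steps = steps)
  }
  rec(tree)$steps
}

#' All maximum-parsimony histories for a small set of sequences
#'
#' Enumerates every rooted binary topology on the given (unique) leaf
#' sequences, scores each by Fitch parsimony, and for every topology
#' attaining the minimum score reconstructs all maximally parsimonious
#' ancestral labellings.  Intended as a fixture generator standing in for
#' an external parsimony search program at desk scale; the number of
#' topologies grows as (2n-3)!!, so the leaf count is capped.
#'
#' @param leaf_sequences Character vector of distinct, equal-length,
#'   unambiguous sequences.
#' @param max_leaves Refuse instances with more than this many leaves.
#' @param max_histories Cap passed to the disambiguation enumeration.
#' @return List of `history` objects, each with unambiguous labels and the
#'   globally minimal parsimony score.
#' @export
exhaustive_mp_trees <- function(leaf_sequences, max_leaves = 8L,
                                max_histories = 1e5) {
  leaf_sequences <- unname(leaf_sequences)
  if (anyDuplicated(leaf_sequences)) {
    stop("leaf sequences must be distinct (aggregate duplicates upstream)",
         call. = FALSE)
  }
  n <- length(leaf_sequences)
  if (n > max_leaves) {
    stop("too many leaves for exhaustive enumeration (", n, " > ",
         max_leaves, ")", call. = FALSE)
  }
  names(leaf_sequences) <- paste0("s", seq_len(n))
  if (n == 1L) {
    stop("need at least two sequences", call. = FALSE)
  }
  bit_list <- lapply(leaf_sequences, .seq_bits)
  names(bit_list) <- NULL
  topos <- .all_rooted_topologies(n)
  scores <- vapply(topos, .fitch_score, integer(1L), bit_list = bit_list)
  s_min <- min(scores)
  # convert an integer-leaf nested topology into a named one
  to_named <- function(node) {
    if (!is.list(node)) return(names(leaf_sequences)[[node]])
    lapply(node, to_named)
  }
  out <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (tp in topos[scores == s_min]) {
    h <- fitch_ancestors(to_named(tp), leaf_sequences)
    dag <- expand_ambiguities(from_histories(list(h)))
    dag <- trim(dag, parsimony_criterion())
    for (hist in enumerate_histories(dag, max_histories = max_histories)) {
      key <- .history_key(hist)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- hist
      }
    }
  }
  out
}
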