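# Tree-comparison metrics: the MRCA sequence distance (which scores
# ancestral sequence reconstruction, not just topology) and a standard
# Robinson-Foulds implementation for cross-checks.

# list of all nodes of a history with their leaf sets (character vectors)
.node_leafsets <- function(h) {
  out <- list()
  walk <- function(node) {
    if (length(node$children) == 0L) {
      ls <- node$label
    } else {
      ls <- sort(unique(unlist(lapply(node$children, walk),
                               use.names = FALSE)))
    }
    out[[length(out) + 1L]] <<- list(label = node$label, leaves = ls)
    ls
  }
  walk(h)
  out
}

# label of the most recent common ancestor of two leaves: the node with
# the smallest leaf set containing both (unique since unary nodes are
# disallowed)
.mrca_label <- function(leafsets, a, b) {
  best <- NULL
  best_size <- Inf
  for (ns in leafsets) {
    if (length(ns$leaves) < best_size &&
        a %in% ns$leaves && b %in% ns$leaves) {
      best <- ns$label
      best_size <- length(ns$leaves)
    }
  }
  if (is.null(best)) stop("leaves not found in tree: ", a, ", ", b)
  best
}

#' MRCA sequence distance between a true and an inferred history
#'
#' For every unordered pair of taxa, the Hamming distance between the true
#' and inferred MRCA node sequences is divided by the mean Hamming
#' distance between each of the two taxa and the true MRCA sequence; the
#' metric is the sum of these terms over all pairs.  Because the MRCA of a
#' pair is unique on any tree, the metric is well defined in the presence
#' of multifurcations.  Pairs whose denominator is zero (both taxa
#' identical to their true MRCA sequence) are skipped and counted in the
#' `n_pairs_skipped` attribute; pairs with a zero numerator contribute 0.
#'
#' @param true_history,inferred_history `history` objects with identical
#'   leaf label sets and all node sequences present.
#' @return Numeric scalar: the pair sum.  Attributes: `mean` (per-pair
#'   mean over non-skipped pairs), `n_pairs`, `n_pairs_skipped`.
#' @export
mrca_distance <- function(true_history, inferred_history) {
  lv_t <- sort(history_leaf_labels(true_history))
  lv_i <- sort(history_leaf_labels(inferred_history))
  if (!identical(lv_t, lv_i)) {
    stop("histories must share the same leaf label set", call. = FALSE)
  }
  ls_t <- .node_leafsets(true_history)
  ls_i <- .node_leafsets(inferred_history)
  n <- length(lv_t)
  total <- 0
  n_pairs <- 0L
  n_skip <- 0L
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        a <- lv_t[[i]]
        b <- lv_t[[j]]
        mt <- .mrca_label(ls_t, a, b)
        mi <- .mrca_label(ls_i, a, b)
        denom <- (hamming_edge_weight(a, mt) + hamming_edge_weight(b, mt)) / 2
        if (denom == 0) {
          n_skip <- n_skip + 1L
          next
        }
        n_pairs <- n_pairs + 1L
        total <- total + hamming_edge_weight(mt, mi) / denom
      }
    }
  }
  structure(total,
            mean = if (n_pairs > 0L) total / n_pairs else 0,
            n_pairs = n_pairs, n_pairs_skipped = n_skip)
}

# canonical nontrivial unrooted splits of a history: each split is
# represented by the sorted side not containing the reference leaf
.splits <- function(h, ref) {
  leaves <- sort(history_leaf_labels(h))
  n <- length(leaves)
  out <- character(0L)
  walk <- function(node) {
    if (length(node$children) == 0L) return(node$label)
    ls <- sort(unique(unlist(lapply(node$children, walk),
                             use.names = FALSE)))
    side <- if (ref %in% ls) setdiff(leaves, ls) else ls
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out[[length(out) + 1L]] <<- paste(sort(side), collapse = ",")
    }
    ls
  }
  walk(h)
  unique(out)
}

#' Robinson-Foulds distance between two histories
#'
#' Standard RF on unrooted nontrivial splits: the size of the symmetric
#' difference of the two split sets, optionally normalized by the total
#' number of splits in both trees (1 when no splits are shared; for two
#' binary trees this equals division by 2n - 6).
#'
#' @param t1,t2 `history` objects on the same leaf set.
#' @param normalized Return the normalized distance (default TRUE).
#' @return Numeric scalar.
#' @export
rf_distance <- function(t1, t2, normalized = TRUE) {
  l1 <- sort(history_leaf_labels(t1))
  l2 <- sort(history_leaf_labels(t2))
  if (!identical(l1, l2)) {
    stop("histories must share the same leaf label set", call. = FALSE)
  }
  ref <- l1[[1L]]
  s1 <- .splits(t1, ref)
  s2 <- .splits(t2, ref)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (!normalized) return(rf)
  denom <- length(s1) + length(s2)
  if (denom == 0L) return(0)
  rf / denom
}
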