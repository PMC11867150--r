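# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's DAG machinery: they recurse over plain history trees or use
# textbook formulations, so DP results are checked against an independent
# computation path.

NTS <- c("A", "C", "G", "T")

rand_seq <- function(L) paste(sample(NTS, L, replace = TRUE), collapse = "")

mutate_seq <- function(s, k) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (j in sample(seq_along(ch), k)) {
    ch[[j]] <- sample(setdiff(NTS, ch[[j]]), 1L)
  }
  paste(ch, collapse = "")
}

# a family of n distinct related sequences of length L (random walk with
# 1..k mutations per step)
mutant_family <- function(n, L, k = 2L) {
  out <- rand_seq(L)
  while (length(out) < n) {
    out <- unique(c(out, mutate_seq(sample(out, 1L), sample.int(k, 1L))))
  }
  out
}

# ---------------------------------------------------------------------------
# independent Sankoff small-parsimony score: explicit 4-state cost vectors,
# one site at a time, plain loops
sankoff_score <- function(topology, seqs) {
  L <- nchar(seqs[[1L]])
  total <- 0L
  for (site in seq_len(L)) {
    cost <- function(node) {
      if (is.character(node)) {
        b <- substr(seqs[[node]], site, site)
        out <- rep(Inf, 4L)
        out[match(b, NTS)] <- 0
        return(out)
      }
      acc <- rep(0, 4L)
      for (ch in node) {
        k <- cost(ch)
        acc <- acc + vapply(1:4, function(s) {
          min(vapply(1:4, function(t) k[[t]] + (s != t), numeric(1L)))
        }, numeric(1L))
      }
      acc
    }
    total <- total + min(cost(topology))
  }
  total
}

# ---------------------------------------------------------------------------
# brute-force per-history weights, recursing over the tree directly

oracle_parsimony <- function(h) {
  walk <- function(node) {
    s <- 0L
    for (ch in node$children) {
      a <- strsplit(node$label, "")[[1L]]
      b <- strsplit(ch$label, "")[[1L]]
      s <- s + sum(a != b) + walk(ch)
    }
    s
  }
  walk(h)
}

# context log-likelihood of a history: direct formula evaluation with
# explicit N-padding and compatible-5-mer averaging
oracle_context <- function(h, model) {
  lookup <- function(fm) {
    # expand every ambiguous flank position recursively
    i <- regexpr("[^ACGT]", fm)
    if (i < 0L) {
      return(c(model$gamma[[fm]], model$sub[fm, ]))
    }
    alts <- list(A = "A", C = "C", G = "G", T = "T",
                 N = c("A", "C", "G", "T"), R = c("A", "G"),
                 Y = c("C", "T"))[[substr(fm, i, i)]]
    rowMeans(vapply(alts, function(b) {
      lookup(paste0(substr(fm, 1L, i - 1L), b, substr(fm, i + 1L, 5L)))
    }, numeric(5L)))
  }
  branch <- function(p, c) {
    pv <- strsplit(p, "")[[1L]]
    cv <- strsplit(c, "")[[1L]]
    L <- length(pv)
    padded <- c("N", "N", pv, "N", "N")
    gam <- numeric(L)
    lam <- numeric(0L)
    for (j in seq_len(L)) {
      fm <- paste(padded[j:(j + 4L)], collapse = "")
      r <- lookup(fm)
      gam[[j]] <- r[[1L]]
      if (pv[[j]] != cv[[j]]) {
        lam <- c(lam, r[[1L]] * r[[1L + match(cv[[j]], NTS)]])
      }
    }
    n <- length(lam)
    if (n == 0L) return(0)
    that <- n / sum(gam)
    sum(log(lam)) + n * log(that) - n
  }
  walk <- function(node) {
    s <- 0
    for (ch in node$children) s <- s + branch(node$label, ch$label) + walk(ch)
    s
  }
  walk(h)
}

# branching-process log-likelihood: sum of log f(c, m) over genotype nodes
# of a collapsed history (leaf children with the parent's label are the
# parent's own observation and are skipped)
oracle_bp <- function(h, params, abundances) {
  node_term <- function(node) {
    c_val <- if (node$label %in% names(abundances)) {
      abundances[[node$label]]
    } else 0L
    m <- sum(vapply(node$children, function(ch) {
      !(length(ch$children) == 0L && ch$label == node$label)
    }, logical(1L)))
    log(genotype_prob(c_val, m, params))
  }
  walk <- function(node) {
    s <- node_term(node)
    for (ch in node$children) {
      if (length(ch$children) == 0L && ch$label == node$label) next
      s <- s + walk(ch)
    }
    s
  }
  walk(h)
}

# ---------------------------------------------------------------------------
# independent MRCA distance: per-pair root paths, intersect, take the last
# common node on the path (instead of smallest containing leaf set)
oracle_mrca <- function(true_h, inf_h) {
  paths <- function(h) {
    out <- list()
    walk <- function(node, path) {
      path <- c(path, list(node))
      if (length(node$children) == 0L) {
        out[[node$label]] <<- path
      } else {
        for (ch in node$children) walk(ch, path)
      }
    }
    walk(h, list())
    out
  }
  mrca_of <- function(pp, a, b) {
    pa <- pp[[a]]
    pb <- pp[[b]]
    last <- NULL
    for (i in seq_len(min(length(pa), length(pb)))) {
      if (identical(pa[[i]], pb[[i]])) last <- pa[[i]] else break
    }
    last$label
  }
  ham <- function(x, y) sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
  pt <- paths(true_h)
  pi_ <- paths(inf_h)
  leaves <- sort(names(pt))
  total <- 0
  for (i in seq_along(leaves)) {
    for (j in seq_along(leaves)) {
      if (j <= i) next
      a <- leaves[[i]]
      b <- leaves[[j]]
      mt <- mrca_of(pt, a, b)
      mi <- mrca_of(pi_, a, b)
      denom <- (ham(a, mt) + ham(b, mt)) / 2
      if (denom == 0) next
      total <- total + ham(mt, mi) / denom
    }
  }
  total
}

# random resolved history on given leaf sequences with randomly mutated
# ancestral labels (not MP; for metric and property tests)
rand_history <- function(leaf_seqs) {
  nodes <- lapply(leaf_seqs, history_node)
  while (length(nodes) > 1L) {
    i <- sample.int(length(nodes), 2L)
    anc <- mutate_seq(nodes[[i[[1L]]]]$label, 1L)
    merged <- history_node(anc, nodes[i])
    nodes <- c(nodes[-i], list(merged))
  }
  as_history(nodes[[1L]])
}

# canonical string form of a history (for set comparisons)
history_key <- function(h) {
  walk <- function(node) {
    if (length(node$children) == 0L) return(node$label)
    paste0(node$label, "(",
           paste(sort(vapply(node$children, walk, character(1L))),
                 collapse = ","), ")")
  }
  walk(h)
}

# small MP fixture: family of n sequences plus their exhaustive MP trees
mp_fixture <- function(n, L, k = 2L) {
  seqs <- mutant_family(n, L, k)
  list(seqs = seqs, mp = exhaustive_mp_trees(seqs))
}
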