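# Abundance-aware branching-process likelihood.  Each genotype clone is
# founded by one cell; a cell divides with probability p into two
# offspring, each of which independently mutates (founding a new genotype
# lineage) with probability q, or terminates with probability 1 - p
# (contributing one observed cell of the genotype).  The probability
# f(c, m | p, q) that a clone leaves c observed same-genotype cells and m
# distinct mutant offspring lineages satisfies the recursion
#
#   f(c, m) = (1-p) [c = 1, m = 0]
#           + p ( q^2 [c = 0, m = 2]
#               + 2 q (1-q) f(c, m-1)
#               + (1-q)^2 sum_{c', m'} f(c', m') f(c-c', m-m') )
#
# with f(0, 0) = 0, so the convolution never references f(c, m) itself and
# the table fills by increasing c + m.  The likelihood of a collapsed
# genotype tree is the product over genotype nodes of f(c, m), which
# factorizes over edges of the history.

#' Branching process parameters
#'
#' @param p Branching probability in (0, 1); by convention fitting is
#'   constrained to p < 0.5 so the process is sub-critical (mean
#'   same-genotype offspring 2p(1-q) < 1) and terminates almost surely.
#' @param q Per-offspring mutation probability in (0, 1).
#' @return Object of class `branching_params`.
#' @export
branching_params <- function(p, q) {
  if (!(p > 0 && p < 1 && q > 0 && q < 1)) {
    stop("p and q must lie in the open interval (0, 1)", call. = FALSE)
  }
  structure(list(p = p, q = q), class = "branching_params")
}

#' @export
print.branching_params <- function(x, ...) {
  cat(sprintf("<branching process: p = %.4f, q = %.4f>\n", x$p, x$q))
  invisible(x)
}

# full table f(c, m) for c in 0..cmax, m in 0..mmax, filled by increasing
# c + m; rows are c + 1, columns m + 1
genotype_prob_table <- function(cmax, mmax, p, q) {
  f <- matrix(0, cmax + 1L, mmax + 1L)
  for (s in 0:(cmax + mmax)) {
    for (c in max(0L, s - mmax):min(cmax, s)) {
      m <- s - c
      v <- 0
      if (c == 1L && m == 0L) v <- v + (1 - p)
      if (c == 0L && m == 2L) v <- v + p * q^2
      if (m >= 1L) v <- v + p * 2 * q * (1 - q) * f[c + 1L, m]
      if (s >= 1L) {
        conv <- 0
        for (c1 in 0:c) {
          conv <- conv + sum(f[c1 + 1L, 1:(m + 1L)] * f[c - c1 + 1L, (m + 1L):1])
        }
        v <- v + p * (1 - q)^2 * conv
      }
      f[c + 1L, m + 1L] <- v
    }
  }
  f
}

#' Genotype clone probability f(c, m)
#'
#' Probability that a single genotype founder leaves `c` observed
#' same-genotype cells and `m` distinct mutant offspring lineages.
#'
#' @param c Non-negative integer abundance.
#' @param m Non-negative integer count of mutant offspring lineages.
#' @param params A [branching_params()].
#' @return Probability in `[0, 1]`.
#' @export
genotype_prob <- function(c, m, params) {
  stopifnot(inherits(params, "branching_params"), c >= 0, m >= 0,
            c + m >= 1)
  tbl <- genotype_prob_table(c, m, params$p, params$q)
  tbl[c + 1L, m + 1L]
}

# ---------------------------------------------------------------------------
# edge weight over a collapsed DAG

# structural (c, m) of a node: c is the label's abundance; m is the number
# of child clades other than the singleton clade of the node's own label
# (that clade holds the same-genotype observation leaf, which contributes
# to c, not m)
.node_cm <- function(node, abundances) {
  lab <- node$label
  c_val <- if (lab %in% names(abundances)) abundances[[lab]] else 0L
  if (length(node$clades) == 0L) return(c(c_val, 0L))
  own <- vapply(node$clades, function(cl) {
    length(cl) == 1L && cl == lab
  }, logical(1L))
  c(c_val, sum(!own))
}

#' Branching-process edge weight function
#'
#' For an edge into node `vc`, the weight is `log f(c, m)` where `c` is the
#' abundance of `vc`'s label and `m` its number of mutant child lineages
#' (child clades other than the node's own observation leaf).  A leaf whose
#' label equals its parent's label carries weight 0: it is the observation
#' of its parent genotype and is already counted in the parent's `c`.  The
#' UA edge carries the root genotype's own term, so a history's edge sum is
#' its branching-process log-likelihood.  The DAG must be collapsed:
#' internal zero-mutation edges would break the genotype-tree reading.
#'
#' @param params A [branching_params()].
#' @param abundances Named integer vector mapping genotype labels to
#'   observed counts; unlisted labels count 0.
#' @return An edge weight function for use with [ranking_criterion()],
#'   [marginalize()] etc.
#' @export
bp_edge_weight <- function(params, abundances) {
  stopifnot(inherits(params, "branching_params"))
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(parent, child) {
    if (!is.null(parent) && length(child$clades) == 0L &&
        parent$label == child$label) {
      return(0)
    }
    if (!is.null(parent) && length(child$clades) > 0L &&
        parent$label == child$label) {
      stop("uncollapsed zero-mutation internal edge; collapse the DAG first",
           call. = FALSE)
    }
    cm <- .node_cm(child, abundances)
    key <- paste0(cm[[1L]], ",", cm[[2L]])
    v <- cache[[key]]
    if (is.null(v)) {
      if (sum(cm) == 0L) {
        stop("genotype with zero abundance and no mutant children",
             call. = FALSE)
      }
      v <- log(genotype_prob(cm[[1L]], cm[[2L]], params))
      cache[[key]] <- v
    }
    v
  }
}

#' Branching-process ranking criterion
#' @inheritParams bp_edge_weight
#' @return A [ranking_criterion()] (direction: maximize).
#' @export
bp_criterion <- function(params, abundances) {
  ranking_criterion(bp_edge_weight(params, abundances),
                    direction = "max", name = "bp_likelihood")
}

#' Branching-process log-likelihood of a single history
#' @param h A collapsed `history`.
#' @inheritParams bp_edge_weight
#' @return Numeric scalar.
#' @export
history_bp_loglik <- function(h, params, abundances) {
  history_weight(h, bp_edge_weight(params, abundances))
}

# ---------------------------------------------------------------------------
# parameter fitting

#' Fit branching-process parameters by marginal likelihood
#'
#' Maximizes the log marginal likelihood, summed over one or several
#' history sDAGs, over theta = (p, q): a coarse grid search followed by
#' Nelder-Mead refinement on the logit scale.  Deterministic (no
#' randomness is used).
#'
#' @param dags A `history_sdag` or list of them (collapsed).
#' @param abundances Named integer vector of genotype abundances, or a
#'   list of such vectors (one per DAG).
#' @param p_max Upper bound on p (default 0.5: sub-criticality).
#' @param grid_n Grid resolution per axis for the coarse search.
#' @return A `branching_params` with attributes `logLik` (the maximized
#'   marginal log-likelihood) and `degenerate` (TRUE, with a warning, when
#'   the optimum sits on the search boundary).
#' @export
fit_branching_params <- function(dags, abundances, p_max = 0.5,
                                 grid_n = 50L) {
  if (inherits(dags, "history_sdag")) {
    dags <- list(dags)
    abundances <- list(abundances)
  }
  stopifnot(length(dags) == length(abundances))
  obj <- function(p, q) {
    params <- branching_params(p, q)
    sum(vapply(seq_along(dags), function(i) {
      marginalize(dags[[i]], bp_edge_weight(params, abundances[[i]]))
    }, numeric(1L)))
  }
  ps <- seq(0.5 / grid_n, 1 - 0.5 / grid_n, length.out = grid_n) * p_max
  qs <- seq(0.5 / grid_n, 1 - 0.5 / grid_n, length.out = grid_n)
  best <- c(NA_real_, NA_real_)
  best_v <- -Inf
  for (p in ps) {
    for (q in qs) {
      v <- obj(p, q)
      if (v > best_v) {
        best_v <- v
        best <- c(p, q)
      }
    }
  }
  logit <- function(x) log(x / (1 - x))
  expit <- function(x) 1 / (1 + exp(-x))
  fn <- function(par) {
    p <- expit(par[[1L]]) * p_max
    q <- expit(par[[2L]])
    -obj(p, q)
  }
  opt <- stats::optim(c(logit(best[[1L]] / p_max), logit(best[[2L]])), fn,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500L))
  p_hat <- expit(opt$par[[1L]]) * p_max
  q_hat <- expit(opt$par[[2L]])
  degenerate <- p_hat < 1e-4 || p_hat > p_max - 1e-4 ||
    q_hat < 1e-4 || q_hat > 1 - 1e-4
  if (degenerate) {
    warning("branching-process fit lies on the parameter boundary; ",
            "the data may be degenerate")
  }
  out <- branching_params(min(max(p_hat, 1e-6), p_max - 1e-6),
                          min(max(q_hat, 1e-6), 1 - 1e-6))
  attr(out, "logLik") <- -opt$value
  attr(out, "degenerate") <- degenerate
  out
}

# ---------------------------------------------------------------------------
# direct simulation of the process (Monte-Carlo oracle and clone generator)

#' Simulate one genotype clone of the branching process
#'
#' Directly simulates the offspring process of a single genotype founder,
#' recursing into mutant lineages up to `max_cells` total cells (guarding
#' super-critical parameter choices).  Returns the collapsed genotype tree
#' as nested lists with fields `c` (abundance), and `mutants` (list of
#' child genotype clones).
#'
#' @param params A [branching_params()].
#' @param max_cells Abort if the clone exceeds this many cell divisions.
#' @return Nested genotype list.
#' @export
simulate_clone <- function(params, max_cells = 1e5) {
  p <- params$p
  q <- params$q
  budget <- max_cells
  sim_genotype <- function() {
    c_count <- 0L
    mutants <- list()
    pending <- 1L  # same-genotype cells awaiting their fate
    while (pending > 0L) {
      budget <<- budget - 1L
      if (budget < 0L) stop("clone exceeded max_cells; process may be ",
                            "super-critical", call. = FALSE)
      pending <- pending - 1L
      if (stats::runif(1L) < p) {
        for (k in 1:2) {
          if (stats::runif(1L) < q) {
            mutants[[length(mutants) + 1L]] <- sim_genotype()
          } else {
            pending <- pending + 1L
          }
        }
      } else {
        c_count <- c_count + 1L
      }
    }
    list(c = c_count, mutants = mutants)
  }
  sim_genotype()
}

# flatten a simulated clone into a matrix of (c, m) pairs, one row per
# genotype node
clone_cm_pairs <- function(clone) {
  rows <- list()
  walk <- function(g) {
    rows[[length(rows) + 1L]] <<- c(g$c, length(g$mutants))
    lapply(g$mutants, walk)
    invisible(NULL)
  }
  walk(clone)
  do.call(rbind, rows)
}

#' Convert a simulated clone into a history
#'
#' Builds a collapsed genotype history from a simulated clone: each
#' genotype receives a distinct sequence (the founder's sequence with one
#' additional fresh-site mutation per mutant edge), observed genotypes get
#' an observation leaf, and the result is a valid `history` whose
#' branching-process log-likelihood matches the clone's node terms.
#' Genotypes with `c = 0` and a single mutant child (invisible
#' pass-through genotypes) cannot occur under the model (`f(0, 1) = 0`).
#'
#' @param clone Output of [simulate_clone()].
#' @param sequence_length Length of the synthetic genotype sequences;
#'   must exceed the number of genotypes in the clone.
#' @return List with `history` (a `history`) and `abundances` (named
#'   integer vector over genotype labels).
#' @export
clone_to_history <- function(clone, sequence_length = 100L) {
  site <- 0L
  abund <- list()
  base_seq <- strrep("A", sequence_length)
  build <- function(g, seq) {
    if (g$c > 0L) abund[[seq]] <<- g$c
    kids <- list()
    if (g$c > 0L && length(g$mutants) > 0L) {
      kids[[1L]] <- history_node(seq)  # observation leaf for this genotype
    }
    for (mg in g$mutants) {
      site <<- site + 1L
      if (site > sequence_length) {
        stop("sequence_length too small for clone size", call. = FALSE)
      }
      mseq <- paste0(substr(seq, 1L, site - 1L), "C",
                     substr(seq, site + 1L, sequence_length))
      kids[[length(kids) + 1L]] <- build(mg, mseq)
    }
    if (length(kids) == 0L) return(history_node(seq))
    if (length(kids) == 1L) return(kids[[1L]])
    history_node(seq, kids)
  }
  h <- build(clone, base_seq)
  list(history = as_history(h),
       abundances = unlist(abund))
}
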