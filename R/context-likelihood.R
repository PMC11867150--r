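# 5-mer mutability models and the Poisson context log-likelihood used to
# rank histories.  A mutability model assigns each of the 1024 unambiguous
# nucleotide 5-mers a normalized targeting rate (the rate at which the
# central base mutates, given its two flanking bases on each side) and a
# substitution distribution over the three bases the central base can
# mutate to.  This mirrors S5F-style somatic hypermutation models.

.BASES <- c("A", "C", "G", "T")

.all_5mers <- function() {
  g <- expand.grid(b5 = .BASES, b4 = .BASES, b3 = .BASES, b2 = .BASES,
                   b1 = .BASES, stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3, g$b4, g$b5))
}

#' Construct a mutability model
#'
#' @param gamma Named numeric vector of length 1024: normalized targeting
#'   rate for each 5-mer (names are the 5-mers).
#' @param sub 1024 x 4 numeric matrix with rownames the 5-mers and colnames
#'   A, C, G, T: probability that the central base mutates to each base.
#'   Each row sums to 1 and has probability 0 in its central-base column.
#' @return An object of class `mutability_model`.
#' @export
mutability_model <- function(gamma, sub) {
  fm <- .all_5mers()
  if (length(gamma) != 1024L || is.null(names(gamma)) ||
      !setequal(names(gamma), fm) || anyDuplicated(names(gamma))) {
    stop("gamma must cover each of the 1024 5-mers exactly once",
         call. = FALSE)
  }
  if (any(gamma < 0) || any(!is.finite(gamma))) {
    stop("targeting rates must be finite and non-negative", call. = FALSE)
  }
  if (!is.matrix(sub) || nrow(sub) != 1024L ||
      !setequal(rownames(sub), fm) || !identical(colnames(sub), .BASES)) {
    stop("sub must be a 1024 x 4 matrix over the 5-mers with columns ACGT",
         call. = FALSE)
  }
  gamma <- gamma[fm]
  sub <- sub[fm, , drop = FALSE]
  central <- substr(fm, 3L, 3L)
  if (any(abs(rowSums(sub) - 1) > 1e-6)) {
    stop("substitution rows must sum to 1", call. = FALSE)
  }
  if (any(sub[cbind(seq_len(1024L), match(central, .BASES))] != 0)) {
    stop("substitution probability to the central base itself must be 0",
         call. = FALSE)
  }
  structure(list(gamma = gamma, sub = sub), class = "mutability_model")
}

#' @export
print.mutability_model <- function(x, ...) {
  cat(sprintf("<5-mer mutability model: 1024 5-mers, mean rate %.4g>\n",
              mean(x$gamma)))
  invisible(x)
}

#' Seeded synthetic mutability model
#'
#' Draws targeting rates from a log-normal distribution (normalized to
#' mean 1, mimicking S5F-style normalized mutabilities) and substitution
#' rows from a flat Dirichlet over the three non-central bases.
#' Deterministic given the seed; the caller's RNG state is preserved.
#'
#' @param seed Integer seed.
#' @param sdlog Log-scale standard deviation of the targeting rates
#'   (default 1, giving the order-of-magnitude spread of hot and cold
#'   spots seen in SHM targeting models).
#' @return A `mutability_model`.
#' @export
synthetic_mutability_model <- function(seed = 1L, sdlog = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fm <- .all_5mers()
  gamma <- stats::rlnorm(1024L, meanlog = 0, sdlog = sdlog)
  gamma <- gamma / mean(gamma)
  names(gamma) <- fm
  central <- substr(fm, 3L, 3L)
  sub <- matrix(0, 1024L, 4L, dimnames = list(fm, .BASES))
  for (i in seq_len(1024L)) {
    others <- setdiff(.BASES, central[[i]])
    draws <- stats::rgamma(3L, shape = 1)
    sub[i, others] <- draws / sum(draws)
  }
  mutability_model(gamma, sub)
}

#' Uniform mutability model
#'
#' All targeting rates 1 and substitution probability 1/3 to each
#' non-central base; useful for closed-form checks.
#' @return A `mutability_model`.
#' @export
uniform_mutability_model <- function() {
  fm <- .all_5mers()
  gamma <- stats::setNames(rep(1, 1024L), fm)
  central <- substr(fm, 3L, 3L)
  sub <- matrix(1 / 3, 1024L, 4L, dimnames = list(fm, .BASES))
  sub[cbind(seq_len(1024L), match(central, .BASES))] <- 0
  mutability_model(gamma, sub)
}

# ---------------------------------------------------------------------------
# model CSV I/O (columns: fivemer, rate, A, C, G, T)

#' Read / write mutability model CSV
#'
#' The on-disk dialect has header `fivemer,rate,A,C,G,T`, one row per
#' 5-mer with probability 0 in the central-base column, mirroring
#' S5F/SHazaM-style tables so experimentally derived models drop in.
#'
#' @param path File path.
#' @return `read_mutability_model`: a `mutability_model`.
#' @export
read_mutability_model <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fivemer", "rate", "A", "C", "G", "T")
  if (!identical(names(df), need)) {
    stop("model CSV must have columns fivemer,rate,A,C,G,T", call. = FALSE)
  }
  if (anyDuplicated(df$fivemer)) {
    stop("duplicate 5-mers in model CSV", call. = FALSE)
  }
  if (nrow(df) != 1024L) {
    stop("model CSV must contain all 1024 5-mers (found ", nrow(df), ")",
         call. = FALSE)
  }
  gamma <- stats::setNames(df$rate, df$fivemer)
  sub <- as.matrix(df[, .BASES])
  rownames(sub) <- df$fivemer
  mutability_model(gamma, sub)
}

#' @param model A `mutability_model`.
#' @rdname read_mutability_model
#' @export
write_mutability_model <- function(model, path) {
  stopifnot(inherits(model, "mutability_model"))
  fm <- names(model$gamma)
  df <- data.frame(fivemer = fm, rate = unname(model$gamma),
                   A = model$sub[, "A"], C = model$sub[, "C"],
                   G = model$sub[, "G"], T = model$sub[, "T"],
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# context extraction and ambiguity-averaged lookup

#' 5-mer context at a site
#'
#' Returns the five characters of `sequence` centred at 1-based site `j`,
#' padding positions that fall outside the sequence with `N` (so site 1 is
#' `NN` + the first three bases).
#'
#' @param sequence Character scalar.
#' @param j 1-based site index.
#' @return Character scalar of length 5.
#' @export
context_5mer <- function(sequence, j) {
  L <- nchar(sequence)
  if (j < 1L || j > L) stop("site index out of range", call. = FALSE)
  padded <- paste0("NN", sequence, "NN")
  substr(padded, j, j + 4L)
}

# all unambiguous 5-mers compatible with an IUPAC-coded 5-mer
.compatible_5mers <- function(fivemer) {
  chars <- strsplit(fivemer, "", fixed = TRUE)[[1L]]
  alts <- .IUPAC[chars]
  grid <- do.call(expand.grid, c(unname(alts), list(stringsAsFactors = FALSE)))
  apply(grid, 1L, paste, collapse = "")
}

#' Model rates for a possibly ambiguous 5-mer context
#'
#' For contexts containing `N` (or other ambiguity codes) in their flanks,
#' the targeting rate and substitution probabilities are the arithmetic
#' means of the model values over all compatible unambiguous 5-mers.  The
#' central base must be unambiguous.
#'
#' @param model A `mutability_model`.
#' @param fivemer Character scalar of length 5.
#' @return List with `gamma` (numeric scalar) and `sub` (named numeric
#'   vector over A, C, G, T).
#' @export
rates_with_ambiguity <- function(model, fivemer) {
  stopifnot(nchar(fivemer) == 5L)
  if (!substr(fivemer, 3L, 3L) %in% .BASES) {
    stop("central base of the 5-mer context must be unambiguous",
         call. = FALSE)
  }
  if (fivemer %in% names(model$gamma)) {
    return(list(gamma = unname(model$gamma[[fivemer]]),
                sub = model$sub[fivemer, ]))
  }
  comp <- .compatible_5mers(fivemer)
  list(gamma = mean(model$gamma[comp]),
       sub = colMeans(model$sub[comp, , drop = FALSE]))
}

# per-site targeting rates for a whole sequence (vectorized; only the two
# boundary sites at each end need ambiguity averaging)
.site_gammas <- function(model, sequence) {
  L <- nchar(sequence)
  padded <- paste0("NN", sequence, "NN")
  fms <- substring(padded, seq_len(L), seq_len(L) + 4L)
  g <- unname(model$gamma[fms])
  boundary <- which(is.na(g))
  for (j in boundary) {
    g[[j]] <- rates_with_ambiguity(model, fms[[j]])$gamma
  }
  g
}

# ---------------------------------------------------------------------------
# branch and history log-likelihoods

#' Poisson context log-likelihood of a branch
#'
#' For a branch with parent sequence `parent` and child sequence `child`,
#' with n the number of differing sites, per-site rates
#' `lambda_j = gamma(w(parent, j)) * S(child_j | w(parent, j))`
#' (contexts always taken from the parent), and branch length at its
#' maximum-likelihood estimate `t = n / sum_j gamma(w(parent, j))`, the
#' branch log-likelihood is
#' `sum_{j : parent_j != child_j} log(lambda_j) + n log(t) - n`.
#' A mutation-free branch scores exactly 0, so the history likelihood is
#' insensitive to collapsing zero-mutation edges.  At most one mutation
#' per site per branch is assumed.
#'
#' @param model A `mutability_model`.
#' @param parent,child Equal-length unambiguous sequences.
#' @return Numeric scalar; `-Inf` (with a warning) if any mutated site has
#'   zero rate under the model.
#' @export
branch_loglik <- function(model, parent, child) {
  if (nchar(parent) != nchar(child)) {
    stop("sequence length mismatch", call. = FALSE)
  }
  if (!.is_unambiguous(parent) || !.is_unambiguous(child)) {
    stop("branch log-likelihood requires unambiguous sequences",
         call. = FALSE)
  }
  pc <- strsplit(parent, "", fixed = TRUE)[[1L]]
  cc <- strsplit(child, "", fixed = TRUE)[[1L]]
  diff <- which(pc != cc)
  n <- length(diff)
  if (n == 0L) return(0)
  g <- .site_gammas(model, parent)
  t_hat <- n / sum(g)
  lam <- vapply(diff, function(j) {
    r <- rates_with_ambiguity(model, context_5mer(parent, j))
    r$gamma * r$sub[[cc[[j]]]]
  }, numeric(1L))
  if (any(lam == 0)) {
    warning("zero Poisson rate at a mutated site; branch log-likelihood -Inf")
    return(-Inf)
  }
  sum(log(lam)) + n * log(t_hat) - n
}

#' Poisson context log-likelihood of a history
#'
#' Sum of [branch_loglik()] over all edges of the history (the UA edge
#' contributes 0).
#'
#' @param h A `history` with unambiguous labels.
#' @param model A `mutability_model`.
#' @return Numeric scalar.
#' @export
history_context_loglik <- function(h, model) {
  total <- 0
  for (e in history_edge_labels(h)) {
    total <- total + branch_loglik(model, e$parent, e$child)
  }
  total
}

#' Poisson context ranking criterion
#'
#' Edge-decomposed context likelihood for DAG trimming and optimization
#' (direction: maximize).  Branch values are memoized per (parent, child)
#' label pair since many DAG edges repeat the same sequences.
#'
#' @param model A `mutability_model`.
#' @return A [ranking_criterion()].
#' @export
context_criterion <- function(model) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  f <- function(parent, child) {
    if (is.null(parent)) return(0)
    key <- paste0(parent$label, ">", child$label)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- branch_loglik(model, parent$label, child$label)
      cache[[key]] <- v
    }
    v
  }
  ranking_criterion(f, direction = "max", name = "context_likelihood")
}
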