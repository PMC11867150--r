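# Germinal-centre B-cell affinity-maturation simulator.  A population of
# cells carrying concatenated heavy+light nucleotide genomes evolves by
# discrete generations: each cell leaves Poisson-many offspring with mean
# set by its affinity (weighted amino-acid distance over paratope
# positions to a fixed target sequence) damped toward 1 as the population
# approaches carrying capacity; offspring mutate under a 5-mer context
# model, with non-synonymous changes at structural positions rejected.
# After the final generation the top cells by affinity are sampled and the
# true genealogy of the sample is emitted for validating inference.

.CODON_TABLE <- {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1L]]
  stats::setNames(aas, codons)
}

.translate <- function(dna) {
  n <- nchar(dna) %/% 3L
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(.CODON_TABLE[codons], collapse = "")
}

#' Simulator configuration
#'
#' Defaults encode the stated simulation world: 100 initial cells sharing
#' a naive sequence 10 weighted amino-acid mutations from a single target,
#' carrying capacity 1000, 60 paratope and 100 structural amino-acid
#' positions, affinity saturating below a target distance of 2, and 70
#' cells sampled by affinity rank at the final generation (15-50).
#'
#' @param n_initial Number of founding cells.
#' @param carrying_capacity Population size at which expected offspring
#'   per cell is exactly 1.
#' @param target_distance Amino-acid mutations separating naive from
#'   target.
#' @param min_target_distance Weighted distance below which affinity no
#'   longer improves.
#' @param n_paratope_sites,n_structural_sites Disjoint random amino-acid
#'   position sets: paratope positions enter the affinity distance;
#'   structural positions admit only synonymous mutations.
#' @param n_sampled Cells sampled (top by affinity) at the end.
#' @param generations Number of generations to simulate (15-50 in the
#'   stated world).
#' @param heavy_length,light_length Nucleotide lengths of the two chains
#'   (codon-aligned; total about 700).
#' @param mutation_rate Expected mutations per sequence per generation
#'   (0.35 gives roughly 1.5 percent nucleotide divergence by generation
#'   30, matching densely sampled GC data).
#' @param fitness_gain,fitness_decay The uncapacitated expected offspring
#'   of a cell at weighted distance d is
#'   `b(d) = 1 + fitness_gain * exp(-fitness_decay * (max(d, min) - min))`,
#'   a bounded decreasing curve; the realized mean is `b(d)^(1 - N/K)`.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_initial = 100L, carrying_capacity = 1000L,
                       target_distance = 10L, min_target_distance = 2,
                       n_paratope_sites = 60L, n_structural_sites = 100L,
                       n_sampled = 70L, generations = 20L,
                       heavy_length = 420L, light_length = 282L,
                       mutation_rate = 0.35,
                       fitness_gain = 1.5, fitness_decay = 0.6,
                       seed = 1L) {
  if (heavy_length %% 3L != 0L || light_length %% 3L != 0L) {
    stop("chain lengths must be codon-aligned (multiples of 3)",
         call. = FALSE)
  }
  n_aa <- (heavy_length + light_length) %/% 3L
  if (n_paratope_sites + n_structural_sites > n_aa) {
    stop("paratope + structural positions exceed protein length",
         call. = FALSE)
  }
  if (target_distance > n_paratope_sites) {
    stop("target_distance cannot exceed the number of paratope positions",
         call. = FALSE)
  }
  structure(list(
    n_initial = n_initial, carrying_capacity = carrying_capacity,
    target_distance = target_distance,
    min_target_distance = min_target_distance,
    n_paratope_sites = n_paratope_sites,
    n_structural_sites = n_structural_sites,
    n_sampled = n_sampled, generations = generations,
    heavy_length = heavy_length, light_length = light_length,
    mutation_rate = mutation_rate, fitness_gain = fitness_gain,
    fitness_decay = fitness_decay, seed = seed), class = "sim_config")
}

#' Draw the naive sequence, target, site partition and paratope weights
#'
#' The naive genome is a uniform random codon sequence (stop codons
#' avoided).  Amino-acid positions are partitioned at random into
#' paratope, structural and unrestricted sets; the target amino-acid
#' sequence differs from the naive translation at exactly
#' `target_distance` paratope positions, and each paratope position
#' carries a weight drawn uniformly from [0, 1] for the affinity distance.
#' Deterministic given `config$seed` (consumes the RNG stream).
#'
#' @param config A [sim_config()].
#' @return List with `naive` (nucleotide genome), `target_aa` (amino-acid
#'   sequence), `paratope_sites`, `structural_sites` (1-based amino-acid
#'   positions), and `weights` (named by paratope position).
#' @export
make_naive_and_target <- function(config) {
  L <- config$heavy_length + config$light_length
  n_aa <- L %/% 3L
  ok_codons <- names(.CODON_TABLE)[.CODON_TABLE != "*"]
  naive <- paste(sample(ok_codons, n_aa, replace = TRUE), collapse = "")
  naive_aa <- .translate(naive)
  sites <- sample.int(n_aa, config$n_paratope_sites +
                        config$n_structural_sites)
  paratope <- sort(sites[seq_len(config$n_paratope_sites)])
  structural <- sort(sites[-seq_len(config$n_paratope_sites)])
  weights <- stats::setNames(stats::runif(config$n_paratope_sites),
                             paratope)
  target_aa <- strsplit(naive_aa, "", fixed = TRUE)[[1L]]
  flip <- if (config$target_distance > 0L) {
    sample(paratope, config$target_distance)
  } else integer(0L)
  aa20 <- setdiff(unique(.CODON_TABLE), "*")
  for (pos in flip) {
    target_aa[[pos]] <- sample(setdiff(aa20, target_aa[[pos]]), 1L)
  }
  list(naive = naive, target_aa = paste(target_aa, collapse = ""),
       paratope_sites = paratope, structural_sites = structural,
       weights = weights)
}

# weighted amino-acid distance to target over paratope positions
.target_distance <- function(aa, world) {
  av <- strsplit(aa, "", fixed = TRUE)[[1L]]
  tv <- strsplit(world$target_aa, "", fixed = TRUE)[[1L]]
  idx <- world$paratope_sites
  sum(world$weights[av[idx] != tv[idx]])
}

.fecundity <- function(dist, config) {
  d_eff <- pmax(dist, config$min_target_distance)
  1 + config$fitness_gain *
    exp(-config$fitness_decay * (d_eff - config$min_target_distance))
}

#' Expected offspring of a cell
#'
#' `b(d)^(1 - N/K)`: the affinity-dependent fecundity at low density,
#' damped to exactly 1 at carrying capacity.
#'
#' @param dist Weighted target distance(s).
#' @param n_cells Current population size.
#' @param config A [sim_config()].
#' @return Numeric vector of expected offspring counts.
#' @export
expected_offspring <- function(dist, n_cells, config) {
  .fecundity(dist, config) ^ (1 - n_cells / config$carrying_capacity)
}

# ---------------------------------------------------------------------------
# context-model mutation with structural-site rejection

# per-genome targeting profile cache
.profile_env <- function() new.env(hash = TRUE, parent = emptyenv())

.genome_profile <- function(model, genome, cache) {
  pr <- cache[[genome]]
  if (is.null(pr)) {
    g <- .site_gammas(model, genome)
    pr <- list(g = g, cum = cumsum(g))
    cache[[genome]] <- pr
  }
  pr
}

#' Mutate a genome under a 5-mer context model
#'
#' Draws `Poisson(mutation_rate)` mutations; each picks a site with
#' probability proportional to the site's targeting rate (context from the
#' parent genome) and a replacement base from the context's substitution
#' distribution.  Proposals that change the amino acid at a structural
#' position are rejected and redrawn, so structural positions accumulate
#' only synonymous changes; at most one mutation per site is kept.
#'
#' @param genome Nucleotide sequence.
#' @param model A `mutability_model`.
#' @param config A [sim_config()].
#' @param world Output of [make_naive_and_target()] (for the structural
#'   site set).
#' @param cache Environment from `.profile_env()` memoizing per-genome
#'   targeting profiles (optional).
#' @param n_mutations Override the Poisson draw with a fixed count.
#' @return The mutated genome.
#' @export
mutate_genome <- function(genome, model, config, world,
                          cache = .profile_env(), n_mutations = NULL) {
  nmut <- if (is.null(n_mutations)) {
    stats::rpois(1L, config$mutation_rate)
  } else n_mutations
  if (nmut == 0L) return(genome)
  pr <- .genome_profile(model, genome, cache)
  total <- pr$cum[[length(pr$cum)]]
  chars <- strsplit(genome, "", fixed = TRUE)[[1L]]
  structural <- world$structural_sites
  mutated <- integer(0L)
  for (k in seq_len(nmut)) {
    for (try in seq_len(1000L)) {
      j <- findInterval(stats::runif(1L) * total, pr$cum) + 1L
      if (j %in% mutated) next
      ctx <- rates_with_ambiguity(model, context_5mer(genome, j))
      b <- sample(.BASES, 1L, prob = ctx$sub)
      aa_pos <- (j - 1L) %/% 3L + 1L
      if (aa_pos %in% structural) {
        cd_start <- 3L * (aa_pos - 1L) + 1L
        old_codon <- paste(chars[cd_start:(cd_start + 2L)], collapse = "")
        new_chars <- chars[cd_start:(cd_start + 2L)]
        new_chars[[j - cd_start + 1L]] <- b
        new_codon <- paste(new_chars, collapse = "")
        if (.CODON_TABLE[[new_codon]] != .CODON_TABLE[[old_codon]]) next
      }
      chars[[j]] <- b
      mutated <- c(mutated, j)
      break
    }
  }
  paste(chars, collapse = "")
}

# ---------------------------------------------------------------------------
# generations and sampling

#' Advance the population by one generation
#'
#' @param population Data frame with columns `id`, `genome`, `dist`.
#' @param model A `mutability_model`.
#' @param config A [sim_config()].
#' @param world Output of [make_naive_and_target()].
#' @param state Simulation state (environment holding the cell record, id
#'   counter and caches); created by [simulate_gc()] internally.
#' @return The next generation's population data frame.
#' @export
step_generation <- function(population, model, config, world, state) {
  if (nrow(population) == 0L) {
    stop("population went extinct", call. = FALSE)
  }
  lambda <- expected_offspring(population$dist, nrow(population), config)
  n_off <- stats::rpois(nrow(population), lambda)
  parents <- rep(seq_len(nrow(population)), n_off)
  if (length(parents) == 0L) {
    stop("population went extinct", call. = FALSE)
  }
  ids <- state$next_id + seq_along(parents) - 1L
  state$next_id <- state$next_id + length(parents)
  genomes <- character(length(parents))
  dists <- numeric(length(parents))
  for (i in seq_along(parents)) {
    p <- parents[[i]]
    g <- mutate_genome(population$genome[[p]], model, config, world,
                       cache = state$profiles)
    genomes[[i]] <- g
    d <- state$dists[[g]]
    if (is.null(d)) {
      d <- .target_distance(.translate(g), world)
      state$dists[[g]] <- d
    }
    dists[[i]] <- d
    state$record[[as.character(ids[[i]])]] <-
      list(parent = population$id[[p]], genome = g)
  }
  data.frame(id = ids, genome = genomes, dist = dists,
             stringsAsFactors = FALSE)
}

#' Sample the highest-affinity cells and emit the true history
#'
#' Ranks cells by affinity (lowest weighted target distance first, ties
#' broken by a seed-deterministic shuffle) and keeps the top `n_sampled`.
#' Identical sampled genomes collapse to one genotype with an abundance;
#' the true genealogy is pruned to the sampled genotypes (each placed at
#' its best-ranked cell), unary pass-through ancestors are suppressed and
#' zero-mutation internal edges collapsed, and genotypes ancestral to
#' other samples appear as internal nodes with a same-label observation
#' leaf.
#'
#' @param population Final-generation population data frame.
#' @param config A [sim_config()].
#' @param state Simulation state environment.
#' @param world Output of [make_naive_and_target()].
#' @return List with `sequences` (named vector, genotype id to genome),
#'   `abundances` (named by genotype id), and `true_history` (a `history`
#'   labelled by genomes; attribute `"node_names"` maps genomes to genotype
#'   ids).
#' @export
sample_cells <- function(population, config, state, world) {
  if (nrow(population) < config$n_sampled) {
    stop("population (", nrow(population), ") smaller than sample size (",
         config$n_sampled, ")", call. = FALSE)
  }
  ord <- order(population$dist, stats::runif(nrow(population)))
  top <- population[ord[seq_len(config$n_sampled)], ]
  abund <- table(top$genome)
  reps <- top[!duplicated(top$genome), ]  # best-ranked cell per genotype

  # ancestor closure of representative cells
  keep <- new.env(hash = TRUE, parent = emptyenv())
  for (id in reps$id) {
    cur <- id
    while (cur != 0L && is.null(keep[[as.character(cur)]])) {
      keep[[as.character(cur)]] <- TRUE
      cur <- state$record[[as.character(cur)]]$parent
    }
  }
  kept_ids <- as.integer(ls(keep))
  children <- split(
    kept_ids,
    vapply(kept_ids, function(i) state$record[[as.character(i)]]$parent,
           numeric(1L)))
  rep_ids <- as.character(reps$id)

  build <- function(id) {
    genome <- if (id == 0L) world$naive
              else state$record[[as.character(id)]]$genome
    kids <- lapply(children[[as.character(id)]], build)
    is_rep <- id != 0L && as.character(id) %in% rep_ids
    if (is_rep && length(kids) > 0L) {
      kids <- c(list(history_node(genome)), kids)
    }
    if (length(kids) == 0L) return(history_node(genome))
    if (length(kids) == 1L) return(kids[[1L]])  # suppress unary ancestors
    history_node(genome, kids)
  }
  h <- collapse_history(as_history(build(0L)))
  genotype_ids <- stats::setNames(paste0("g", seq_len(nrow(reps))),
                                  reps$genome)
  sequences <- stats::setNames(reps$genome, genotype_ids[reps$genome])
  abundances <- stats::setNames(as.integer(abund[reps$genome]),
                                reps$genome)
  list(sequences = sequences, abundances = abundances, true_history = h,
       genotype_ids = genotype_ids)
}

#' Run a full germinal-centre simulation
#'
#' @param config A [sim_config()].
#' @param model A `mutability_model` (defaults to a synthetic model drawn
#'   from the run seed).
#' @return List with the sampled `sequences`, `abundances` (named by
#'   genome), `true_history`, `world` (naive/target/site partition),
#'   `config`, and `final_population_size`.
#' @export
simulate_gc <- function(config = sim_config(),
                        model = synthetic_mutability_model(config$seed)) {
  set.seed(config$seed)
  world <- make_naive_and_target(config)
  state <- new.env(parent = emptyenv())
  state$record <- new.env(hash = TRUE, parent = emptyenv())
  state$profiles <- .profile_env()
  state$dists <- new.env(hash = TRUE, parent = emptyenv())
  state$next_id <- 1L

  d0 <- .target_distance(.translate(world$naive), world)
  ids <- seq_len(config$n_initial)
  for (i in ids) {
    state$record[[as.character(i)]] <- list(parent = 0L,
                                            genome = world$naive)
  }
  state$next_id <- config$n_initial + 1L
  population <- data.frame(id = ids, genome = world$naive, dist = d0,
                           stringsAsFactors = FALSE)
  for (gen in seq_len(config$generations)) {
    population <- step_generation(population, model, config, world, state)
  }
  samp <- sample_cells(population, config, state, world)
  c(samp, list(world = world, config = config,
               final_population_size = nrow(population)))
}
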