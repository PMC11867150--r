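# germinal-centre simulator contracts (scaled-down configurations)

small_cfg <- function(seed = 1L, ...) {
  defaults <- list(n_initial = 30L, carrying_capacity = 150L,
                   n_sampled = 25L, generations = 8L,
                   heavy_length = 120L, light_length = 60L,
                   n_paratope_sites = 20L, n_structural_sites = 15L,
                   target_distance = 5L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("make_naive_and_target honours the configured distances", {
  cfg <- small_cfg(seed = 11L)
  set.seed(cfg$seed)
  w <- make_naive_and_target(cfg)
  naive_aa <- strsplit(phylodag:::.translate(w$naive), "")[[1L]]
  target_aa <- strsplit(w$target_aa, "", fixed = TRUE)[[1L]]
  # target differs at exactly target_distance paratope positions
  diff <- which(naive_aa != target_aa)
  expect_length(diff, cfg$target_distance)
  expect_true(all(diff %in% w$paratope_sites))
  expect_length(intersect(w$paratope_sites, w$structural_sites), 0L)
  expect_true(all(w$weights >= 0 & w$weights <= 1))
  # unweighted mutation count from naive to target is the target distance
  expect_equal(sum(naive_aa[w$paratope_sites] !=
                     target_aa[w$paratope_sites]), cfg$target_distance)
  # target_distance = 0: naive translates to the target
  cfg0 <- small_cfg(seed = 11L, target_distance = 0L)
  set.seed(cfg0$seed)
  w0 <- make_naive_and_target(cfg0)
  expect_identical(phylodag:::.translate(w0$naive), w0$target_aa)
  # determinism under the seed
  set.seed(cfg$seed)
  expect_identical(make_naive_and_target(cfg), w)
})

test_that("expected offspring is affinity-monotone and capacity-damped", {
  cfg <- small_cfg()
  d <- seq(0, 10, by = 0.25)
  lam <- expected_offspring(d, n_cells = 10L, cfg)
  # flat below the minimum distance, non-increasing above it
  below <- d <= cfg$min_target_distance
  expect_equal(length(unique(round(lam[below], 12L))), 1L)
  expect_true(all(diff(lam[!below]) <= 1e-12))
  expect_true(all(lam[below] > 1))
  # exactly stationary at carrying capacity
  expect_equal(expected_offspring(c(0, 3, 8), cfg$carrying_capacity, cfg),
               rep(1, 3L))
  # growth below capacity at best affinity, and a Monte-Carlo check that
  # realized offspring means track the density factor
  set.seed(12L)
  for (n in c(20L, cfg$carrying_capacity)) {
    mu <- expected_offspring(0, n, cfg)
    draws <- stats::rpois(4000L, mu)
    expect_lt(abs(mean(draws) - mu), 3 * sqrt(mu / 4000) + 1e-9)
  }
})

test_that("mutation machinery: zero rate freezes genomes, spectrum tracks model", {
  cfg <- small_cfg(seed = 13L)
  set.seed(cfg$seed)
  w <- make_naive_and_target(cfg)
  m <- synthetic_mutability_model(13L)
  # zero mutation rate: genomes identical across generations
  cfg0 <- small_cfg(seed = 13L, mutation_rate = 0)
  sim0 <- simulate_gc(cfg0, model = m)
  expect_identical(unname(sim0$sequences), sim0$world$naive)

  # mutation site spectrum proportional to site targeting rates, on a
  # world with no structural constraints
  cfg_free <- small_cfg(seed = 13L, n_structural_sites = 0L)
  set.seed(cfg_free$seed)
  w_free <- make_naive_and_target(cfg_free)
  g <- phylodag:::.site_gammas(m, w_free$naive)
  set.seed(99L)
  hits <- integer(nchar(w_free$naive))
  n_rep <- 4000L
  for (i in seq_len(n_rep)) {
    mut <- mutate_genome(w_free$naive, m, cfg_free, w_free,
                         n_mutations = 1L)
    j <- which(strsplit(mut, "")[[1L]] != strsplit(w_free$naive, "")[[1L]])
    hits[j] <- hits[j] + 1L
  }
  p_site <- g / sum(g)
  # aggregate sites into bins with expected counts >= 10
  ord <- order(p_site)
  bins <- ceiling(cumsum(p_site[ord] * n_rep) / 25)
  obs <- tapply(hits[ord], bins, sum)
  exp_p <- tapply(p_site[ord], bins, sum)
  chi <- suppressWarnings(stats::chisq.test(obs, p = exp_p / sum(exp_p)))
  expect_gt(chi$p.value, 0.01)
})

test_that("structural sites are protein-invariant through a full run", {
  cfg <- small_cfg(seed = 14L)
  sim <- simulate_gc(cfg)
  naive_aa <- strsplit(phylodag:::.translate(sim$world$naive), "")[[1L]]
  idx <- sim$world$structural_sites
  for (g in sim$sequences) {
    aa <- strsplit(phylodag:::.translate(g), "")[[1L]]
    expect_identical(aa[idx], naive_aa[idx])
  }
})

test_that("sampling returns the configured abundance total and true history", {
  cfg <- small_cfg(seed = 15L)
  sim <- simulate_gc(cfg)
  expect_equal(sum(sim$abundances), cfg$n_sampled)
  expect_setequal(history_leaf_labels(sim$true_history),
                  names(sim$abundances))
  # true history is collapsed: no internal zero-mutation edges
  check <- function(node) {
    for (ch in node$children) {
      if (length(ch$children) > 0L) {
        expect_false(ch$label == node$label)
        check(ch)
      }
    }
  }
  check(sim$true_history)
  expect_equal(as.numeric(mrca_distance(sim$true_history,
                                        sim$true_history)), 0)
  # determinism
  sim2 <- simulate_gc(cfg)
  expect_identical(sim2$abundances, sim$abundances)
  # sample larger than the population errors
  cfg_big <- small_cfg(seed = 15L, n_sampled = 10000L)
  expect_error(simulate_gc(cfg_big), "smaller than")
})
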