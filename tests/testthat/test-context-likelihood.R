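# 5-mer mutability models and Poisson context likelihood

test_that("model constructors validate the 5-mer table", {
  m <- synthetic_mutability_model(42L)
  expect_length(m$gamma, 1024L)
  expect_true(all(abs(rowSums(m$sub) - 1) < 1e-9))
  # same seed reproduces, different seed does not
  expect_identical(m, synthetic_mutability_model(42L))
  expect_false(identical(m$gamma, synthetic_mutability_model(43L)$gamma))
  # missing / duplicate 5-mers rejected
  g <- m$gamma
  expect_error(mutability_model(g[-1L], m$sub), "1024")
  names(g)[1:2] <- names(g)[c(2L, 2L)]
  expect_error(mutability_model(g, m$sub), "1024|exactly once")
})

test_that("model CSV round-trips bit-exactly", {
  m <- synthetic_mutability_model(7L)
  path <- tempfile(fileext = ".csv")
  write_mutability_model(m, path)
  back <- read_mutability_model(path)
  expect_equal(back$gamma, m$gamma, tolerance = 1e-12)
  expect_equal(back$sub, m$sub, tolerance = 1e-12)
  # truncated table rejected
  lines <- readLines(path)
  writeLines(lines[1:100], path)
  expect_error(read_mutability_model(path), "1024")
  unlink(path)
})

test_that("context_5mer pads with N at boundaries", {
  s <- "ACGTACG"
  expect_identical(context_5mer(s, 2L), paste0("N", substr(s, 1L, 4L)))
  expect_identical(context_5mer(s, 1L), paste0("NN", substr(s, 1L, 3L)))
  expect_identical(context_5mer(s, 4L), substr(s, 2L, 6L))
  expect_identical(context_5mer(s, 7L), paste0(substr(s, 5L, 7L), "NN"))
  expect_error(context_5mer(s, 0L), "out of range")
  expect_error(context_5mer(s, 8L), "out of range")
})

test_that("rates_with_ambiguity averages over compatible 5-mers", {
  m <- synthetic_mutability_model(5L)
  # one N: mean over the four compatible 5-mers
  r <- rates_with_ambiguity(m, "NACGT")
  comp <- paste0(c("A", "C", "G", "T"), "ACGT")
  expect_equal(r$gamma, mean(m$gamma[comp]), tolerance = 1e-12)
  expect_equal(unname(r$sub), unname(colMeans(m$sub[comp, ])),
               tolerance = 1e-12)
  # unambiguous 5-mer: identity
  r2 <- rates_with_ambiguity(m, "ACGTA")
  expect_equal(r2$gamma, unname(m$gamma[["ACGTA"]]))
  # constant-rate model: any ambiguity still yields the constant
  u <- uniform_mutability_model()
  expect_equal(rates_with_ambiguity(u, "NNANN")$gamma, 1)
  expect_error(rates_with_ambiguity(m, "AANGT"), "central base")
})

test_that("branch_loglik matches the closed form on hand cases", {
  u <- uniform_mutability_model()
  L <- 10L
  s <- strrep("A", L)
  # no mutations: exactly 0
  expect_identical(branch_loglik(u, s, s), 0)
  # uniform model, one mutation: log(1/3) + log(1/L) - 1
  s2 <- paste0("C", strrep("A", L - 1L))
  expect_equal(branch_loglik(u, s, s2), log(1 / 3) + log(1 / L) - 1,
               tolerance = 1e-12)
  # doubling all rates leaves the value unchanged for the uniform model
  # (lambda doubles, t-hat halves: the shifts cancel)
  u2 <- mutability_model(u$gamma * 2, u$sub)
  set.seed(401)
  for (rep in 1:5) {
    a <- rand_seq(12L)
    b <- mutate_seq(a, sample.int(3L, 1L))
    expect_equal(branch_loglik(u2, a, b), branch_loglik(u, a, b),
                 tolerance = 1e-12)
  }
  expect_error(branch_loglik(u, "ACGT", "ACG"), "length mismatch")
})

test_that("branch_loglik agrees with the independent oracle on random data", {
  set.seed(402)
  m <- synthetic_mutability_model(17L)
  h <- rand_history(mutant_family(5L, 15L))
  expect_equal(history_context_loglik(h, m), oracle_context(h, m),
               tolerance = 1e-9)
})

test_that("adding a low-rate mutation cannot increase the log-likelihood", {
  # monotonicity guard on sign conventions: a mutation at a site with
  # lambda_j < e^{-1} * (n / sum gamma) strictly decreases fC
  set.seed(403)
  m <- synthetic_mutability_model(19L)
  for (rep in 1:20) {
    a <- rand_seq(20L)
    b <- mutate_seq(a, 2L)
    g <- phylodag:::.site_gammas(m, a)
    base <- branch_loglik(m, a, b)
    # add one more mutation at a random further site
    free <- which(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])
    j <- sample(free, 1L)
    r <- rates_with_ambiguity(m, context_5mer(a, j))
    to <- sample(setdiff(c("A", "C", "G", "T"), substr(a, j, j)), 1L)
    b2 <- b
    substr(b2, j, j) <- to
    lam <- r$gamma * r$sub[[to]]
    n_new <- 3L
    if (lam > 0 && lam < exp(-1) * n_new / sum(g)) {
      expect_lt(branch_loglik(m, a, b2), base)
    }
  }
})

test_that("history context likelihood is invariant under collapse", {
  set.seed(404)
  m <- synthetic_mutability_model(23L)
  for (rep in 1:5) {
    h <- rand_history(mutant_family(5L, 12L))
    # splice a zero-mutation internal edge above the root: (x, (x, ...))
    new_leaf <- mutate_seq(h$label, 1L)
    if (!new_leaf %in% history_leaf_labels(h)) {
      h2 <- as_history(history_node(h$label, list(
        history_node(h$label, h$children),
        history_node(new_leaf))))
      expect_equal(history_context_loglik(collapse_history(h2), m),
                   history_context_loglik(h2, m), tolerance = 1e-12)
    }
    ch <- collapse_history(h)
    expect_equal(history_context_loglik(ch, m),
                 history_context_loglik(h, m), tolerance = 1e-12)
  }
  # a zero-mutation leaf edge contributes exactly 0
  h3 <- as_history(history_node("AAA", list(history_node("AAA"),
                                            history_node("AAT"))))
  expect_equal(history_context_loglik(h3, m),
               branch_loglik(m, "AAA", "AAT"), tolerance = 1e-12)
})
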