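# DP over the sDAG vs brute-force enumeration oracles

test_that("optimal_weight, count and trim match enumeration on random DAGs", {
  set.seed(201)
  for (rep in 1:6) {
    fx <- mp_fixture(sample(4:6, 1L), 12L)
    dag <- trim(complete(expand_ambiguities(from_histories(fx$mp))),
                parsimony_criterion())
    hs <- enumerate_histories(dag)
    expect_equal(count_histories(dag), length(hs))
    scores <- vapply(hs, oracle_parsimony, integer(1L))
    expect_equal(optimal_weight(dag, parsimony_criterion()), min(scores))

    # a generic real-valued edge function, both directions
    f <- function(parent, child) {
      if (is.null(parent)) return(0.5)
      sum(utf8ToInt(child$label)) * 1e-3 -
        0.2 * hamming_edge_weight(parent$label, child$label)
    }
    ora <- vapply(hs, history_weight, numeric(1L), weight_fn = f)
    for (dir in c("min", "max")) {
      cr <- ranking_criterion(f, dir)
      expect_equal(optimal_weight(dag, cr),
                   if (dir == "min") min(ora) else max(ora))
      tr <- trim(dag, cr)
      validate_sdag(tr)
      kept <- vapply(enumerate_histories(tr), history_weight, numeric(1L),
                     weight_fn = f)
      opt <- if (dir == "min") min(ora) else max(ora)
      expect_true(all(abs(kept - opt) <= 1e-9 * max(1, abs(opt))))
      expect_equal(length(kept), sum(abs(ora - opt) <=
                                       1e-9 * max(1, abs(opt))))
    }
  }
})

test_that("constant and zero weight functions behave as identities", {
  set.seed(202)
  fx <- mp_fixture(5L, 10L)
  dag <- from_histories(fx$mp)
  zero <- ranking_criterion(function(p, c) 0, "min")
  expect_equal(optimal_weight(dag, zero), 0)
  tr <- trim(dag, zero)  # all histories tie
  expect_equal(count_histories(tr), count_histories(dag))
  # trim is idempotent
  cr <- parsimony_criterion()
  t1 <- trim(dag, cr)
  t2 <- trim(t1, cr)
  expect_equal(count_histories(t2), count_histories(t1))
})

test_that("marginalize matches the explicit sum and representation", {
  set.seed(203)
  for (rep in 1:4) {
    fx <- mp_fixture(sample(4:5, 1L), 10L)
    dag <- complete(from_histories(fx$mp))
    hs <- enumerate_histories(dag)
    f <- local({
      salt <- stats::runif(1L)
      function(parent, child) {
        key <- if (is.null(parent)) child$label else
          paste0(parent$label, child$label)
        # deterministic pseudo-random edge weight
        -((utf8ToInt(substr(key, 1L, 8L)) |> sum()) %% 97) / 17 - salt
      }
    })
    brute <- vapply(hs, history_weight, numeric(1L), weight_fn = f)
    m <- max(brute)
    expect_equal(marginalize(dag, f), m + log(sum(exp(brute - m))),
                 tolerance = 1e-9)
    # log_edge_fn == 0 gives log(count)
    expect_equal(marginalize(dag, function(p, c) 0),
                 log(count_histories(dag)), tolerance = 1e-12)
    # invariance under re-representation
    dag2 <- from_histories(hs)
    expect_equal(marginalize(dag2, f), marginalize(dag, f),
                 tolerance = 1e-9)
  }
})

test_that("lexicographic_trim equals brute-force lexicographic sorting", {
  set.seed(204)
  fx <- mp_fixture(5L, 12L)
  dag <- trim(complete(expand_ambiguities(from_histories(fx$mp))),
              parsimony_criterion())
  model <- synthetic_mutability_model(11L)
  crits <- list(parsimony_criterion(), context_criterion(model))
  lt <- lexicographic_trim(dag, crits)
  validate_sdag(lt)
  hs <- enumerate_histories(dag)
  p <- vapply(hs, oracle_parsimony, integer(1L))
  cl <- vapply(hs, oracle_context, numeric(1L), model = model)
  best_p <- min(p)
  best_c <- max(cl[p == best_p])
  keys_want <- vapply(hs[p == best_p & abs(cl - best_c) <= 1e-9 * abs(best_c)],
                      history_key, character(1L))
  keys_got <- vapply(enumerate_histories(lt), history_key, character(1L))
  expect_setequal(keys_got, keys_want)

  # a leading constant criterion is a no-op
  const <- ranking_criterion(function(p, c) 1, "min")
  a <- lexicographic_trim(dag, list(const, parsimony_criterion()))
  b <- trim(dag, parsimony_criterion())
  expect_setequal(names(a$nodes), names(b$nodes))
})

test_that("linear_combination satisfies the history-weight identity", {
  set.seed(205)
  fx <- mp_fixture(4L, 10L)
  dag <- from_histories(fx$mp)
  f1 <- function(p, c) if (is.null(p)) 0 else
    hamming_edge_weight(p$label, c$label)
  f2 <- function(p, c) if (is.null(p)) 0.25 else
    (utf8ToInt(c$label)[[1L]] %% 5) / 3
  expect_error(linear_combination(list(f1, f2), 1), "equal length")
  for (co in list(c(1, 0), c(1, 1), stats::runif(2L, -2, 2))) {
    fc <- linear_combination(list(f1, f2), co)
    for (h in enumerate_histories(dag)[1:min(5, count_histories(dag))]) {
      expect_equal(history_weight(h, fc),
                   co[[1L]] * history_weight(h, f1) +
                     co[[2L]] * history_weight(h, f2),
                   tolerance = 1e-12)
    }
    # combination optimum never beats the combination of optima (max case)
    cr <- ranking_criterion(fc, "max")
    hs <- enumerate_histories(dag)
    w1 <- vapply(hs, history_weight, numeric(1L), weight_fn = f1)
    w2 <- vapply(hs, history_weight, numeric(1L), weight_fn = f2)
    expect_equal(optimal_weight(dag, cr), max(co[[1L]] * w1 + co[[2L]] * w2),
                 tolerance = 1e-9)
  }
})
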