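# history sDAG construction, enumeration, expansion, completion, collapse

test_that("clade_union covers leaf, internal and example cases", {
  # the worked example node (GAA, {{GAA},{AAA,ACT,GAT}})
  node <- list(label = "GAA",
               clades = list("GAA", c("AAA", "ACT", "GAT")))
  expect_setequal(clade_union(node), c("GAA", "AAA", "ACT", "GAT"))
  expect_identical(clade_union(list(label = "ACT", clades = list())), "ACT")
  expect_setequal(
    clade_union(list(label = "AAA", clades = list("A", "B", "C"))),
    c("A", "B", "C"))
})

test_that("from_histories round-trips a single history and validates input", {
  set.seed(101)
  h <- rand_history(mutant_family(4L, 10L))
  dag <- from_histories(list(h))
  validate_sdag(dag)
  out <- enumerate_histories(dag)
  expect_length(out, 1L)
  expect_identical(history_key(out[[1L]]), history_key(h))

  h2 <- rand_history(mutant_family(4L, 8L))  # different leaf set
  expect_error(from_histories(list(h, h2)), "leaf label set")
  h3 <- rand_history(mutant_family(4L, 12L))
  expect_error(from_histories(list(h, h3)), "leaf label set|length")
  # unary internal nodes are rejected
  bad <- as_history(history_node("AA", list(history_node("AT"))))
  expect_error(from_histories(list(bad)), "unary")
})

test_that("graph union of histories recovers all inputs and possibly more", {
  set.seed(102)
  for (rep in 1:5) {
    fx <- mp_fixture(sample(4:5, 1L), 12L)
    k <- min(4L, length(fx$mp))
    inputs <- fx$mp[sample.int(length(fx$mp), k)]
    dag <- from_histories(inputs)
    validate_sdag(dag)
    keys <- vapply(enumerate_histories(dag), history_key, character(1L))
    expect_true(all(vapply(inputs, history_key, character(1L)) %in% keys))
    expect_identical(anyDuplicated(keys), 0L)
    expect_equal(count_histories(dag), length(keys))
  }
})

test_that("expand_ambiguities is the per-site Cartesian product", {
  # node labelled ART (R = A/G) becomes AAT and AGT with the same clades
  leaves <- c("AAT", "ACT")
  h <- as_history(history_node("ART", lapply(leaves, history_node)))
  dag <- expand_ambiguities(from_histories(list(h)))
  labs <- sort(vapply(dag$nodes, `[[`, character(1L), "label"))
  expect_setequal(labs, c("AAT", "ACT", "AAT", "AGT"))
  expect_equal(count_histories(dag), 2)

  # no ambiguity: identity
  h2 <- as_history(history_node("AAT", lapply(leaves, history_node)))
  dag2 <- from_histories(list(h2))
  expect_identical(sort(names(expand_ambiguities(dag2)$nodes)),
                   sort(names(dag2$nodes)))

  # blow-up cap raises a distinct error
  wide <- as_history(history_node(strrep("N", 9L), lapply(
    c(strrep("A", 9L), strrep("C", 9L)), history_node)))
  expect_error(expand_ambiguities(from_histories(list(wide)),
                                  max_expansion = 1000),
               "exceeds cap")
})

test_that("expansion + MP trim equals the per-site Fitch optima", {
  # single history with one internal N site
  leaves <- c("AAAA", "AAAT", "ATAA")
  h <- as_history(history_node("ANAA", lapply(leaves, history_node)))
  dag <- expand_ambiguities(from_histories(list(h)))
  expect_equal(count_histories(dag), 4)
  trimmed <- trim(dag, parsimony_criterion())
  labs <- vapply(trimmed$nodes, `[[`, character(1L), "label")
  internal <- labs[vapply(trimmed$nodes, function(n) length(n$clades) > 0L,
                          logical(1L))]
  # Fitch on the star topology: root must be A at site 2 (majority A,A,T)
  expect_identical(unname(internal), "AAAA")
})

test_that("complete is idempotent and only adds clade-consistent edges", {
  set.seed(103)
  fx <- mp_fixture(5L, 12L)
  dag <- from_histories(fx$mp[1:2])
  cdag <- complete(dag)
  validate_sdag(cdag)
  expect_gte(count_histories(cdag), count_histories(dag))
  cdag2 <- complete(cdag)
  expect_identical(sort(names(cdag2$nodes)), sort(names(cdag$nodes)))
  expect_equal(count_histories(cdag2), count_histories(cdag))
  # leaf sets preserved in every expressed history
  for (h in enumerate_histories(cdag)) {
    expect_setequal(history_leaf_labels(h), dag$leaves)
  }
})

test_that("two same-clade nodes with different labels both get edges", {
  leaves <- c("AA", "AC")
  h1 <- as_history(history_node("AA", lapply(leaves, history_node)))
  h2 <- as_history(history_node("AC", lapply(leaves, history_node)))
  cdag <- complete(from_histories(list(h1, h2)))
  # both roots available under the UA node
  expect_length(cdag$ua, 2L)
})

test_that("collapse removes internal zero-mutation edges, keeps leaf edges", {
  # internal edge parent == child label gets contracted
  inner <- history_node("AAA", list(history_node("AAT"),
                                    history_node("ATA")))
  h <- as_history(history_node("AAA", list(history_node("AAC"), inner)))
  ch <- collapse_history(h)
  expect_length(ch$children, 3L)
  expect_identical(history_key(ch),
                   history_key(collapse_history(ch)))  # fixed point

  # leaf child with the parent's label is retained
  h2 <- as_history(history_node("AAA", list(history_node("AAA"),
                                            history_node("AAT"))))
  expect_identical(history_key(collapse_history(h2)), history_key(h2))
})

test_that("DAG collapse equals per-history collapse on random MP fixtures", {
  set.seed(104)
  for (rep in 1:5) {
    fx <- mp_fixture(sample(4:5, 1L), 10L)
    dag <- trim(complete(expand_ambiguities(from_histories(fx$mp))),
                parsimony_criterion())
    cdag <- collapse_sdag(dag)
    validate_sdag(cdag)
    want <- unique(vapply(enumerate_histories(dag), function(h) {
      history_key(collapse_history(h))
    }, character(1L)))
    got <- vapply(enumerate_histories(cdag), history_key, character(1L))
    expect_setequal(got, want)
    # count never increases under collapse
    expect_lte(count_histories(cdag), count_histories(dag))
    # parsimony score unchanged by collapse
    expect_equal(optimal_weight(cdag, parsimony_criterion()),
                 optimal_weight(dag, parsimony_criterion()))
  }
})

test_that("leaf labels with ambiguity codes are rejected", {
  h <- as_history(history_node("AA", list(history_node("AN"),
                                          history_node("AC"))))
  expect_error(from_histories(list(h)), "ambiguity")
})

test_that("DAG JSON serialization round-trips", {
  set.seed(105)
  fx <- mp_fixture(5L, 10L)
  dag <- collapse_sdag(trim(complete(expand_ambiguities(
    from_histories(fx$mp))), parsimony_criterion()))
  for (ext in c(".json", ".json.gz")) {
    path <- tempfile(fileext = ext)
    write_dag_json(dag, path)
    back <- read_dag_json(path)
    expect_identical(sort(names(back$nodes)), sort(names(dag$nodes)))
    expect_equal(count_histories(back), count_histories(dag))
    expect_setequal(
      vapply(enumerate_histories(back), history_key, character(1L)),
      vapply(enumerate_histories(dag), history_key, character(1L)))
    unlink(path)
  }
})
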