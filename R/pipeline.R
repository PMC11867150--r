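# The inference pipeline: input MP histories -> history sDAG -> ambiguity
# expansion -> completion -> parsimony trim -> collapse -> branching
# process parameter fit -> criterion ranking -> best history + report.

#' Run the history-sDAG ranking pipeline
#'
#' Builds a history sDAG from input maximum-parsimony histories, expands
#' ancestral ambiguity codes, completes the DAG (adding every structurally
#' allowed edge), trims it back to maximum parsimony, collapses
#' zero-mutation internal edges, and then ranks the surviving histories.
#' Ranking is lexicographic over the requested criteria (default:
#' maximize branching-process likelihood, then maximize Poisson context
#' likelihood) or, when `coefficients` is given, by a single linear
#' combination of the criteria's edge weights.
#'
#' @param histories List of `history` objects (e.g. from
#'   [parse_dnapars_outfile()] or [read_history()]).
#' @param abundances Integer vector named by genotype sequence (see
#'   [read_alignment_with_abundances()]); required for the
#'   branching-process criterion.
#' @param model A `mutability_model`; required for the context criterion.
#' @param params A [branching_params()], or `NULL` to fit by maximizing
#'   the marginal branching-process likelihood over the DAG.
#' @param criteria Character vector, in descending order of importance,
#'   from `"bp_likelihood"`, `"context_likelihood"`, `"parsimony"`.
#' @param coefficients Optional numeric vector (same length as
#'   `criteria`): rank by the linear combination
#'   `sum(coefficients * criterion weights)` (maximized) instead of
#'   lexicographically.
#' @param max_expansion,max_histories Caps forwarded to
#'   [expand_ambiguities()] and [enumerate_histories()].
#' @return List with `best_history`, `dag` (the ranked, trimmed DAG),
#'   `params` (fitted or given), and `report` (per-stage history counts,
#'   optimal criterion values, and best-input-history criterion values
#'   for superset checks).
#' @export
run_pipeline <- function(histories, abundances = NULL, model = NULL,
                         params = NULL,
                         criteria = c("bp_likelihood", "context_likelihood"),
                         coefficients = NULL,
                         max_expansion = 1e5, max_histories = 1e6) {
  if (inherits(histories, "history")) histories <- list(histories)
  known <- c("bp_likelihood", "context_likelihood", "parsimony")
  if (!all(criteria %in% known)) {
    stop("criteria must be drawn from: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  if ("context_likelihood" %in% criteria && is.null(model)) {
    stop("context_likelihood criterion requires a mutability model",
         call. = FALSE)
  }
  if ("bp_likelihood" %in% criteria && is.null(abundances)) {
    stop("bp_likelihood criterion requires abundances", call. = FALSE)
  }
  report <- list(n_input = length(histories), stages = list())
  stage <- function(name, dag) {
    report$stages[[name]] <<- count_histories(dag)
    dag
  }
  dag <- stage("build", from_histories(histories))
  dag <- stage("expand", expand_ambiguities(dag, max_expansion))
  dag <- stage("complete", complete(dag))
  dag <- stage("trim_parsimony", trim(dag, parsimony_criterion()))
  dag <- stage("collapse", collapse_sdag(dag))
  report$parsimony_score <- optimal_weight(dag, parsimony_criterion())

  if ("bp_likelihood" %in% criteria && is.null(params)) {
    params <- fit_branching_params(dag, abundances)
    report$fitted <- TRUE
  }
  make_criterion <- function(name) {
    switch(name,
           bp_likelihood = bp_criterion(params, abundances),
           context_likelihood = context_criterion(model),
           parsimony = parsimony_criterion())
  }
  crits <- lapply(criteria, make_criterion)
  names(crits) <- criteria

  # best criterion values over the *input* histories (after collapsing and
  # disambiguating each input on its own), for superset-guarantee checks
  input_dags <- lapply(histories, function(h) {
    collapse_sdag(trim(expand_ambiguities(
      from_histories(list(h)), max_expansion), parsimony_criterion()))
  })
  input_best <- lapply(crits, function(cr) {
    vals <- vapply(input_dags, optimal_weight, numeric(1L), criterion = cr)
    if (cr$direction == "max") max(vals) else min(vals)
  })
  report$input_best <- input_best
  # number of distinct collapsed MP disambiguations among the inputs: the
  # tree count the previous, DAG-free pipeline would have ranked
  input_keys <- unique(unlist(lapply(input_dags, function(d) {
    vapply(enumerate_histories(d, max_histories = max_histories),
           .history_key, character(1L))
  })))
  report$n_input_unique <- length(input_keys)
  # best values over the whole collapsed MP DAG (before ranking trims):
  # these are guaranteed >= the input-history optima when inputs are MP
  report$dag_best <- lapply(crits, function(cr) optimal_weight(dag, cr))

  if (is.null(coefficients)) {
    dag <- lexicographic_trim(dag, crits)
  } else {
    if (length(coefficients) != length(crits)) {
      stop("one coefficient per criterion is required", call. = FALSE)
    }
    combined <- ranking_criterion(
      linear_combination(lapply(crits, `[[`, "weight_fn"), coefficients),
      direction = "max", name = "linear_combination")
    dag <- trim(dag, combined)
  }
  report$stages[["rank"]] <- count_histories(dag)
  best <- enumerate_histories(dag, max_histories = max_histories)[[1L]]
  list(best_history = best, dag = dag, params = params, report = report)
}
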