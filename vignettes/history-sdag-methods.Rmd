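---
title: "Ranking maximum-parsimony B-cell histories with a history sDAG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking maximum-parsimony B-cell histories with a history sDAG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodag)
```

## The problem

Densely sampled B-cell receptor (BCR) data from germinal centres have two
properties that generic phylogenetics handles poorly. First, the same
genotype is observed many times, and those abundances are informative
about the branching structure of the underlying cell lineage. Second,
maximum parsimony (MP) typically admits very many co-optimal trees and
ancestral sequence assignments, so the scientific question becomes *which
MP history to report*, not merely how to find one.

`phylodag` addresses both: it stores collections of MP *histories*
(trees whose internal nodes carry inferred ancestral sequences) in a
**history sDAG**, a directed acyclic graph whose vertices are
(label, child-clade-set) pairs under a formal universal-ancestor (UA)
root. Substructure shared between histories is stored once, and any
recombination of stored substructures is itself an expressible history,
so the DAG usually expresses far more MP histories than it was built
from — crucially, when the inputs are MP, the extra histories are MP
too, because parsimony decomposes over edges and completion-plus-trim
preserves the optimum.

## Edge-decomposable weights and the DP engine

Any history score of the form $g_f(V, E) = \sum_{(v_p, v_c) \in E}
f(v_p, v_c)$ can be minimized/maximized, counted, marginalized
($\log \sum_{\text{histories}} e^{g_f}$) and trimmed on the DAG in one
bottom-up pass with $O(|E|)$ evaluations of $f$, because the child
clades of a node are independent choices. `ranking_criterion()` wraps an
edge function and direction; `optimal_weight()`, `count_histories()`,
`marginalize()`, `trim()`, `lexicographic_trim()` and
`linear_combination()` share this engine. Three criteria ship with the
package:

* **Parsimony** — $f$ is the Hamming distance between edge endpoint
  labels; UA edges weigh 0.
* **Branching-process likelihood** — under binary branching with
  probability $p$ and per-offspring mutation probability $q$, the
  probability that a genotype founder leaves $c$ observed same-genotype
  cells and $m$ mutant offspring lineages satisfies
  $f(c,m) = (1-p)[c{=}1,m{=}0] + p\,(q^2[c{=}0,m{=}2] +
  2q(1-q)f(c,m-1) + (1-q)^2 (f \ast f)(c,m))$, with $f(0,0)=0$; the
  recursion is well founded by increasing $c+m$ and the implementation
  is validated against direct Monte-Carlo simulation of the process
  rather than a printed table. On a collapsed genotype tree the history
  log-likelihood is the sum of $\log f(c,m)$ over genotype nodes, which
  factorizes over edges (a leaf that repeats its parent's label is that
  genotype's own observation and weighs 0).
* **Poisson context likelihood** — a 5-mer mutability model supplies a
  normalized targeting rate $\gamma_w$ and substitution distribution
  $S^w_B$ for each of the 1024 5-mers. For a branch from $\ell$ to
  $\ell'$ with $n$ differing sites, rates
  $\lambda_j = \gamma_{w(\ell,j)} S^{w(\ell,j)}_{\ell'_j}$ (contexts
  always read from the **parent**), and branch length at its MLE
  $\hat t = n / \sum_j \gamma_{w(\ell,j)}$, the branch log-likelihood is
  $\sum_{j:\ell_j \ne \ell'_j} \log \lambda_j + n \log \hat t - n$.
  A mutation-free branch scores exactly 0 (returned without evaluating
  $\log \hat t$), which makes the criterion invariant to collapsing
  zero-mutation edges.

Fitting $\theta = (p, q)$ maximizes the **marginal** likelihood over all
histories in the DAG (sum-product DP with log-sum-exp), via a coarse
grid on $(0, p_{\max}) \times (0,1)$ followed by Nelder-Mead on the
logit scale; $p_{\max} = 0.5$ by default so the process is sub-critical
($2p(1-q) < 1$) and terminates.

## Pipeline

`run_pipeline()` mirrors the intended inference flow: graph-union the
input MP histories; expand IUPAC ambiguity codes in ancestral labels
(per-site Cartesian product — correctness of this over-expansion is
restored by the subsequent MP trim); `complete()` the DAG by adding
every edge whose child clade union matches a parent child clade (and UA
edges to full-leaf-set nodes); trim to MP; collapse zero-mutation
internal edges; fit $(p,q)$ if requested; and rank lexicographically
(default: maximize branching-process likelihood, then maximize context
likelihood) or by a linear combination of edge weights. The report
carries per-stage history counts, the distinct-collapsed-input count
(the baseline a DAG-free pipeline would have ranked), and best criterion
values over the DAG and over the inputs, so the ranked-superset
guarantee can be checked directly.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `max_expansion` | 1e5 | disambiguations/node | errors (not truncates) on combinatorial blow-up |
| trim `tol` | 1e-9 | relative | real-valued likelihood ties must not be pruned by rounding noise; parsimony integers are unaffected |
| `p_max` | 0.5 | — | sub-criticality of the branching process |
| `grid_n` | 50 | — | coarse-grid resolution before local refinement; deterministic |
| mutability `sdlog` | 1 | log units | order-of-magnitude hot/cold-spot spread, as in SHM targeting models |

## The simulator: what it emulates, and what it does not

`simulate_gc()` is a discrete-generation birth-death simulator of
affinity maturation designed to produce data whose *abundance
distribution* and *mutation clustering* resemble a densely sampled
germinal centre. Its stated world: 100 initial cells share a naive
sequence; a single target amino-acid sequence sits 10 paratope
mutations away; 60 random amino-acid positions are "paratope"
(affinity-relevant, each with a U[0,1] weight), a disjoint 100 are
"structural" (synonymous changes only, enforced by proposal rejection),
the rest are free; carrying capacity is 1000; after 15-50 generations
the top 70 cells by affinity are sampled and identical genomes collapse
into genotypes with abundances. Mutations are drawn per offspring
(Poisson, default 0.35/sequence/generation — chosen so ~30 generations
give roughly 1.5% nucleotide divergence) with sites chosen
proportionally to model targeting rates and bases from the model's
substitution rows.

Two quantities are deliberately *not* stated by the source material and
are package design choices, exposed in `sim_config()`: the
affinity-to-fecundity curve $b(d) = 1 + \text{gain} \cdot
e^{-\text{decay}(\max(d, d_{\min}) - d_{\min})}$ and the density law
$\lambda = b(d)^{1 - N/K}$, which is exactly stationary at capacity and
reduces to $b(d)$ in an empty GC. Chain lengths default to 420+282 nt
(codon-aligned; a 280-nt light chain cannot be translated, so the
nearest multiple of 3 is used).

A green simulator test therefore establishes that the *contracts* hold
(abundances sum to the sample size, structural positions are
protein-invariant, the mutation spectrum follows the supplied model,
offspring means are affinity-monotone and capacity-damped) — it does not
establish that the simulator reproduces real GC dynamics (no light/dark
zone structure, no T-cell help, no isotype switching, no intermediate
sampling, stop codons are not penalized, and within-branch mutations are
drawn against the parent genome's contexts, matching the likelihood's
single-mutation-per-site assumption rather than strictly sequential
context updating).

## Numerical and structural choices

* **Node identity** is the (label, canonically sorted child clades)
  pair; graph union is set union of node/edge sets, which is what makes
  `from_histories()` correct and cheap.
* **Unary internal nodes are rejected** in histories. With them,
  clade-union size does not strictly decrease along edges, and
  completion would connect equal-clade-union chains into cycles. No
  supported input source produces unary nodes; rejecting them keeps the
  DAG provably acyclic and gives a trivial topological order (ascending
  clade-union size).
* **Collapse on the DAG** is a memoized bottom-up rewrite in which each
  node yields one collapsed variant per combination of merge/keep
  decisions across its clades. Property tests assert it is extensionally
  identical to collapsing every expressed history and deduplicating.
* **Ancestral reconstruction** (`fitch_ancestors()`) computes, per site,
  the full set of states occurring in *some* MP labelling (0/1-cost
  Sankoff up- and down-pass), encoded as IUPAC codes — bottom-up Fitch
  sets alone would miss MP states at non-root nodes, breaking the
  expand-then-trim contract.
* **Zero-denominator MRCA pairs** (both taxa identical to their true
  MRCA) are skipped and counted; pairs with zero numerator contribute 0.
  The returned value is the raw pair sum; a per-pair mean is attached as
  an attribute since the source does not state a further normalization.
* **Degenerate branching fits** (optimum on the search boundary) return
  the clipped estimate with a warning and a `degenerate` attribute.

## Known limitations

* Enumeration-backed operations (`enumerate_histories()`, fixture
  generation) are desk-scale by design; caps raise errors rather than
  truncate silently.
* `exhaustive_mp_trees()` enumerates all $(2n-3)!!$ rooted topologies
  and is capped at 8 leaves; it stands in for an external parsimony
  search, which is out of scope.
* Isotype-aware ranking is not implemented (the criteria registry in
  `run_pipeline()` is the extension point).
* The dnapars outfile parser targets the ancestral-state table dialect
  documented in `?parse_dnapars_outfile`; PHYLIP versions with diverging
  layouts may need preprocessing.
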