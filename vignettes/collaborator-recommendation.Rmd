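---
title: "Recommending collaborators from a multilayer molecular-literature network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending collaborators from a multilayer molecular-literature network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molcollab)
```

## The model

`molcollab` represents the scientific literature around a set of molecules
as a heterogeneous multilayer network. Three typed node layers — molecules,
publications, authors — are joined by one weighted undirected intra-layer
edge set (molecular interactions, weight = association strength) and two
cross-layers: a publication mentions a molecule, and an author wrote a
publication. All relations are semantically symmetric, so the package
stores one undirected edge per pair. There are no intra-layer edges among
publications or among authors: co-mention and coauthorship structure is
always *derived* from the cross-layers when needed, never materialized. (A
publication–publication "mentions the same molecule" relation could be
defined, but it is redundant with the mention cross-layer and would blur
the provenance of every derived statistic, so we model none.)

Molecule identity is a canonical symbol plus an alias set; lookup is
case-insensitive over both, and an alias claimed by two molecules is
rejected at load time rather than resolved arbitrarily. Author identity is
the exact normalized name string (trimmed, internal whitespace collapsed,
case preserved): name disambiguation is a hard problem we deliberately do
not attempt, so two researchers sharing a name are one node, and the same
researcher under two spellings is two nodes.

### Mention matching

A mention edge is created when any alias of a molecule occurs as a whole
token in a publication's title or abstract, or equals one of its keywords
(case-insensitive). A token is a maximal alphanumeric run with internal
hyphens kept, so `TREM-2` is a single token: `APP` matches neither inside
`APPLE` nor inside `APP-knockout`. Substring matching would create false
edges at corpus scale; token matching under-links only unusual
typographies. The cross-layer is a *set* — mention multiplicity is ignored
here. The validation analysis (below) deliberately re-counts occurrences
with multiplicity, because "most commonly mentioned" is a frequency
statement, while "mentions" is a binary one.

## Publication-count ranking

For a query molecule `q`, its *related molecules* are its one-hop neighbors
in the molecular layer. For each author, the per-molecule counts `x, y, ...`
are the numbers of that author's publications mentioning each related
molecule; merging them gives

- `n_PC` — the author's publication count on related molecules. The default
  (`mode = "sum"`) literally sums the per-molecule counts, so one
  publication mentioning two related molecules counts twice; this matches
  how per-molecule counts are conventionally merged and printed
  (`MOL1(x), MOL2(y)` with total `x + y`). A `"distinct"` mode counts
  distinct publications instead, which guarantees `n_PC <= n_TOTAL` and
  hence `r_PC <= 1`.
- `n_TOTAL` — the author's total molecule-linked publication count (every
  publication with at least one mention edge, related or not).
- `r_PC = n_PC / n_TOTAL` — the normalized count.

Three rankings are built from these. Non-normalized: by number of related
molecules published on, then `n_PC`. Normalized: same primary key, then
`r_PC`. Hypergeometric: ascending in the inclusive upper-tail probability
`P[X >= k]` of a hypergeometric draw with population `N` = all ingested
publications, successes `K` = distinct publications on related molecules,
sample `n = n_TOTAL`, and `k` = the author's *distinct* publications on
related molecules. Two parameter choices deserve a note:

- `N` counts **all** ingested publications, including any with no molecule
  mention. Restricting to molecule-linked publications would make `N`
  depend on matcher recall; the corpus size does not.
- `k` is always the distinct-publication count, even in sum mode, because a
  sum-mode `k` could exceed the sample size `n` and leave the sampling
  model undefined.

All three rankings end with a deterministic lexicographic tie-break on the
author key, so output order is reproducible across platforms. On the
bundled toy network (`toy_fixture()`, four molecules A–D, five
publications, authors X/Y/Z) the three rankings for query A are
`Y, X, Z` (non-normalized: all cover 2 molecules; Y leads with `n_PC = 3`,
X beats Z lexicographically at `n_PC = 2`), `Y, Z, X` (normalized: Y and Z
both reach `r_PC = 1` and tie-break lexicographically), and `X, Y, Z`
(hypergeometric, `p = 0.7, 0.7, 0.9`).

## The PageRank recommender

The alternative ranking builds, per query, the coauthorship subnetwork of
all authors with at least one publication on a related molecule. Edge
weights are the collaboration strength: the raw count `M_xy` of distinct
coauthored publications on related molecules, or its normalized form
`w = M_xy / sqrt(N_x N_y)` with `N` the authors' corpus-wide publication
totals. Normalization lowers the pull of prolific authors, so the
normalized variant systematically surfaces researchers with smaller
publication records — the package's tests verify this directional effect on
a controlled two-pair construction.

Scores come from a weighted power iteration authored in the package: the
surfer follows an incident edge with probability `damping` (neighbor chosen
proportionally to edge weight) or teleports uniformly; dangling mass is
redistributed uniformly, so isolated authors keep teleport-only scores.
Defaults are the canonical `damping = 0.85`, `tol = 1e-10` (L1), and
`max_iter = 200`, none of which is prescribed by the method itself; scores
are invariant to rescaling all weights, and the implementation is checked
against direct linear-system solutions and against `igraph::page_rank` in
the test suite. A `personalization` vector is exposed for restart-biased
variants but is not used by any default pipeline. The per-molecule
top-pairs prefilter (`prefilter_k`) reproduces the divide-and-conquer
speed-up of iterating related molecules one at a time; it is off by default
because it is an optimization, not part of the model.

## Validation: are coauthors' interests adjacent?

The validation statistic asks whether the molecular interests of frequent
coauthors are closer in the molecular layer than chance. Interests are an
author's top `m = 5` most frequently mentioned molecules (token
occurrences, with multiplicity); collaborators are the `c = 5` most
frequent coauthors; `n_authors = 250` authors with at least `min_pubs = 5`
molecule-linked publications are sampled. For each author–coauthor
relation, molecules present in both top lists are removed (shared interests
explain collaboration trivially) and the remaining molecules are crossed
into ordered pairs. The null is all ordered pairs of `n_mol = 500` randomly
drawn molecules — `n_mol²` pairs *including self-pairs*, which is the
convention under which 500 molecules give exactly 250,000 pairs; self-pairs
count as non-neighbors since no molecule neighbors itself. Each
author–coauthor relation contributes once per direction in which it is
sampled. The 2×2 table (coauthor/random × neighbor/non-neighbor) is
summarized by the odds ratio `ad/bc` and Fisher's exact two-sided test;
reports floor the displayed p-value at the conventional `2.2e-16`.

Ranking methods are compared by pairing each of the top 120 authors of one
ranking with its position in another (authors absent from the second
ranking are placed just past its end) and correlating the position vectors
(Pearson).

## The synthetic generator

`generate_network(synth_config(...))` emits the exact ingestion formats
(molecular TSV, alias TSV, line-delimited JSON records) and loads them back
through the regular parser, so the mention cross-layer always comes from
the real matcher, never from a side channel. It emulates: a molecular graph
(preferential attachment by default, matching the heavy-tailed degree
distributions of curated interaction networks; Erdős–Rényi optionally),
heavy-tailed author productivity (Pareto weights with tail exponent 2.5, in
the classically observed range), publications mentioning 1–3 molecules, and
two planted structures:

- **Planted expert**: a designated author receives sole-authored
  publications on `ceiling(coverage × deg(query))` distinct neighbors of
  the query, and the generator verifies post hoc that this author strictly
  leads the distinct-molecule count, retrying with an incremented sub-seed
  on the rare tie (retry count recorded in the manifest).
- **Interest coupling** in `[0, 1]`: with this probability a publication's
  molecules are drawn from its lead author's home-molecule neighborhood and
  its coauthors from authors with adjacent homes. At 0, interests are
  independent of the molecular graph and the validation log-odds-ratio is
  centered near zero over seeds; near 1, coauthors' interests are
  genuinely adjacent and the odds ratio is consistently above 1.

Molecule names are assigned to graph nodes in *shuffled* order: preferential
attachment creates its hubs first, and several downstream tie-breaks are
lexicographic, so assigning names in growth order would correlate label
order with degree and bias "uniform" samples toward hubs. The generator is
fully deterministic given config and seed, down to file bytes.

What the generator does **not** emulate: real bibliographic metadata (MeSH
terms, affiliations, misspelled author names), multi-corpus molecule
nomenclature collisions, or temporal structure. A green test on synthetic
data therefore establishes the *mechanics* of each method and the
*direction* of each planted effect, not performance on any real literature
corpus, whose author lists and scores depend on the underlying database
snapshot and are out of scope here.

## Numerical and testing choices

- Exact tests use `stats::phyper` / `stats::fisher.test`; both are checked
  against exhaustive enumeration oracles in the test suite (all
  hypergeometric parameter sets with `N <= 12` to `1e-12`; all Fisher
  tables with total `<= 40`).
- Duplicate molecular edges collapse to the **maximum** weight: repeated
  rows usually reflect the same association reported by multiple sources,
  and the strongest report is the conventional consensus.
- Degenerate inputs are contracts, not surprises: unknown molecules,
  duplicate publication ids, ambiguous aliases, zero-margin tables and
  empty subnetworks all raise classed conditions that the CLI maps to
  distinct exit codes.
- Test-suite validation runs use scaled-down sampling parameters
  (e.g. 10–15 authors, profile size 3, 40–60 null molecules on corpora of
  ~100 molecules) so the directional properties run in seconds; the
  defaults of the user-facing functions keep the full-scale values
  (250 / 5 / 5 / 5 / 500).

## Known limitations

Author names are not disambiguated; mention detection is lexical and will
miss paraphrased molecule references; `n_TOTAL` depends on matcher recall
(it counts molecule-linked publications); the validation's random-pair
convention (ordered, self-pairs included) must be kept in mind when
comparing odds ratios across tools with other conventions.
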