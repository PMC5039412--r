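---
title: "Drug repositioning from side-effect networks and module connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug repositioning from side-effect networks and module connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repomod)
```

## The idea

Drugs with similar clinical side-effect profiles tend to act on similar
physiology, and diseases with similar symptom profiles tend to share
mechanisms. `repomod` exploits both observations jointly: it builds a
drug–drug similarity network from side-effect co-occurrence and accepts a
symptom-based disease–disease network, clusters each into dense (possibly
overlapping) modules, connects drug modules to disease modules through
curated chemical–disease associations, and finally scores every individual
drug–disease pair inside a strongly linked module pair. High-scoring pairs
that lack direct curated evidence are repositioning candidates.

The pipeline needs no gene-level data at all, which is precisely its
niche: it can propose indications for drugs and diseases with few or no
annotated genes.

## Model and procedure

### 1. TF-IDF profiles and cosine similarity

Let $W_{ij} = 1$ when drug $j$ displays side effect $i$. Raw
co-occurrence over-weights ubiquitous side effects (nausea, headache), so
incidence is reweighted as

$$w_{ij} = W_{ij}\,\log\frac{N}{n_i},$$

with $N$ the number of drugs and $n_i$ the number of drugs showing side
effect $i$. A side effect present in every drug carries weight zero. The
base of the logarithm is deliberately unspecified-by-convention here: it
multiplies every weight of a feature by the same constant and therefore
cancels exactly in the cosine

$$\mathrm{sim}(d_i, d_j) = \frac{d_i \cdot d_j}{\lVert d_i\rVert\,\lVert d_j\rVert} \in [0, 1],$$

so the natural log is used and the choice is tested to be inconsequential.
Drugs whose entire profile consists of ubiquitous features have an
all-zero vector; they are excluded from the network with a warning rather
than aborting, since real corpora do contain them.

Edges with cosine $\ge 0.4$ are kept for the drug network; the disease
network (supplied as a precomputed weighted edge list) is thresholded at
$\ge 0.5$. Both comparisons are inclusive — an edge exactly at the cutoff
survives — and nodes left without edges are dropped, which is why a large
drug corpus collapses to a much smaller networked core.

### 2. Overlapping module detection

Modules are found by greedy cohesiveness optimisation in the style of
ClusterONE. The objective for a node set $S$ is

$$f(S) = \frac{w_{\mathrm{in}}(S)}{w_{\mathrm{in}}(S) + w_{\mathrm{bound}}(S) + p\,|S|},$$

where $w_{\mathrm{in}}$ sums edge weights inside $S$, $w_{\mathrm{bound}}$
sums edges crossing the boundary, and the penalty $p$ (default 2) charges
each member a constant amount of presumed unobserved connectivity. Seeds
are taken in order of decreasing weighted degree among nodes not yet
covered; each seed set is grown *and shrunk* one node at a time (both move
types enabled) until no single move improves $f$. Candidate pairs with
overlap score $|A \cap B|^2 / (|A||B|) \ge 0.8$ are merged, and each
merged union is re-optimised by the same local search so that every
reported module is a genuine local maximum of $f$ — merging alone can
break that property. Modules smaller than `min_size = 3` or with internal
density below `min_density = 0.5` are discarded. All tie-breaks are
lexicographic on node names, making the procedure fully deterministic.

Module significance is a one-sided Mann–Whitney test of internal versus
boundary edge weights: small $p$ means the module's interior is
stochastically heavier than its attachments. The exact null distribution
is used when both samples have at most 20 tie-free values, otherwise the
normal approximation with tie correction. A module with no boundary (an
isolated component) has no contrast to test and is assigned $p = 1$
rather than an artificially significant value.

The parameter defaults (`penalty = 2`, `min_size = 3`,
`min_density = 0.5`, `merge_overlap = 0.8`) mirror the published
ClusterONE defaults. Absolute module counts on any given corpus depend on
such heuristics and on implementation details; they are treated as soft
descriptive output, not as invariants.

### 3. Linking drug modules to disease modules

For drug module $i$ (size $N_i$) and disease module $j$ (size $N_j$),
let $M_{ij}$ count curated associations crossing the pair. The default
pair score is the cross-link density

$$w(i,j) = \frac{M_{ij}}{N_i\,N_j} \in [0,1],$$

the only normalisation by both module sizes that is bounded and uses
exactly the quantities involved. Because published variants of this
statistic differ, `M/(N_i + N_j)` and `M/\sqrt{N_i N_j}` are available
behind the `formula` argument. Similarly, which curation marks count
toward $M_{ij}$ is configurable; the default accepts any curated mark
(`M`, `T`, `M&T`), since all three encode manually curated evidence.
Pairs scoring at least `min_score = 0.2` are kept and the strongest
`top_k = 3` selected — in the worked 4×4 toy with 5 cross links the
default score is $5/16 = 0.3125$.

### 4. Within-module path similarity and cross-module propagation

Inside a selected module the similarity of nodes $a, b$ is recomputed
from the module's own subgraph: for each path length $\ell = 1, \dots,
n-1$ take the best simple path with exactly $\ell$ edges, average its
weight per edge, and sum the per-length averages:

$$\mathrm{sim}(a,b) = \sum_{\ell=1}^{n-1} \frac{\max_{P \in
\mathcal{P}_\ell(a,b)} \sum_{e \in P} w_e}{\ell},$$

with a zero contribution for lengths with no path. Two choices here are
genuinely open and resolved as follows. First, when several paths share a
length, the *maximum*-weight one is used (the `aggregate = "mean"`
alternative averages over all of them): the maximum is order-independent,
keeps each term bounded by the largest edge weight, and reduces to the
edge weight itself for adjacent pairs. Second, paths are restricted to
simple paths — with repeated nodes allowed, weighted cycles would make
the sum diverge. No normalisation by the number of contributing lengths
is applied, so values grow with module connectivity; scores are
interpreted within, not across, module pairs. Modules are small (around
a dozen nodes), so exhaustive depth-first search is exact and fast, and
the implementation is verified against an independent enumeration oracle
on every module size up to 10.

For a disease $v$ and drug $w$ in a linked module pair, the association
score propagates similarity across the known (curated) cross links:

$$\mathrm{corr}(v,w) = \sum_{p \in N_{DI}(v)} \mathrm{sim}(v,p)\,
\mathbb{1}[(w,p)\ \mathrm{known}] \;+\; \sum_{q \in N_{DR}(w)}
\mathrm{sim}(w,q)\, \mathbb{1}[(q,v)\ \mathrm{known}],$$

where $N_{DI}(v)$ are the within-module neighbours of $v$ that carry at
least one known link into the drug module, and symmetrically for
$N_{DR}(w)$. This is the minimal two-sided expression over exactly those
ingredients; one-sided variants are a trivial restriction and the
two-sided default is recorded in the context object. Scores are
unnormalised sums. Known pairs are ranked together with novel ones and
only *labelled* by their curation mark — the precision evaluator then
counts marks `M`, `T`, `M&T` as known and everything else as potential.

## Synthetic corpora

`generate_fixture()` plants the structure the pipeline is supposed to
find: each drug module shares a block of dedicated side effects (default
12, against a 150-feature vocabulary and 2% Bernoulli noise), giving
within-module cosine far above the 0.4 cutoff; disease modules are
near-cliques with weights drawn from U(0.8, 1) against inter-module and
background noise in U(0.05, 0.2), cleanly separated by the 0.5 threshold;
and drug module $m$ is paired with disease module $m$ by a complete set
of planted links, a seeded fraction $\rho$ (default 0.5) of which is
exposed as curated `M&T` records while the rest is held out in a
manifest. Twenty background entities per layer carry sparse random
features calibrated so that their pairwise cosine rarely reaches 0.4. A
single integer seed drives every draw and the caller's RNG state is
restored afterwards.

What the generator does *not* emulate: the heavy-tailed degree and
prevalence distributions of real side-effect corpora, synonymy between
drug names, the mixture of reliable and noisy curation in real
association tables, and module overlap (planted modules are disjoint).
Passing the recovery tests therefore demonstrates correctness of the
machinery under clean planted conditions, not performance on real
extracts.

Problem sizes used throughout the test suite and the acceptance script —
3+3 planted modules of sizes 4–6, path-oracle subgraphs of 4–10 nodes,
ten seeds for the held-out-link AUROC — were chosen as the smallest
corpora in which every stage (thresholding, clustering, linking,
propagation, evaluation) is non-trivially exercised.

## Numerical and degenerate-case conventions

* Cosine values are clipped into $[0,1]$ against floating-point rounding;
  similarity of a zero vector is an error at the vector level, and an
  exclusion-with-warning at the network level.
* All ordering (module seeds, grow/shrink moves, ranked pairs, ranked
  predictions) breaks ties lexicographically on identifiers; repeated
  runs are byte-identical.
* Greedy moves require a strict improvement ($>10^{-12}$), which
  guarantees termination.
* `weight` columns are written with 17 significant digits so that
  write/read round-trips are bit-exact.
* Duplicate incidence rows deduplicate with one summary warning;
  duplicate edges must agree in weight (tolerance $10^{-12}$) or raise;
  duplicate associations must agree in mark or raise.
* A module with no internal or no boundary edges gets $p = 1$.

## Limitations

The method cannot distinguish therapeutic from adverse (marker-type)
associations — a high `corr` says the drug and disease are strongly
connected through module structure, not in which direction. Scores are
comparable within one module pair only. Identifier matching is exact and
case-sensitive; resolving synonyms (brand versus generic drug names) is
the caller's responsibility upstream.

## A compact run

```{r example, eval = FALSE}
fx <- generate_fixture(fixture_spec(seed = 3))
profile <- occurrence_profile(fx$occurrences$entity, fx$occurrences$feature)
drug_net <- build_similarity_network(tfidf_weight(profile), cutoff = 0.4)
disease_net <- filter_network(
  igraph::graph_from_data_frame(fx$disease_edges, directed = FALSE), 0.5)

drug_mods <- detect_modules(drug_net)
disease_mods <- detect_modules(disease_net)
top <- rank_module_pairs(link_modules(drug_mods, disease_mods, fx$curated))

ctx <- build_bipartite_context(
  module_members(drug_mods)[[top$drug_module_id[1]]],
  module_members(disease_mods)[[top$disease_module_id[1]]],
  drug_net, disease_net, fx$curated)
head(predict_associations(ctx))
```
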