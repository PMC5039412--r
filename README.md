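# repomod

Drug repositioning from clinical surface data: side-effect similarity
networks, symptom-based disease networks, overlapping module detection,
and module-to-module propagation of curated chemical–disease evidence.

## The problem

Most computational repositioning methods lean on gene-level data, which
leaves out drugs and diseases with few or no annotated genes. `repomod`
works entirely from clinical observables. Drugs are embedded in a
TF-IDF-weighted side-effect space,

```
w_ij = W_ij · log(N / n_i),        sim(d_i, d_j) = d_i·d_j / (‖d_i‖‖d_j‖),
```

and linked when their cosine similarity reaches a cutoff (default 0.4);
diseases arrive as a precomputed symptom-similarity edge list,
thresholded at 0.5. Both networks are clustered into dense, possibly
overlapping modules by greedy cohesiveness search
(`f(S) = w_in / (w_in + w_bound + p·|S|)`, ClusterONE-style defaults),
with a one-sided Mann–Whitney p-value contrasting internal against
boundary edge weights. A drug module *i* and a disease module *j* are
linked with score `w(i,j) = M_ij / (N_i·N_j)`, the density of curated
CTD-style associations crossing the pair. Inside a strongly linked pair,
every drug–disease cell is scored by propagating within-module path
similarities (sum over path lengths of the best simple path's per-edge
average weight) across the known cross links; high-scoring cells without
direct curated evidence are the repositioning candidates. Precision-at-k
against curation marks (`M`, `T`, `M&T` = known) evaluates any ranked
list.

Intended users: computational biologists and cheminformaticians who have
(or can simulate) a drug/side-effect table, a disease similarity network
and a curated association table, and want module-level repositioning
hypotheses with a reproducible, fully offline toolchain.

## Worked example

The package ships a seeded generator that plants module structure and
cross-layer links, so the whole pipeline runs without any download:

```r
library(repomod)

fx <- generate_fixture(fixture_spec(seed = 3))
profile  <- occurrence_profile(fx$occurrences$entity, fx$occurrences$feature)
drug_net <- build_similarity_network(tfidf_weight(profile), cutoff = 0.4)
disease_net <- filter_network(
  igraph::graph_from_data_frame(fx$disease_edges, directed = FALSE), 0.5)

drug_mods    <- detect_modules(drug_net)
disease_mods <- detect_modules(disease_net)
as.data.frame(drug_mods)
#>   module_id                                      member_ids size   density
#> 1        M1 drug010,drug011,drug012,drug013,drug014,drug015    6 0.7681472
#> 2        M2         drug005,drug006,drug007,drug008,drug009    5 0.5968558
#> 3        M3                 drug001,drug002,drug003,drug004    4 0.8540784

top <- rank_module_pairs(link_modules(drug_mods, disease_mods, fx$curated))
top
#>   drug_module_id disease_module_id M_ij N_i N_j     score
#> 1             M3                M3   13   4   5 0.6500000
#> 2             M2                M1   14   5   6 0.4666667
#> 3             M1                M2   16   6   6 0.4444444
```

The three detected drug modules are exactly the three planted ones, and
the strongest module pairs are the planted pairings: 13 of the 20
possible links of the `M3`/`M3` pair are curated, giving the top score
13/20 = 0.65. Scoring every cell of that pair:

```r
ctx <- build_bipartite_context(
  module_members(drug_mods)[["M3"]],
  module_members(disease_mods)[["M3"]],
  drug_net, disease_net, fx$curated)
head(predict_associations(ctx), 6)
#>   rank    drug disease    score curated_mark
#> 1    1 drug004  dis001 20.55845         none
#> 2    2 drug003  dis003 20.54439         none
#> 3    3 drug001  dis004 19.44199         none
#> 4    4 drug004  dis004 17.01273          M&T
#> 5    5 drug004  dis002 16.95465          M&T
#> 6    6 drug004  dis005 16.85485          M&T
```

The top three cells carry no curated mark — in this synthetic corpus
they are planted links that were deliberately held out, i.e. exactly the
associations the method is supposed to surface. Evaluating a bundled
published ranking list against its curation marks:

```r
pred <- read_predictions(system.file("extdata", "top20_module_pair1.tsv",
                                     package = "repomod"))
evaluate_precision(pred, top_n = 20)
#> [1] 0.9
```

18 of these 20 top-ranked associations are curated as known; the two
unmarked ones are repositioning candidates.

A thin CLI wraps the same functions
(`exec/repomod {simulate|build-network|cluster|link-modules|predict|evaluate}`).

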