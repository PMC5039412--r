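# Seeded synthetic corpora with planted module structure and planted
# cross-layer links, so every pipeline stage is testable offline.

#' Specification for a synthetic corpus
#'
#' Describes a two-layer corpus: drug modules planted in side-effect space
#' (drugs of one module share `shared_feature_count` dedicated side
#' effects, plus sparse Bernoulli noise features), a disease similarity
#' network with planted dense modules (intra-module edge weights drawn
#' from `intra_weight_range`, sparse inter-module noise from
#' `inter_weight_range`), and curated cross-layer links: drug module `m`
#' is paired with disease module `m` and every cell of the pairing is a
#' planted link, of which a `link_coverage` fraction is exposed as a
#' curated `M&T` record and the rest held out in the ground-truth
#' manifest. Background entities on both layers carry only sparse random
#' structure, calibrated so their pairwise cosine rarely reaches 0.4.
#'
#' @param n_drug_modules,n_disease_modules numbers of planted modules.
#' @param module_size_range integer interval of module sizes.
#' @param n_background_entities background drugs and diseases (each).
#' @param n_features size of the side-effect vocabulary.
#' @param shared_feature_count dedicated side effects per drug module.
#' @param noise_feature_prob per-feature Bernoulli noise probability.
#' @param intra_weight_range,inter_weight_range weight intervals in
#'   \[0, 1\] for the disease network.
#' @param link_coverage fraction of planted cross links exposed as
#'   curated records (rho in \[0, 1\]).
#' @param seed integer seed driving every random draw.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_drug_modules = 3, n_disease_modules = 3,
                         module_size_range = c(4, 6),
                         n_background_entities = 20, n_features = 150,
                         shared_feature_count = 12,
                         noise_feature_prob = 0.02,
                         intra_weight_range = c(0.8, 1.0),
                         inter_weight_range = c(0.05, 0.2),
                         link_coverage = 0.5, seed = 1) {
  spec <- list(n_drug_modules = n_drug_modules,
               n_disease_modules = n_disease_modules,
               module_size_range = as.integer(module_size_range),
               n_background_entities = n_background_entities,
               n_features = n_features,
               shared_feature_count = shared_feature_count,
               noise_feature_prob = noise_feature_prob,
               intra_weight_range = intra_weight_range,
               inter_weight_range = inter_weight_range,
               link_coverage = link_coverage,
               seed = as.integer(seed))
  counts <- c(spec$n_drug_modules, spec$n_disease_modules,
              spec$module_size_range, spec$n_background_entities,
              spec$n_features, spec$shared_feature_count)
  if (any(counts < 1)) stopf("all counts must be at least 1")
  ranges <- c(spec$intra_weight_range, spec$inter_weight_range,
              spec$noise_feature_prob, spec$link_coverage)
  if (any(ranges < 0 | ranges > 1)) {
    stopf("probabilities and weight ranges must lie within [0, 1]")
  }
  if (spec$shared_feature_count * spec$n_drug_modules > spec$n_features) {
    stopf("infeasible: %d modules x %d shared features exceed %d features",
          spec$n_drug_modules, spec$shared_feature_count, spec$n_features)
  }
  structure(spec, class = "fixture_spec")
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a synthetic corpus from a specification
#'
#' Fully determined by `spec$seed`: two calls with the same spec return
#' identical corpora, and the caller's RNG state is left untouched.
#'
#' @param spec a [fixture_spec()].
#' @return A `repomod_fixture` list with elements `occurrences` (drug,
#'   side-effect pair data frame), `disease_edges` (weighted edge list
#'   data frame), `curated` (exposed links as a
#'   [curated_associations()] table), `manifest` (every planted link with
#'   its module pairing and an `exposed` flag), `drug_modules` /
#'   `disease_modules` (planted memberships) and `spec`.
#' @export
generate_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stopf("expected a fixture_spec")
  with_seed(spec$seed, {
    szr <- spec$module_size_range
    dr_sizes <- sample(seq(szr[1], szr[2]), spec$n_drug_modules,
                       replace = TRUE)
    di_sizes <- sample(seq(szr[1], szr[2]), spec$n_disease_modules,
                       replace = TRUE)
    n_drugs <- sum(dr_sizes) + spec$n_background_entities
    n_diseases <- sum(di_sizes) + spec$n_background_entities
    drugs <- sprintf("drug%03d", seq_len(n_drugs))
    diseases <- sprintf("dis%03d", seq_len(n_diseases))
    features <- sprintf("se%04d", seq_len(spec$n_features))

    drug_modules <- split(drugs[seq_len(sum(dr_sizes))],
                          rep(seq_along(dr_sizes), dr_sizes))
    names(drug_modules) <- paste0("DM", seq_along(drug_modules))
    disease_modules <- split(diseases[seq_len(sum(di_sizes))],
                             rep(seq_along(di_sizes), di_sizes))
    names(disease_modules) <- paste0("XM", seq_along(disease_modules))
    background_drugs <- drugs[seq_len(n_drugs) > sum(dr_sizes)]
    background_diseases <- diseases[seq_len(n_diseases) > sum(di_sizes)]

    # --- occurrence table: planted shared features + Bernoulli noise ---
    shared <- split(features[seq_len(spec$shared_feature_count *
                                       spec$n_drug_modules)],
                    rep(seq_len(spec$n_drug_modules),
                        each = spec$shared_feature_count))
    noise_pool <- setdiff(features, unlist(shared))
    occ_entity <- character(0); occ_feature <- character(0)
    for (m in seq_along(drug_modules)) {
      for (d in drug_modules[[m]]) {
        occ_entity <- c(occ_entity, rep(d, length(shared[[m]])))
        occ_feature <- c(occ_feature, shared[[m]])
        if (length(noise_pool)) {
          hit <- noise_pool[stats::runif(length(noise_pool)) <
                              spec$noise_feature_prob]
          occ_entity <- c(occ_entity, rep(d, length(hit)))
          occ_feature <- c(occ_feature, hit)
        }
      }
    }
    for (d in background_drugs) {
      k <- min(5L, length(noise_pool))
      if (k == 0) k <- 1L
      hit <- sample(if (length(noise_pool)) noise_pool else features, k)
      occ_entity <- c(occ_entity, rep(d, k))
      occ_feature <- c(occ_feature, hit)
    }
    occurrences <- data.frame(entity = occ_entity, feature = occ_feature,
                              stringsAsFactors = FALSE)

    # --- disease network: planted near-cliques + sparse weak noise ---
    efrom <- character(0); eto <- character(0); ew <- numeric(0)
    for (mod in disease_modules) {
      pairs <- utils::combn(mod, 2)
      efrom <- c(efrom, pairs[1, ]); eto <- c(eto, pairs[2, ])
      ew <- c(ew, runif_range(ncol(pairs), spec$intra_weight_range))
    }
    planted_diseases <- unlist(disease_modules)
    module_of <- rep(names(disease_modules), lengths(disease_modules))
    if (length(planted_diseases) > 1) {
      ap <- utils::combn(planted_diseases, 2)
      cross <- module_of[match(ap[1, ], planted_diseases)] !=
        module_of[match(ap[2, ], planted_diseases)]
      pick <- cross & stats::runif(ncol(ap)) < 0.02
      if (any(pick)) {
        efrom <- c(efrom, ap[1, pick]); eto <- c(eto, ap[2, pick])
        ew <- c(ew, runif_range(sum(pick), spec$inter_weight_range))
      }
    }
    for (d in background_diseases) {
      others <- setdiff(diseases, d)
      nb <- sample(others, min(2L, length(others)))
      efrom <- c(efrom, rep(d, length(nb))); eto <- c(eto, nb)
      ew <- c(ew, runif_range(length(nb), spec$inter_weight_range))
    }
    ew[ew <= 0] <- 1e-6
    key <- pair_key(efrom, eto)
    first <- !duplicated(key)
    disease_edges <- data.frame(from = efrom[first], to = eto[first],
                                weight = ew[first], stringsAsFactors = FALSE)

    # --- planted cross links: module m <-> module m, complete bipartite ---
    n_pairs <- min(spec$n_drug_modules, spec$n_disease_modules)
    man <- do.call(rbind, lapply(seq_len(n_pairs), function(m) {
      expand.grid(drug = drug_modules[[m]], disease = disease_modules[[m]],
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }))
    man$drug_module <- rep(names(drug_modules)[seq_len(n_pairs)],
                           vapply(seq_len(n_pairs), function(m)
                             dr_sizes[m] * di_sizes[m], integer(1)))
    man$disease_module <- rep(names(disease_modules)[seq_len(n_pairs)],
                              vapply(seq_len(n_pairs), function(m)
                                dr_sizes[m] * di_sizes[m], integer(1)))
    n_exposed <- round(spec$link_coverage * nrow(man))
    man$exposed <- FALSE
    if (n_exposed > 0) {
      man$exposed[sample(nrow(man), n_exposed)] <- TRUE
    }

    # a few computational (inferred) background records exercise labelling
    n_inf <- min(5L, length(background_drugs), length(background_diseases))
    cur_chem <- c(man$drug[man$exposed],
                  sample(background_drugs, n_inf))
    cur_dis <- c(man$disease[man$exposed],
                 sample(background_diseases, n_inf))
    cur_mark <- c(rep("M&T", sum(man$exposed)), rep("inferred", n_inf))

    structure(
      list(occurrences = occurrences,
           disease_edges = disease_edges,
           curated = curated_associations(cur_chem, cur_dis, cur_mark),
           manifest = man,
           drug_modules = drug_modules,
           disease_modules = disease_modules,
           spec = spec),
      class = "repomod_fixture"
    )
  })
}

#' @export
print.repomod_fixture <- function(x, ...) {
  cat(sprintf(paste0("<repomod_fixture> %d drug module(s), %d disease ",
                     "module(s), %d planted link(s) (%d exposed)\n"),
              length(x$drug_modules), length(x$disease_modules),
              nrow(x$manifest), sum(x$manifest$exposed)))
  invisible(x)
}

#' Write a synthetic corpus to a directory
#'
#' Emits `occurrences.tsv`, `disease_network.tsv`, `curated.tsv` and
#' `manifest.tsv`, readable by the package's own readers.
#'
#' @param fixture a [generate_fixture()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!inherits(fixture, "repomod_fixture")) stopf("expected a fixture")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  occ <- fixture$occurrences
  writeLines(paste(occ$entity, occ$feature, sep = "\t"),
             file.path(dir, "occurrences.tsv"))
  de <- fixture$disease_edges
  writeLines(paste(de$from, de$to, fmt_num(de$weight), sep = "\t"),
             file.path(dir, "disease_network.tsv"))
  cu <- fixture$curated
  writeLines(paste(cu$chemical, cu$disease, cu$mark, sep = "\t"),
             file.path(dir, "curated.tsv"))
  man <- fixture$manifest
  writeLines(c(paste("drug", "disease", "drug_module", "disease_module",
                     "exposed", sep = "\t"),
               paste(man$drug, man$disease, man$drug_module,
                     man$disease_module, man$exposed, sep = "\t")),
             file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' The four-drug / four-disease worked toy
#'
#' A minimal module pair: four drugs and four diseases, each layer a
#' small weighted subgraph, crossed by five curated `M&T` links. Used to
#' exercise module linking (`M_ij = 5`, `N(i) = N(j) = 4`, default score
#' 5/16) and the bipartite prediction context.
#'
#' @return A list with `drug_members`, `disease_members`, `drug_network`,
#'   `disease_network` (weighted `igraph` graphs) and `curated`.
#' @export
worked_toy <- function() {
  drug_members <- paste0("drug", 1:4)
  disease_members <- paste0("disease", 1:4)
  drug_network <- igraph::graph_from_data_frame(data.frame(
    from = c("drug1", "drug2", "drug3", "drug1"),
    to = c("drug2", "drug3", "drug4", "drug3"),
    weight = c(0.9, 0.8, 0.7, 0.6)
  ), directed = FALSE)
  disease_network <- igraph::graph_from_data_frame(data.frame(
    from = c("disease1", "disease2", "disease3", "disease1"),
    to = c("disease2", "disease3", "disease4", "disease4"),
    weight = c(0.85, 0.75, 0.65, 0.55)
  ), directed = FALSE)
  curated <- curated_associations(
    chemical = c("drug1", "drug2", "drug2", "drug3", "drug4"),
    disease = c("disease1", "disease1", "disease2", "disease3", "disease4"),
    mark = rep("M&T", 5)
  )
  list(drug_members = drug_members, disease_members = disease_members,
       drug_network = drug_network, disease_network = disease_network,
       curated = curated)
}
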