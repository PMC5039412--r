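# End-to-end evaluation against a synthetic corpus's ground truth.

#' Exact recovery of planted modules
#'
#' Compares detected module member sets against planted ones. A planted
#' module counts as recovered when some detected module equals it exactly;
#' a detected module is a false merge when it contains members of two or
#' more different planted modules.
#'
#' @param planted named list of planted member vectors.
#' @param detected a `module_set` or named list of member vectors.
#' @return A list with `rate` (fraction of planted modules recovered
#'   exactly) and `false_merges` (count of mixing detected modules).
#' @export
module_recovery <- function(planted, detected) {
  det <- if (inherits(detected, "module_set"))
    module_members(detected) else detected
  det_keys <- vapply(det, function(m) paste(sort(m), collapse = ","),
                     character(1))
  pl_keys <- vapply(planted, function(m) paste(sort(m), collapse = ","),
                    character(1))
  origin <- rep(names(planted), lengths(planted))
  names(origin) <- unlist(planted)
  merges <- vapply(det, function(m) {
    src <- unique(origin[intersect(m, names(origin))])
    length(src) > 1
  }, logical(1))
  list(rate = mean(pl_keys %in% det_keys),
       false_merges = sum(merges))
}

#' Held-out planted-link recovery across a synthetic corpus
#'
#' Scores every drug-disease cell of every (planted drug module, planted
#' disease module) combination using only the exposed curated links, then
#' measures how well the held-out planted links (positives) rank above
#' cells that were never planted (negatives); exposed links are excluded
#' from the evaluation. The area under the ROC curve is computed with
#' \pkg{pROC}.
#'
#' @param fixture a [generate_fixture()] result.
#' @inheritParams path_similarity
#' @return The AUROC as a plain number.
#' @export
evaluate_link_recovery <- function(fixture, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(fixture, "repomod_fixture")) stopf("expected a fixture")
  profile <- occurrence_profile(fixture$occurrences$entity,
                                fixture$occurrences$feature)
  drug_net <- build_similarity_network(tfidf_weight(profile), cutoff = 0.4)
  disease_net <- igraph::graph_from_data_frame(fixture$disease_edges,
                                               directed = FALSE)
  man_key <- paste(fixture$manifest$drug, fixture$manifest$disease,
                   sep = "\r")
  exposed_key <- man_key[fixture$manifest$exposed]
  heldout_key <- man_key[!fixture$manifest$exposed]

  scores <- numeric(0); labels <- integer(0)
  for (dm in names(fixture$drug_modules)) {
    dr <- intersect(fixture$drug_modules[[dm]],
                    igraph::V(drug_net)$name)
    if (length(dr) < 2) next
    for (xm in names(fixture$disease_modules)) {
      di <- intersect(fixture$disease_modules[[xm]],
                      igraph::V(disease_net)$name)
      if (length(di) < 2) next
      ctx <- build_bipartite_context(dr, di, drug_net, disease_net,
                                     fixture$curated, aggregate)
      pred <- predict_associations(ctx)
      key <- paste(pred$drug, pred$disease, sep = "\r")
      keep <- !(key %in% exposed_key)
      scores <- c(scores, pred$score[keep])
      labels <- c(labels, as.integer(key[keep] %in% heldout_key))
    }
  }
  if (length(unique(labels)) < 2) {
    stopf("recovery evaluation needs both held-out and unplanted cells")
  }
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}
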