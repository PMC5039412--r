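# Within-module path similarity and cross-module association scoring.
#
# Step 1: rescore every node pair inside a module from the module's own
# subgraph topology, summing over path lengths the per-edge average weight
# of the best simple path of that length.
# Step 2: propagate those similarities across the curated links crossing a
# (drug module, disease module) pair to score every drug-disease cell.

# Best (max) or average total edge weight per simple-path length between
# a and b, by depth-first enumeration. adj is a named adjacency list of
# data frames (node, weight).
path_length_profile <- function(adj, a, b, max_len, aggregate) {
  best <- rep(-Inf, max_len)    # max total weight per length
  tot <- rep(0, max_len)        # sum of totals per length (for "mean")
  cnt <- integer(max_len)
  visited <- setNames(logical(length(adj)), names(adj))
  recurse <- function(node, depth, wsum) {
    nb <- adj[[node]]
    for (k in seq_len(nrow(nb))) {
      nxt <- nb$node[k]
      w <- wsum + nb$weight[k]
      if (nxt == b) {
        len <- depth + 1L
        if (w > best[len]) best[len] <<- w
        tot[len] <<- tot[len] + w
        cnt[len] <<- cnt[len] + 1L
      } else if (depth + 1L < max_len && !visited[[nxt]]) {
        visited[[nxt]] <<- TRUE
        recurse(nxt, depth + 1L, w)
        visited[[nxt]] <<- FALSE
      }
    }
  }
  visited[[a]] <- TRUE
  recurse(a, 0L, 0)
  if (aggregate == "max") {
    ifelse(is.finite(best), best, 0)
  } else {
    ifelse(cnt > 0, tot / cnt, 0)
  }
}

graph_adj_list <- function(subgraph) {
  nodes <- igraph::V(subgraph)$name
  ends <- igraph::as_edgelist(subgraph)
  w <- igraph::E(subgraph)$weight
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- data.frame(node = character(), weight = numeric())
  if (nrow(ends)) {
    df <- rbind(data.frame(from = ends[, 1], to = ends[, 2], weight = w),
                data.frame(from = ends[, 2], to = ends[, 1], weight = w))
    sp <- split(df[c("to", "weight")], df$from)
    for (v in names(sp)) {
      o <- order(sp[[v]]$to)
      adj[[v]] <- data.frame(node = sp[[v]]$to[o], weight = sp[[v]]$weight[o])
    }
  }
  adj
}

#' Path-based similarity between two nodes of a module subgraph
#'
#' For each path length `i` from 1 to `max_len`, take the best simple path
#' from `a` to `b` with exactly `i` edges and average its weight over its
#' edges; the similarity is the sum of these per-length averages. Lengths
#' with no simple path contribute 0. "Best" defaults to the maximum-weight
#' simple path of that length (`aggregate = "max"`), which is
#' order-independent and reduces to the edge weight for adjacent pairs;
#' `aggregate = "mean"` averages over all simple paths of the length
#' instead. Paths are restricted to simple paths: with cycles allowed the
#' length-indexed sum would be unbounded.
#'
#' The value lies in \[0, `max_len`\] since each per-length average is at
#' most the maximum edge weight (at most 1 for similarity networks).
#'
#' @param subgraph an undirected weighted `igraph` graph (a module's
#'   induced subgraph).
#' @param a,b distinct vertex names in `subgraph`.
#' @param max_len maximum path length in edges; defaults to
#'   `vcount(subgraph) - 1`, the longest possible simple path.
#' @param aggregate `"max"` (default) or `"mean"` over same-length paths.
#' @return A nonnegative number; 0 when `a` and `b` are disconnected.
#' @export
path_similarity <- function(subgraph, a, b, max_len = NULL,
                            aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  nodes <- igraph::V(subgraph)$name
  if (!(a %in% nodes) || !(b %in% nodes)) {
    stopf("both nodes must belong to the subgraph")
  }
  if (a == b) stopf("path similarity is defined for distinct nodes")
  if (is.null(max_len)) max_len <- length(nodes) - 1L
  if (max_len < 1) return(0)
  prof <- path_length_profile(graph_adj_list(subgraph), a, b,
                              as.integer(max_len), aggregate)
  sum(prof / seq_along(prof))
}

#' All pairwise path similarities inside a module
#'
#' @param network the weighted network the module was detected in.
#' @param members character vector of module vertex names.
#' @inheritParams path_similarity
#' @return A symmetric numeric matrix (diagonal `NA`) over `members`.
#' @export
intra_module_similarity <- function(network, members,
                                    aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  members <- sort(members)
  sub <- igraph::induced_subgraph(network, members)
  n <- length(members)
  sim <- matrix(NA_real_, n, n, dimnames = list(members, members))
  adj <- graph_adj_list(sub)
  if (n >= 2 && n - 1L >= 1L) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        prof <- path_length_profile(adj, members[i], members[j],
                                    n - 1L, aggregate)
        sim[i, j] <- sim[j, i] <- sum(prof / seq_along(prof))
      }
    }
  }
  sim
}

#' Assemble the heterogeneous context for a module pair
#'
#' Builds the drug-disease heterogeneous network for one
#' (drug module, disease module) pair: the two module-induced subgraphs
#' with their internal path similarities, the curated links crossing the
#' pair (the external connections), and the qualifying neighbor sets. A
#' disease neighbor `p` of `v` qualifies (`N_DI(v)`) when `p` carries at
#' least one known link into the drug module; symmetrically for drug
#' neighbors (`N_DR(w)`).
#'
#' @param drug_module,disease_module character member vectors (non-empty).
#' @param drug_network,disease_network the weighted networks the modules
#'   were detected in.
#' @param curated a [curated_associations()] table; marks in `known_marks`
#'   define the known cross links, all marks are kept for labelling.
#' @param known_marks curation marks treated as verified links.
#' @inheritParams path_similarity
#' @return An object of class `bipartite_context`.
#' @export
build_bipartite_context <- function(drug_module, disease_module,
                                    drug_network, disease_network, curated,
                                    aggregate = c("max", "mean"),
                                    known_marks = .KNOWN_MARKS) {
  aggregate <- match.arg(aggregate)
  if (!length(drug_module) || !length(disease_module)) {
    stopf("modules must be non-empty")
  }
  if (!inherits(curated, "curated_associations")) {
    stopf("expected a curated_associations table")
  }
  drug_module <- sort(drug_module)
  disease_module <- sort(disease_module)
  drug_sim <- intra_module_similarity(drug_network, drug_module, aggregate)
  disease_sim <- intra_module_similarity(disease_network, disease_module,
                                         aggregate)
  cross <- curated[curated$chemical %in% drug_module &
                     curated$disease %in% disease_module, , drop = FALSE]
  known <- cross[cross$mark %in% known_marks, , drop = FALSE]
  known_key <- paste(known$chemical, known$disease, sep = "\r")

  drug_sub <- igraph::induced_subgraph(drug_network, drug_module)
  disease_sub <- igraph::induced_subgraph(disease_network, disease_module)
  drug_adj <- lapply(graph_adj_list(drug_sub), function(d) d$node)
  disease_adj <- lapply(graph_adj_list(disease_sub), function(d) d$node)

  linked_drugs <- unique(known$chemical)     # drugs with >= 1 known link
  linked_diseases <- unique(known$disease)
  n_di <- lapply(setNames(disease_module, disease_module), function(v) {
    intersect(disease_adj[[v]], linked_diseases)
  })
  n_dr <- lapply(setNames(drug_module, drug_module), function(w) {
    intersect(drug_adj[[w]], linked_drugs)
  })
  structure(
    list(drug_module = drug_module, disease_module = disease_module,
         drug_sim = drug_sim, disease_sim = disease_sim,
         known_links = known, known_key = known_key,
         all_marks = cross, n_di = n_di, n_dr = n_dr,
         aggregate = aggregate),
    class = "bipartite_context"
  )
}

#' @export
print.bipartite_context <- function(x, ...) {
  cat(sprintf(paste0("<bipartite_context> %d drugs x %d diseases, ",
                     "%d known cross link(s)\n"),
              length(x$drug_module), length(x$disease_module),
              nrow(x$known_links)))
  invisible(x)
}

#' Cross-module association score for one drug-disease pair
#'
#' Propagates within-module path similarities across the known cross
#' links: `corr(v, w)` sums `sim(v, p)` over the qualifying disease
#' neighbors `p` of `v` that are known-linked to `w`, plus `sim(w, q)`
#' over the qualifying drug neighbors `q` of `w` that are known-linked to
#' `v`. The score is nonnegative, unnormalized, monotone in every
#' similarity and in the known-link set, and zero when neither
#' neighborhood carries a supporting link.
#'
#' @param context a [build_bipartite_context()] result.
#' @param v a disease in the context's disease module.
#' @param w a drug in the context's drug module.
#' @return A nonnegative number.
#' @export
cross_module_score <- function(context, v, w) {
  if (!inherits(context, "bipartite_context")) {
    stopf("expected a bipartite_context")
  }
  if (!(v %in% context$disease_module)) stopf("disease %s not in context", v)
  if (!(w %in% context$drug_module)) stopf("drug %s not in context", w)
  s <- 0
  for (p in context$n_di[[v]]) {
    if (paste(w, p, sep = "\r") %in% context$known_key) {
      s <- s + context$disease_sim[v, p]
    }
  }
  for (q in context$n_dr[[w]]) {
    if (paste(q, v, sep = "\r") %in% context$known_key) {
      s <- s + context$drug_sim[w, q]
    }
  }
  s
}

#' Score and rank every drug-disease pair of a module pair
#'
#' Computes [cross_module_score()] for every cell of the module pair,
#' orders by descending score (ties broken lexicographically by drug then
#' disease), and attaches each pair's curation mark from the full
#' association table (`inferred` and absent pairs are labelled too: known
#' pairs are ranked alongside novel ones and only labelled, never
#' excluded).
#'
#' @param context a [build_bipartite_context()] result.
#' @return A data frame of class `association_predictions` with columns
#'   `rank`, `drug`, `disease`, `score`, `curated_mark`.
#' @export
predict_associations <- function(context) {
  if (!inherits(context, "bipartite_context")) {
    stopf("expected a bipartite_context")
  }
  grid <- expand.grid(drug = context$drug_module,
                      disease = context$disease_module,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$score <- mapply(function(w, v) cross_module_score(context, v, w),
                       grid$drug, grid$disease)
  mark_key <- paste(context$all_marks$chemical, context$all_marks$disease,
                    sep = "\r")
  idx <- match(paste(grid$drug, grid$disease, sep = "\r"), mark_key)
  grid$curated_mark <- ifelse(is.na(idx), "none", context$all_marks$mark[idx])
  grid <- grid[order(-grid$score, grid$drug, grid$disease), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(grid)), drug = grid$drug,
                    disease = grid$disease, score = grid$score,
                    curated_mark = grid$curated_mark,
                    stringsAsFactors = FALSE)
  class(out) <- c("association_predictions", "data.frame")
  out
}

#' Precision of the top-ranked predictions
#'
#' The fraction of the `top_n` highest-ranked predictions whose curation
#' mark is `M`, `T` or `M&T` (a known association); `inferred` and `none`
#' count as potential/unknown.
#'
#' @param predictions an `association_predictions` data frame (from
#'   [predict_associations()] or [read_predictions()]).
#' @param top_n number of top predictions to evaluate (default 20).
#' @param known_marks marks that count as known.
#' @return A number in \[0, 1\].
#' @export
evaluate_precision <- function(predictions, top_n = 20,
                               known_marks = .KNOWN_MARKS) {
  if (!is_scalar_number(top_n) || top_n <= 0) {
    stopf("top_n must be a positive number")
  }
  if (top_n > nrow(predictions)) {
    stopf("top_n = %d exceeds the %d available predictions",
          top_n, nrow(predictions))
  }
  top <- predictions[order(predictions$rank), , drop = FALSE][seq_len(top_n), ]
  mean(top$curated_mark %in% known_marks)
}
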