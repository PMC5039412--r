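# TF-IDF weighting of binary occurrence profiles and cosine-similarity
# network construction.

#' TF-IDF weighting of an occurrence profile
#'
#' Converts a binary incidence matrix into term-frequency/inverse-document-
#' frequency weights: `w[i, j] = W[i, j] * log(N / n_i)`, where `N` is the
#' number of entities and `n_i` the number of entities displaying feature
#' `i`. Ubiquitous features (present in every entity) receive weight zero,
#' which down-weights uninformative side effects such as very common
#' adverse reactions. The logarithm base is immaterial downstream: it
#' rescales all weights of a feature uniformly and cancels in the cosine;
#' the natural log is used.
#'
#' @param profile an [occurrence_profile()].
#' @return An object of class `tfidf_profile`: a list with `entity_ids`,
#'   `feature_ids`, the sparse `weights` matrix (features x entities), `N`
#'   and the per-feature counts `n_i`.
#' @export
tfidf_weight <- function(profile) {
  if (!inherits(profile, "occurrence_profile")) {
    stopf("expected an occurrence_profile")
  }
  W <- profile$incidence
  N <- length(profile$entity_ids)
  n_i <- Matrix::rowSums(W)
  if (any(n_i == 0)) {
    stopf("feature(s) with no associated entity: %s",
          paste(profile$feature_ids[n_i == 0], collapse = ", "))
  }
  idf <- log(N / n_i)
  weights <- Matrix::Diagonal(x = idf) %*% W
  weights <- methods::as(weights, "CsparseMatrix")
  dimnames(weights) <- dimnames(W)
  structure(
    list(entity_ids = profile$entity_ids,
         feature_ids = profile$feature_ids,
         weights = weights, N = N,
         n_i = setNames(as.numeric(n_i), profile$feature_ids)),
    class = "tfidf_profile"
  )
}

#' @export
print.tfidf_profile <- function(x, ...) {
  cat(sprintf("<tfidf_profile> %d entities x %d features (N = %d)\n",
              length(x$entity_ids), length(x$feature_ids), x$N))
  invisible(x)
}

#' Cosine similarity between two weighted vectors
#'
#' `dot(u, v) / (|u| * |v|)`, clipped into \[0, 1\] against floating-point
#' rounding. With nonnegative TF-IDF weights the value is 0 exactly when
#' the supports are disjoint (no shared side effects) and 1 for identical
#' profiles.
#'
#' @param u,v numeric vectors of equal length, each with at least one
#'   nonzero coordinate.
#' @return A number in \[0, 1\].
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 1))  # 0.5
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stopf("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("cosine similarity of a zero vector is undefined")
  min(max(sum(u * v) / (nu * nv), 0), 1)
}

#' Build a cosine-similarity network from a TF-IDF profile
#'
#' Computes all pairwise cosine similarities between entity columns and
#' keeps the edges with similarity `>= cutoff`. Entities whose TF-IDF
#' vector is all-zero (every one of their features is ubiquitous) are
#' excluded with a warning; entities left without any surviving edge are
#' dropped from the network.
#'
#' @param profile a `tfidf_profile` from [tfidf_weight()].
#' @param cutoff similarity threshold in \[0, 1\]; edges strictly below it
#'   are discarded.
#' @return An undirected weighted `igraph` graph.
#' @export
build_similarity_network <- function(profile, cutoff) {
  if (!inherits(profile, "tfidf_profile")) stopf("expected a tfidf_profile")
  if (!is_scalar_number(cutoff) || cutoff < 0 || cutoff > 1) {
    stopf("cutoff must be a number in [0, 1]")
  }
  W <- profile$weights
  norms <- sqrt(Matrix::colSums(W^2))
  zero <- norms == 0
  if (any(zero)) {
    warnf("excluded %d entit%s with all-zero TF-IDF vectors: %s",
          sum(zero), if (sum(zero) == 1) "y" else "ies",
          paste(head(profile$entity_ids[zero], 5), collapse = ", "))
    W <- W[, !zero, drop = FALSE]
    norms <- norms[!zero]
  }
  if (ncol(W) < 2) stopf("fewer than two entities with nonzero profiles")
  normed <- W %*% Matrix::Diagonal(x = 1 / norms)
  S <- as.matrix(Matrix::crossprod(normed))
  dimnames(S) <- list(colnames(W), colnames(W))
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 0
  S[S < cutoff] <- 0
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE)
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}

#' Discard low-weight edges from a network
#'
#' Keeps edges with `weight >= cutoff`; nodes left isolated are dropped.
#' Used to restrict a similarity network to its reliable edges (e.g. a
#' symptom-based disease network thresholded at 0.5).
#'
#' @param network an undirected weighted `igraph` graph.
#' @param cutoff threshold in \[0, 1\].
#' @return The filtered `igraph` graph.
#' @export
filter_network <- function(network, cutoff) {
  if (!igraph::is_igraph(network)) stopf("expected an igraph network")
  if (!is_scalar_number(cutoff) || cutoff < 0 || cutoff > 1) {
    stopf("cutoff must be a number in [0, 1]")
  }
  w <- igraph::E(network)$weight
  g <- igraph::delete_edges(network, which(w < cutoff))
  igraph::delete_vertices(g, which(igraph::degree(g) == 0))
}
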