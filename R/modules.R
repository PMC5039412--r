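# Overlapping dense-module detection by greedy cohesiveness growth,
# in the style of ClusterONE: seed from high-strength nodes, grow/shrink
# each seed to a local cohesiveness maximum, merge heavily overlapping
# candidates, and keep sufficiently large, dense modules.

new_module_set <- function(modules, network = NULL) {
  structure(list(modules = modules, source_network = network),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d module(s)\n", length(x$modules)))
  if (length(x$modules)) {
    df <- as.data.frame(x)
    df$member_ids <- ifelse(nchar(df$member_ids) > 40,
                            paste0(substr(df$member_ids, 1, 37), "..."),
                            df$member_ids)
    print(head(df, 10))
    if (nrow(df) > 10) cat(sprintf("... and %d more\n", nrow(df) - 10))
  }
  invisible(x)
}

#' @export
as.data.frame.module_set <- function(x, ...) {
  if (!length(x$modules)) {
    return(data.frame(module_id = character(), member_ids = character(),
                      size = integer(), density = numeric(),
                      cohesiveness = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    module_id = vapply(x$modules, `[[`, character(1), "id"),
    member_ids = vapply(x$modules, function(m)
      paste(m$members, collapse = ","), character(1)),
    size = vapply(x$modules, function(m) length(m$members), integer(1)),
    density = vapply(x$modules, `[[`, numeric(1), "density"),
    cohesiveness = vapply(x$modules, `[[`, numeric(1), "cohesiveness"),
    p_value = vapply(x$modules, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
}

#' Extract module member vectors
#'
#' @param modules a `module_set`.
#' @return A named list of character vectors of member identifiers.
#' @export
module_members <- function(modules) {
  if (!inherits(modules, "module_set")) stopf("expected a module_set")
  setNames(lapply(modules$modules, `[[`, "members"),
           vapply(modules$modules, `[[`, character(1), "id"))
}

#' Cohesiveness of a node set
#'
#' `w_in / (w_in + w_bound + penalty * |S|)` where `w_in` is the total
#' weight of edges with both endpoints in the set and `w_bound` the total
#' weight of edges with exactly one endpoint inside. The penalty term
#' models unobserved connectivity: each member is charged a constant
#' amount of presumed external weight, which discourages modules held
#' together by single weak edges.
#'
#' @param network an undirected weighted `igraph` graph.
#' @param node_set character vector of vertex names (non-empty).
#' @param penalty nonnegative per-node penalty (default 2).
#' @return A number in \[0, 1\].
#' @export
cohesiveness <- function(network, node_set, penalty = 2) {
  if (!length(node_set)) stopf("node_set must be non-empty")
  ends <- igraph::as_edgelist(network)
  w <- igraph::E(network)$weight
  a_in <- ends[, 1] %in% node_set
  b_in <- ends[, 2] %in% node_set
  w_in <- sum(w[a_in & b_in])
  w_bound <- sum(w[xor(a_in, b_in)])
  denom <- w_in + w_bound + penalty * length(node_set)
  if (denom == 0) return(0)
  w_in / denom
}

# Grow/shrink a seed set to a local cohesiveness maximum over the dense
# adjacency matrix A (named, symmetric). Returns integer vertex indices.
grow_to_local_maximum <- function(A, strength, seed_idx, penalty) {
  n <- nrow(A)
  in_set <- logical(n)
  in_set[seed_idx] <- TRUE
  # incremental bookkeeping: w_in and per-node weight into the current set
  into_set <- A[, seed_idx, drop = FALSE]
  into_set <- if (length(seed_idx) > 1) rowSums(into_set) else as.numeric(into_set)
  w_in <- sum(A[seed_idx, seed_idx]) / 2
  coh <- function(w_in, size, w_bound) {
    d <- w_in + w_bound + penalty * size
    if (d == 0) 0 else w_in / d
  }
  node_names <- rownames(A)
  repeat {
    size <- sum(in_set)
    w_bound <- sum(into_set[!in_set])
    current <- coh(w_in, size, w_bound)
    # candidate additions: external nodes touching the set
    cand_add <- which(!in_set & into_set > 0)
    best_gain <- 1e-12
    best_move <- NULL
    if (length(cand_add)) {
      gain_in <- w_in + into_set[cand_add]
      gain_bound <- w_bound - into_set[cand_add] +
        (strength[cand_add] - into_set[cand_add])
      vals <- ifelse(gain_in + gain_bound + penalty * (size + 1) == 0, 0,
                     gain_in / (gain_in + gain_bound + penalty * (size + 1)))
      gains <- vals - current
      ord <- order(-gains, node_names[cand_add])
      if (gains[ord[1]] > best_gain) {
        best_gain <- gains[ord[1]]
        best_move <- list(type = "add", node = cand_add[ord[1]],
                          value = vals[ord[1]])
      }
    }
    if (size > 1) {
      cand_rm <- which(in_set)
      rm_in <- w_in - into_set[cand_rm]
      rm_bound <- w_bound + into_set[cand_rm] -
        (strength[cand_rm] - into_set[cand_rm])
      vals <- ifelse(rm_in + rm_bound + penalty * (size - 1) == 0, 0,
                     rm_in / (rm_in + rm_bound + penalty * (size - 1)))
      gains <- vals - current
      ord <- order(-gains, node_names[cand_rm])
      if (gains[ord[1]] > best_gain) {
        best_gain <- gains[ord[1]]
        best_move <- list(type = "remove", node = cand_rm[ord[1]],
                          value = vals[ord[1]])
      }
    }
    if (is.null(best_move)) break
    v <- best_move$node
    if (best_move$type == "add") {
      in_set[v] <- TRUE
      w_in <- w_in + into_set[v]
      into_set <- into_set + A[, v]
    } else {
      in_set[v] <- FALSE
      into_set <- into_set - A[, v]
      w_in <- w_in - into_set[v]
    }
  }
  which(in_set)
}

# Overlap score between two node sets: |A n B|^2 / (|A| |B|).
overlap_score <- function(a, b) {
  length(intersect(a, b))^2 / (length(a) * length(b))
}

module_density <- function(A, idx) {
  k <- length(idx)
  if (k < 2) return(0)
  sum(A[idx, idx]) / 2 / (k * (k - 1) / 2)
}

#' Detect overlapping dense modules in a weighted network
#'
#' Greedy cohesiveness clustering: nodes are visited in order of
#' decreasing weighted degree (ties broken lexicographically); each node
#' not yet covered by a cluster seeds a candidate set that is grown and
#' shrunk one node at a time until [cohesiveness()] is locally maximal.
#' Candidate pairs whose overlap score `|A.B|^2 / (|A| |B|)` reaches
#' `merge_overlap` are merged (and the merged set re-optimised so every
#' reported module remains a local maximum). Modules smaller than
#' `min_size` or sparser than `min_density` are discarded. Each surviving
#' module is annotated with its density, cohesiveness and a one-sided
#' Mann-Whitney p-value contrasting internal against boundary edge
#' weights ([module_pvalue()]).
#'
#' The procedure is fully deterministic: the same network always yields
#' the same module set.
#'
#' @param network an undirected weighted `igraph` graph.
#' @param penalty per-node cohesiveness penalty (default 2).
#' @param min_size minimum module size (default 3).
#' @param min_density minimum internal density (default 0.5).
#' @param merge_overlap overlap score at or above which candidate modules
#'   are merged (default 0.8).
#' @return A `module_set`; modules are ordered by decreasing size, then
#'   lexicographically by membership, with ids `M1`, `M2`, ...
#' @export
detect_modules <- function(network, penalty = 2, min_size = 3,
                           min_density = 0.5, merge_overlap = 0.8) {
  if (!igraph::is_igraph(network)) stopf("expected an igraph network")
  if (igraph::vcount(network) == 0) {
    warnf("empty network: no modules to detect")
    return(new_module_set(list(), network))
  }
  A <- weighted_adjacency(network)
  nodes <- rownames(A)
  strength <- rowSums(A)
  seed_order <- order(-strength, nodes)

  covered <- logical(length(nodes))
  candidates <- list()
  for (s in seed_order) {
    if (covered[s]) next
    idx <- grow_to_local_maximum(A, strength, s, penalty)
    covered[idx] <- TRUE
    candidates[[length(candidates) + 1]] <- sort(nodes[idx])
  }
  candidates <- unique(candidates)

  # iteratively merge heavily overlapping candidates, re-optimising unions
  repeat {
    merged <- FALSE
    n_c <- length(candidates)
    if (n_c < 2) break
    for (i in seq_len(n_c - 1)) {
      for (j in seq(i + 1, n_c)) {
        if (overlap_score(candidates[[i]], candidates[[j]]) >= merge_overlap) {
          union_idx <- match(union(candidates[[i]], candidates[[j]]), nodes)
          opt <- grow_to_local_maximum(A, strength, union_idx, penalty)
          candidates[[i]] <- sort(nodes[opt])
          candidates[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
    candidates <- unique(candidates)
  }

  keep <- vapply(candidates, function(m) {
    length(m) >= min_size && module_density(A, match(m, nodes)) >= min_density
  }, logical(1))
  candidates <- candidates[keep]
  if (!length(candidates)) return(new_module_set(list(), network))

  ord <- order(-lengths(candidates),
               vapply(candidates, paste, character(1), collapse = ","))
  candidates <- candidates[ord]
  mods <- lapply(seq_along(candidates), function(k) {
    m <- candidates[[k]]
    idx <- match(m, nodes)
    list(id = paste0("M", k), members = m,
         density = module_density(A, idx),
         cohesiveness = cohesiveness(network, m, penalty),
         p_value = module_pvalue(network, m))
  })
  new_module_set(mods, network)
}

#' Significance of a module's internal weights
#'
#' One-sided Mann-Whitney U test comparing the multiset of internal edge
#' weights against the multiset of boundary edge weights; a small p-value
#' means internal edges are stochastically heavier than the module's
#' connections to the rest of the network. The exact null distribution is
#' used when both samples have at most 20 tie-free observations, the
#' normal approximation with tie correction otherwise. A module with no
#' internal or no boundary edges offers no contrast and gets p = 1.
#'
#' @param network an undirected weighted `igraph` graph.
#' @param members character vector of module vertex names.
#' @return A p-value in (0, 1\].
#' @export
module_pvalue <- function(network, members) {
  ends <- igraph::as_edgelist(network)
  w <- igraph::E(network)$weight
  a_in <- ends[, 1] %in% members
  b_in <- ends[, 2] %in% members
  internal <- w[a_in & b_in]
  boundary <- w[xor(a_in, b_in)]
  if (!length(internal) || !length(boundary)) return(1)
  exact <- length(internal) <= 20 && length(boundary) <= 20 &&
    !anyDuplicated(c(internal, boundary))
  p <- suppressWarnings(
    stats::wilcox.test(internal, boundary, alternative = "greater",
                       exact = exact)$p.value
  )
  min(max(p, .Machine$double.xmin), 1)
}
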