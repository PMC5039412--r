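# Shared builders for the test suite.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Weighted undirected graph from a (from, to, weight) triple list.
make_graph <- function(from, to, weight) {
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = weight,
               stringsAsFactors = FALSE),
    directed = FALSE
  )
}

# k disjoint cliques with intra weights ~ U(0.8, 1) plus sparse weak
# inter-clique noise (weight < 0.2). Returns the graph and the planted
# member sets.
make_planted_cliques <- function(k, sizes, noise_edges = 2 * k, seed = 1) {
  set.seed(seed)
  stopifnot(length(sizes) == k)
  nodes <- sprintf("n%03d", seq_len(sum(sizes)))
  membership <- rep(seq_len(k), sizes)
  planted <- split(nodes, membership)
  names(planted) <- paste0("P", seq_len(k))
  from <- character(0); to <- character(0); w <- numeric(0)
  for (m in planted) {
    pr <- utils::combn(m, 2)
    from <- c(from, pr[1, ]); to <- c(to, pr[2, ])
    w <- c(w, stats::runif(ncol(pr), 0.8, 1.0))
  }
  if (noise_edges > 0 && k > 1) {
    for (i in seq_len(noise_edges)) {
      mods <- sample(k, 2)
      a <- sample(planted[[mods[1]]], 1)
      b <- sample(planted[[mods[2]]], 1)
      key <- pair_key_test(a, b)
      if (!(key %in% pair_key_test(from, to))) {
        from <- c(from, a); to <- c(to, b)
        w <- c(w, stats::runif(1, 0.05, 0.19))
      }
    }
  }
  list(graph = make_graph(from, to, w), planted = planted)
}

pair_key_test <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Random connected-ish weighted graph for path-similarity oracle trials.
random_subgraph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  nodes <- letters[seq_len(n)]
  pr <- utils::combn(nodes, 2)
  pick <- stats::runif(ncol(pr)) < p
  if (!any(pick)) pick[1] <- TRUE
  make_graph(pr[1, pick], pr[2, pick],
             round(stats::runif(sum(pick), 0.05, 1), 3))
}

# Independent brute-force oracle for path similarity: enumerate all simple
# paths with igraph and aggregate per length.
oracle_path_similarity <- function(g, a, b, max_len = igraph::vcount(g) - 1,
                                   aggregate = "max") {
  # no cutoff: igraph's cutoff-pruned search can miss same-length paths
  paths <- igraph::all_simple_paths(g, from = a, to = b, cutoff = -1)
  paths <- paths[lengths(paths) - 1L <= max_len]
  if (!length(paths)) return(0)
  len <- lengths(paths) - 1L
  wsum <- vapply(paths, function(p) {
    v <- as.integer(p)
    # interleaved (v1,v2, v2,v3, ...) pair vector, one entry per edge
    ids <- igraph::get_edge_ids(g, as.vector(rbind(v[-length(v)], v[-1])))
    sum(igraph::E(g)$weight[ids])
  }, numeric(1))
  per_len <- vapply(seq_len(max_len), function(i) {
    hit <- len == i
    if (!any(hit)) return(0)
    if (aggregate == "max") max(wsum[hit]) / i else mean(wsum[hit]) / i
  }, numeric(1))
  sum(per_len)
}
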