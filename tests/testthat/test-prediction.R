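test_that("path similarity matches hand-enumerated cases", {
  # adjacent pair in a two-node module: only the length-1 term
  g2 <- make_graph("a", "b", 0.7)
  expect_equal(path_similarity(g2, "a", "b"), 0.7)

  # triangle: direct edge plus the two-edge detour
  tri <- make_graph(c("a", "b", "a"), c("b", "c", "c"), c(0.6, 0.8, 0.9))
  expect_equal(path_similarity(tri, "a", "c"), 0.9 + (0.6 + 0.8) / 2)

  # disconnected nodes share no path of any length
  disc <- igraph::add_vertices(make_graph("a", "b", 0.5), 1, name = "c")
  expect_equal(path_similarity(disc, "a", "c"), 0)

  expect_error(path_similarity(tri, "a", "zz"), "belong")
  expect_error(path_similarity(tri, "a", "a"), "distinct")
})

test_that("path similarity equals the exhaustive simple-path oracle", {
  for (trial in 1:40) {
    n <- sample(4:10, 1)
    g <- random_subgraph(n, p = 0.45, seed = 100 + trial)
    nodes <- igraph::V(g)$name
    ab <- sample(nodes, 2)
    for (agg in c("max", "mean")) {
      expect_equal(
        path_similarity(g, ab[1], ab[2], aggregate = agg),
        oracle_path_similarity(g, ab[1], ab[2], aggregate = agg),
        tolerance = 1e-12
      )
    }
  }
})

test_that("intra-module similarities are symmetric and bounded by n - 1", {
  g <- random_subgraph(7, p = 0.5, seed = 77)
  members <- igraph::V(g)$name
  sim <- intra_module_similarity(g, members)
  expect_true(all(is.na(diag(sim))))
  expect_identical(sim, t(sim))
  expect_true(all(sim[upper.tri(sim)] <= length(members) - 1 + 1e-12))
  expect_true(all(sim[upper.tri(sim)] >= 0))
})

test_that("the bipartite context wires neighbors through known links", {
  toy <- worked_toy()
  ctx <- build_bipartite_context(toy$drug_members, toy$disease_members,
                                 toy$drug_network, toy$disease_network,
                                 toy$curated)
  expect_equal(nrow(ctx$known_links), 5)

  # no curated cross links: everything empties
  none <- curated_associations(character(0), character(0), character(0))
  ctx0 <- build_bipartite_context(toy$drug_members, toy$disease_members,
                                  toy$drug_network, toy$disease_network,
                                  none)
  expect_equal(nrow(ctx0$known_links), 0)
  expect_true(all(lengths(ctx0$n_di) == 0))
  expect_true(all(lengths(ctx0$n_dr) == 0))
  pred0 <- predict_associations(ctx0)
  expect_true(all(pred0$score == 0))

  # a drug with no within-module edges has an empty neighbor set
  lone_net <- igraph::add_vertices(toy$drug_network, 1, name = "drug9")
  ctx1 <- build_bipartite_context(c(toy$drug_members, "drug9"),
                                  toy$disease_members, lone_net,
                                  toy$disease_network, toy$curated)
  expect_length(ctx1$n_dr[["drug9"]], 0)

  expect_error(
    build_bipartite_context(character(0), toy$disease_members,
                            toy$drug_network, toy$disease_network,
                            toy$curated),
    "non-empty"
  )
})

test_that("cross-module scores propagate similarity over known links", {
  # v -- p (0.7) on the disease side; (w, p) known; w isolated on its side
  drug_net <- igraph::add_vertices(make_graph("w", "u", 0.4), 0)
  disease_net <- make_graph("v", "p", 0.7)
  cur <- curated_associations("w", "p", "M&T")
  ctx <- build_bipartite_context(c("w", "u"), c("v", "p"),
                                 drug_net, disease_net, cur)
  expect_equal(cross_module_score(ctx, "v", "w"), 0.7)

  # symmetric construction: both sums contribute 0.5 each
  dn <- make_graph("w", "q", 0.5)
  xn <- make_graph("v", "p", 0.5)
  cur2 <- curated_associations(c("w", "q"), c("p", "v"), c("T", "T"))
  ctx2 <- build_bipartite_context(c("w", "q"), c("v", "p"), dn, xn, cur2)
  expect_equal(cross_module_score(ctx2, "v", "w"), 1.0)

  expect_error(cross_module_score(ctx2, "nope", "w"), "not in context")
})

test_that("scores are monotone in the known-link set and local", {
  toy <- worked_toy()
  full_ctx <- build_bipartite_context(toy$drug_members, toy$disease_members,
                                      toy$drug_network, toy$disease_network,
                                      toy$curated)
  full <- predict_associations(full_ctx)
  key <- function(df) paste(df$drug, df$disease)
  full_scores <- setNames(full$score, key(full))
  for (drop in seq_len(nrow(toy$curated))) {
    cur <- curated_associations(toy$curated$chemical[-drop],
                                toy$curated$disease[-drop],
                                toy$curated$mark[-drop])
    ctx <- build_bipartite_context(toy$drug_members, toy$disease_members,
                                   toy$drug_network, toy$disease_network,
                                   cur)
    red <- predict_associations(ctx)
    red_scores <- setNames(red$score, key(red))[names(full_scores)]
    # removing a link never raises any score
    expect_true(all(red_scores <= full_scores + 1e-12))
    # and only cells sharing the removed link's drug or disease can change
    changed <- names(full_scores)[abs(red_scores - full_scores) > 1e-12]
    w <- toy$curated$chemical[drop]; p <- toy$curated$disease[drop]
    touches <- grepl(paste0("^", w, " "), changed) |
      grepl(paste0(" ", p, "$"), changed)
    expect_true(all(touches))
  }
})

test_that("predictions rank descending with lexicographic tie-breaks", {
  toy <- worked_toy()
  ctx <- build_bipartite_context(toy$drug_members, toy$disease_members,
                                 toy$drug_network, toy$disease_network,
                                 toy$curated)
  pred <- predict_associations(ctx)
  expect_equal(nrow(pred), 16)  # every cell of the 4 x 4 pair
  expect_equal(pred$rank, 1:16)
  expect_true(all(diff(pred$score) <= 1e-12))
  ord <- order(-pred$score, pred$drug, pred$disease)
  expect_equal(ord, seq_len(nrow(pred)))
  # known pairs are ranked alongside novel ones, labelled not excluded
  expect_true(any(pred$curated_mark == "M&T"))
  expect_true(any(pred$curated_mark == "none"))
})

test_that("precision counts curated marks among the top ranks", {
  pred <- data.frame(
    rank = 1:6,
    drug = paste0("d", 1:6), disease = paste0("x", 1:6),
    score = c(5, 4, 3, 2, 1, 0.5),
    curated_mark = c("M", "T", "none", "M&T", "inferred", "none"),
    stringsAsFactors = FALSE
  )
  class(pred) <- c("association_predictions", "data.frame")
  expect_equal(evaluate_precision(pred, top_n = 4), 3 / 4)
  expect_equal(evaluate_precision(pred, top_n = 6), 3 / 6)
  all_none <- transform(pred, curated_mark = "none")
  expect_equal(evaluate_precision(all_none, top_n = 6), 0)
  expect_error(evaluate_precision(pred, top_n = 0), "positive")
  expect_error(evaluate_precision(pred, top_n = 7), "exceeds")
})
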