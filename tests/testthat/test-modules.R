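test_that("cohesiveness matches hand-computed values", {
  clique <- make_graph(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1))
  expect_equal(cohesiveness(clique, c("a", "b", "c"), penalty = 0), 1)

  pend <- make_graph("a", "b", 0.7)
  expect_equal(cohesiveness(pend, "a", penalty = 0), 0)  # w_in = 0

  # unit triangle plus one pendant edge: w_in = 3, w_bound = 1
  tri <- make_graph(c("a", "a", "b", "c"), c("b", "c", "c", "d"),
                    c(1, 1, 1, 1))
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 0), 3 / 4)

  # the penalty enters the denominator once per member
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 2),
               3 / (3 + 1 + 6))
  expect_error(cohesiveness(tri, character(0)), "non-empty")
})

test_that("two weakly bridged cliques are recovered as two modules", {
  nodes1 <- c("a1", "a2", "a3", "a4")
  nodes2 <- c("b1", "b2", "b3", "b4")
  p1 <- utils::combn(nodes1, 2); p2 <- utils::combn(nodes2, 2)
  g <- make_graph(c(p1[1, ], p2[1, ], "a1"),
                  c(p1[2, ], p2[2, ], "b1"),
                  c(rep(1, 12), 0.05))
  mods <- detect_modules(g)
  members <- module_members(mods)
  expect_length(members, 2)
  expect_setequal(vapply(members, paste, character(1), collapse = ","),
                  c("a1,a2,a3,a4", "b1,b2,b3,b4"))
  # both planted cliques are local cohesiveness maxima
  for (m in members) {
    base <- cohesiveness(g, m)
    for (v in setdiff(igraph::V(g)$name, m)) {
      expect_lte(cohesiveness(g, c(m, v)), base)
    }
    for (v in m) {
      expect_lte(cohesiveness(g, setdiff(m, v)), base)
    }
  }
})

test_that("a complete graph yields one full module with density 1", {
  nodes <- paste0("v", 1:5)
  pr <- utils::combn(nodes, 2)
  g <- make_graph(pr[1, ], pr[2, ], rep(1, ncol(pr)))
  mods <- detect_modules(g)
  expect_length(mods$modules, 1)
  expect_setequal(mods$modules[[1]]$members, nodes)
  expect_equal(mods$modules[[1]]$density, 1)
})

test_that("networks with no qualifying module give an empty set", {
  g <- make_graph("a", "b", 0.9)  # below min_size everywhere
  mods <- detect_modules(g, min_size = 3)
  expect_length(mods$modules, 0)
  expect_warning(detect_modules(igraph::make_empty_graph(directed = FALSE)),
                 "empty network")
})

test_that("module detection is deterministic", {
  sim <- make_planted_cliques(3, c(4, 5, 6), seed = 11)
  m1 <- detect_modules(sim$graph)
  m2 <- detect_modules(sim$graph)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("reported modules are local cohesiveness maxima", {
  sim <- make_planted_cliques(3, c(4, 5, 6), seed = 3)
  mods <- detect_modules(sim$graph)
  expect_gt(length(mods$modules), 0)
  for (m in module_members(mods)) {
    base <- cohesiveness(sim$graph, m)
    for (v in setdiff(igraph::V(sim$graph)$name, m)) {
      expect_lte(cohesiveness(sim$graph, c(m, v)), base + 1e-12)
    }
    if (length(m) > 1) {
      for (v in m) {
        expect_lte(cohesiveness(sim$graph, setdiff(m, v)), base + 1e-12)
      }
    }
  }
})

test_that("density never increases when adding an unconnected node", {
  sim <- make_planted_cliques(2, c(4, 4), noise_edges = 0, seed = 5)
  g <- igraph::add_vertices(sim$graph, 1, name = "loner")
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  m <- sim$planted[[1]]
  dens <- function(mem) {
    k <- length(mem)
    sum(A[mem, mem]) / 2 / (k * (k - 1) / 2)
  }
  expect_lte(dens(c(m, "loner")), dens(m))
  expect_true(dens(m) >= 0 && dens(m) <= 1)
})

test_that("module significance contrasts internal vs boundary weights", {
  # 6 internal edges at 0.9 vs 6 boundary edges at 0.1: strong separation
  core <- c("a", "b", "c", "d")
  pr <- utils::combn(core, 2)
  g <- make_graph(
    c(pr[1, ], core[c(1, 2, 3, 4, 1, 2)]),
    c(pr[2, ], paste0("x", 1:6)),
    c(rep(0.9, 6), rep(0.1, 6))
  )
  expect_lt(module_pvalue(g, core), 0.05)

  # identical internal and boundary multisets carry no signal
  g2 <- make_graph(
    c(pr[1, ], core[c(1, 2, 3, 4, 1, 2)]),
    c(pr[2, ], paste0("x", 1:6)),
    rep(0.5, 12)
  )
  expect_gte(module_pvalue(g2, core), 0.5)

  # no boundary edges: no contrast, p = 1 by convention
  iso <- make_graph(pr[1, ], pr[2, ], rep(0.9, 6))
  expect_equal(module_pvalue(iso, core), 1)
})

test_that("exact Mann-Whitney branch agrees with the exact distribution", {
  # tie-free samples small enough for the exact null: complete separation
  core <- c("a", "b", "c")
  g <- make_graph(
    c("a", "a", "b", "a", "b", "c"),
    c("b", "c", "c", "x1", "x2", "x3"),
    c(0.91, 0.92, 0.93, 0.11, 0.12, 0.13)
  )
  # internal {0.91,0.92,0.93} all above boundary {0.11,0.12,0.13}:
  # one-sided exact p = 1 / choose(6, 3)
  expect_equal(module_pvalue(g, core), 1 / choose(6, 3), tolerance = 1e-12)
})
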