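test_that("vertex weights follow the core-clustering definition", {
  tri <- complete_graph(c("A", "B", "C"))
  expect_true(all(vertex_weights(tri) == 2.0))

  # degree below the cutoff zeroes the weight
  g <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("C", "A"), c("C", "L")))
  w <- vertex_weights(g)
  expect_equal(unname(w[["L"]]), 0)
  iso <- ppi_network(nodes = c("X", "Y"))
  expect_true(all(vertex_weights(iso) == 0))
})

test_that("planted clique vertices outweigh scale-free backbone vertices", {
  withr::with_seed(31, {
    backbone <- random_test_graph(9, 0.25, sprintf("B%02d", 1:9))
    clique_edges <- t(utils::combn(sprintf("K%d", 1:6), 2))
    bridge <- rbind(c("K1", "B01"))
    g <- ppi_network(rbind(igraph::as_edgelist(backbone), clique_edges, bridge))
    w <- vertex_weights(g)
    expect_gt(min(w[sprintf("K%d", 1:6)]), max(w[sprintf("B%02d", 1:9)]))
  })
})

test_that("highest-core-of-neighbourhood matches the peeling oracle", {
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(4:10, 1)
      g <- random_test_graph(n, stats::runif(1, 0.2, 0.8))
      w <- vertex_weights(g)
      A <- adjacency_of(g)
      deg <- rowSums(A)
      for (v in seq_len(n)) {
        nm <- rownames(A)[v]
        if (deg[v] < 2) {
          expect_equal(unname(w[[nm]]), 0)
        } else {
          nb <- c(v, which(A[v, ] > 0))
          hk <- peel_highest_core(A[nb, nb, drop = FALSE])
          expect_equal(unname(w[[nm]]), hk$k * hk$density, tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("disjoint cliques are recovered as separate complexes with density scores", {
  k5 <- sprintf("A%d", 1:5); k4 <- sprintf("B%d", 1:4)
  g <- ppi_network(rbind(t(utils::combn(k5, 2)), t(utils::combn(k4, 2))))
  mods <- predict_complexes(g)
  expect_length(mods, 2L)
  expect_setequal(mods[[1]]$members, k5)
  expect_setequal(mods[[2]]$members, k4)
  expect_equal(mods[[1]]$score, 5.0)
  expect_equal(mods[[2]]$score, 4.0)
  expect_true(mods[[1]]$seed %in% k5)
})

test_that("sparse paths yield no complexes", {
  p6 <- path_graph(sprintf("P%d", 1:6))
  expect_length(predict_complexes(p6), 0L)
})

test_that("complexes are vertex-disjoint, contain a k-core, and are deterministic", {
  spec <- synthetic_spec(n_nodes = 400L, n_seeds = 40L,
                         n_planted_modules = 2L, planted_size = 8L,
                         rng_seed = 13L)
  g <- generate_interactome(spec)
  mods <- predict_complexes(g)
  all_members <- unlist(lapply(mods, `[[`, "members"))
  expect_false(anyDuplicated(all_members) > 0)
  for (m in mods) {
    expect_true(m$seed %in% m$members)
    A <- adjacency_of(igraph::induced_subgraph(g, m$members))
    expect_gte(peel_highest_core(A)$k, 2)
    expect_equal(m$score,
                 2 * m$n_edges / (m$n_nodes * (m$n_nodes - 1)) * m$n_nodes)
  }
  mods2 <- predict_complexes(g)
  expect_identical(module_table(mods), module_table(mods2))
})

test_that("planted modules are recovered at >= 80% Jaccard (seeded instance)", {
  spec <- synthetic_spec(rng_seed = 3L)
  g <- generate_interactome(spec)
  mods <- predict_complexes(g)
  for (p in g$planted_modules) {
    best <- max(vapply(mods, function(m) jaccard(m$members, p), numeric(1)))
    expect_gte(best, 0.8)
  }
})

test_that("module retention is strict on both thresholds", {
  fake <- function(score, n) structure(
    list(members = sprintf("X%d", seq_len(n)), seed = "X1",
         score = score, n_nodes = n, n_edges = 0L),
    class = "network_module")
  kept <- filter_modules(list(fake(3.0, 10), fake(7.6, 65), fake(4.0, 6),
                              fake(3.3, 13)))
  expect_equal(vapply(kept, `[[`, numeric(1), "score"), c(7.6, 3.3))
  expect_length(filter_modules(list()), 0L)
})

test_that("fluff adds shared boundary members only when enabled", {
  # K4 with one boundary node attached to two clique members
  k4 <- sprintf("A%d", 1:4)
  g <- ppi_network(rbind(t(utils::combn(k4, 2)), c("B", "A1"), c("B", "A2")))
  no_fluff <- predict_complexes(g, mcode_params())
  expect_false("B" %in% unlist(lapply(no_fluff, `[[`, "members")))
  fluffed <- predict_complexes(g, mcode_params(fluff = TRUE, haircut = FALSE))
  expect_true("B" %in% unlist(lapply(fluffed, `[[`, "members")))
})
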