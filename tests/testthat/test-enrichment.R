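test_that("hypergeometric upper tail: degenerate cases and argument checks", {
  expect_equal(hypergeometric_p(0, 5, 6, 20), 1.0)
  # term covers the universe: every draw is a hit
  expect_equal(hypergeometric_p(6, 20, 6, 20), 1.0)
  expect_error(hypergeometric_p(7, 5, 6, 20), "inconsistent")
  expect_error(hypergeometric_p(2, 25, 6, 20), "inconsistent")
})

test_that("hypergeometric upper tail equals exhaustive enumeration", {
  expect_equal(hypergeometric_p(4, 5, 6, 20), bf_hyper_tail(4, 5, 6, 20),
               tolerance = 1e-12)
  withr::with_seed(42, {
    for (i in 1:10) {
      uni <- sample(8:25, 1)
      term <- sample(seq_len(uni), 1)
      mod <- sample(seq_len(uni), 1)
      ov <- sample(0:min(term, mod), 1)
      expect_equal(hypergeometric_p(ov, term, mod, uni),
                   bf_hyper_tail(ov, term, mod, uni), tolerance = 1e-12)
    }
  })
})

test_that("Bonferroni step-down equals the direct Holm formula", {
  expect_equal(bonferroni_step_down(0.04), 0.04)
  expect_equal(bonferroni_step_down(c(0.01, 0.01, 0.01)), rep(0.03, 3))
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- stats::runif(sample(1:6, 1))
      adj <- bonferroni_step_down(p)
      expect_equal(adj, holm_direct(p), tolerance = 1e-12)
      expect_true(all(adj >= p & adj <= 1))
      expect_true(all(diff(adj[order(p)]) >= -1e-12))
    }
  })
})

test_that("kappa agreement: identity, perfect disagreement, 2x2 oracle", {
  cat <- annotation_catalog(
    list(A = c("g1", "g2"), B = c("g1", "g2"), C = c("g3", "g4")),
    universe = c("g1", "g2", "g3", "g4"))
  km <- kappa_matrix(cat, gene_scope = c("g1", "g2", "g3", "g4"))
  expect_equal(km["A", "B"], 1.0)
  expect_equal(km["A", "C"], -1.0)
  expect_true(isSymmetric(km))

  withr::with_seed(11, {
    genes <- sprintf("g%02d", 1:12)
    for (i in 1:15) {
      t1 <- sample(genes, sample(1:10, 1))
      t2 <- sample(genes, sample(1:10, 1))
      cat2 <- annotation_catalog(list(T1 = t1, T2 = t2), universe = genes)
      km2 <- kappa_matrix(cat2, genes)
      expect_equal(km2["T1", "T2"],
                   kappa_2x2(genes %in% t1, genes %in% t2), tolerance = 1e-12)
    }
  })
})

test_that("kappa grouping is single-linkage and order-invariant", {
  ids <- c("A", "B", "C")
  km <- matrix(0, 3, 3, dimnames = list(ids, ids)); diag(km) <- 1
  expect_equal(unname(group_terms(km)), 1:3)

  km2 <- km
  km2["A", "B"] <- km2["B", "A"] <- 0.5
  km2["B", "C"] <- km2["C", "B"] <- 0.5
  km2["A", "C"] <- km2["C", "A"] <- 0.1
  g <- group_terms(km2)
  expect_true(length(unique(g)) == 1)  # transitive closure

  perm <- c("C", "A", "B")
  g_perm <- group_terms(km2[perm, perm])
  expect_equal(g_perm[names(g)], g)
})

test_that("module enrichment ranks a containing term first and respects top_n", {
  cat <- annotation_catalog(
    list(HIT = sprintf("g%d", 1:5), OTHER = sprintf("g%d", 4:12)),
    universe = sprintf("g%d", 1:20))
  res <- enrich_module(sprintf("g%d", 1:4), cat)
  expect_equal(res$term_id[1], "HIT")
  expect_true(all(res$p_corrected >= res$p_value))
  res_all <- enrich_module(sprintf("g%d", 1:4), cat, top_n = 10L)
  expect_equal(nrow(res_all), 2L)
  expect_error(enrich_module(character(), cat), "empty module")
  expect_warning(enrich_module(c("g1", "g2", "g3", "nope"), cat), "dropped")
})

test_that("planted-enrichment instances put the matched term at rank 1", {
  spec <- synthetic_spec(n_nodes = 800L, n_seeds = 80L,
                         n_planted_modules = 2L, planted_size = 10L,
                         rng_seed = 11L)
  g <- generate_interactome(spec)
  cat <- generate_annotations(g, spec)
  planted_terms <- attr(cat, "planted_terms")
  mods <- filter_modules(predict_complexes(g))
  for (i in seq_along(g$planted_modules)) {
    members <- g$planted_modules[[i]]
    best <- which.max(vapply(mods, function(m) jaccard(m$members, members),
                             numeric(1)))
    res <- enrich_module(mods[[best]], cat, module_id = names(planted_terms)[i])
    expect_equal(res$term_id[1], planted_terms[[i]])
    expect_lt(res$p_corrected[1], 0.05)
  }
})

test_that("enrichment output is deterministic and order-invariant", {
  withr::with_seed(3, {
    genes <- sprintf("g%03d", 1:60)
    terms <- lapply(1:6, function(i) sample(genes, 12))
    names(terms) <- sprintf("T%d", 1:6)
    cat1 <- annotation_catalog(terms, universe = genes)
    cat2 <- annotation_catalog(terms[rev(names(terms))], universe = genes)
    module <- sample(genes, 15)
    r1 <- enrich_module(module, cat1, top_n = 6L)
    r2 <- enrich_module(module, cat2, top_n = 6L)
    expect_equal(r1, r2)
  })
})
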