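test_that("published hub block is selected exactly, highest degree first", {
  tab <- laryngeal_centrality("up")
  hubs <- select_hubs(tab)
  expect_length(hubs, 20L)
  expect_equal(hubs[1], "YWHAZ")
  expect_equal(tab$degree[tab$symbol == "YWHAZ"], 1634L)
  expect_setequal(hubs, c("YWHAZ", "FN1", "PPP2R1A", "CDC37", "HNRNPA1",
                          "CAND1", "PABPC1", "MAPRE1", "HNRNPD", "XRCC5",
                          "PSMD2", "FUS", "KPNB1", "DHX9", "EEF1G",
                          "ALB", "NCL", "STAT1", "ACTR2", "CCT7"))
})

test_that("published bottleneck block is selected exactly by BC rank", {
  tab <- laryngeal_centrality("up")
  bn <- select_bottlenecks(tab)
  expect_length(bn, 20L)
  expect_setequal(bn, c("PDXK", "KHC", "YWHAZ", "FN1", "CAND1", "HNRNPA1",
                        "CDC37", "GNAI2", "PPP2R1A", "MAPRE1", "FUS",
                        "ENO1", "HNRNPD", "ACTR2", "KPNB1", "PSMD2",
                        "ALB", "HSPD1", "XRCC5", "STAT1"))
  expect_equal(tab$bc[tab$symbol == "YWHAZ"], 0.13462)
})

test_that("short tables are returned whole with a warning; ties break by symbol", {
  small <- suppressMessages(centrality_table(
    degree = c(E = 2L, D = 2L, F = 1L),
    bc = c(E = 0, D = 0, F = 0)))
  expect_warning(hubs <- select_hubs(small), "only 3")
  expect_equal(hubs, c("D", "E", "F"))
  # all-zero BC: lexicographically smallest symbols first
  expect_warning(bn <- select_bottlenecks(small), "only 3")
  expect_equal(bn, c("D", "E", "F"))
  # boundary tie resolved lexicographically
  tied <- suppressMessages(centrality_table(
    degree = c(B = 5L, A = 3L, C = 3L, D = 1L),
    bc = c(B = 0, A = 0, C = 0, D = 0)))
  expect_equal(select_hubs(tied, screen_params(top_k = 2L)), c("B", "A"))
})

test_that("hub-bottleneck intersections reproduce the published counts", {
  up <- laryngeal_centrality("up")
  hb_up <- intersect_hub_bottleneck(select_hubs(up), select_bottlenecks(up))
  expect_length(hb_up, 15L)
  expect_setequal(hb_up, c("YWHAZ", "FN1", "PPP2R1A", "CDC37", "HNRNPA1",
                           "CAND1", "MAPRE1", "HNRNPD", "XRCC5", "PSMD2",
                           "FUS", "KPNB1", "ALB", "STAT1", "ACTR2"))
  down <- laryngeal_centrality("down")
  hb_down <- intersect_hub_bottleneck(select_hubs(down),
                                      select_bottlenecks(down))
  expect_length(hb_down, 11L)
  expect_length(intersect_hub_bottleneck(c("A", "B"), c("C", "D")), 0L)
})

test_that("module-membership filtering is a plain union-intersection", {
  hb <- c("A", "B", "C")
  mods <- list(c("B", "X"), c("Y", "Z"))
  expect_equal(filter_by_module_membership(hb, mods), "B")
  expect_length(filter_by_module_membership(hb, list()), 0L)
  expect_equal(filter_by_module_membership(hb, list(c("A", "B", "C", "D"))),
               c("A", "B", "C"))
})

test_that("degree-cutoff panel selection is inclusive and validates degrees", {
  s <- laryngeal_screen()
  expect_setequal(s$panel, c("YWHAZ", "PPP2R1A", "HSP90AA1", "CALM3"))
  deg <- laryngeal_degrees()
  # PPP2R1A (1208) is kept by the inclusive cutoff; CDC37 (1158) is not
  expect_true(deg[["PPP2R1A"]] >= 1200 && deg[["CDC37"]] < 1200)
  expect_setequal(select_panel(s$module_resident, deg,
                               screen_params(degree_panel_cutoff = 0)),
                  s$module_resident)
  expect_length(select_panel(s$module_resident, deg,
                             screen_params(degree_panel_cutoff = 2020)), 0L)
  expect_equal(max(deg), 2019L)
  expect_error(select_panel(c("NOPE"), deg), "NOPE")
})

test_that("the cascade is monotone and invariant to input row order", {
  spec <- synthetic_spec(n_nodes = 400L, n_seeds = 60L,
                         n_planted_modules = 2L, planted_size = 8L,
                         rng_seed = 21L)
  g <- generate_interactome(spec)
  net <- expand_seed_neighborhood(draw_seed_list(g, spec), g)
  tab <- suppressMessages(rank_table(net))
  mods <- filter_modules(predict_complexes(net))
  params <- screen_params(top_k = 20L, degree_panel_cutoff = 10)
  res <- screen_cascade(tab, mods, params)
  expect_true(all(res$panel %in% res$module_resident))
  expect_true(all(res$module_resident %in% res$hub_bottlenecks))
  expect_true(all(res$hub_bottlenecks %in% union(res$hubs, res$bottlenecks)))
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  res2 <- screen_cascade(shuffled, mods, params)
  expect_identical(res[c("hub_bottlenecks", "module_resident", "panel")],
                   res2[c("hub_bottlenecks", "module_resident", "panel")])
})
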