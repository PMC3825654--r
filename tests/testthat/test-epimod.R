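test_that("edge weights are the mean of endpoint statistic magnitudes", {
  g <- igraph::make_graph(~ A - B, A - C)
  net <- build_weighted_network(g, data.frame(
    gene = c("A", "B"), z_dnam = c(4, -2)))  # C unmeasured
  ew <- setNames(igraph::E(net$graph)$weight,
                 apply(igraph::as_edgelist(net$graph), 1, paste,
                       collapse = "-"))
  expect_equal(unname(ew["A-B"]), 3.0)   # (|4| + |-2|) / 2
  expect_equal(unname(ew["A-C"]), 2.0)   # unmeasured node weighs 0

  net0 <- build_weighted_network(g, data.frame(gene = "A", z_dnam = 0))
  expect_true(all(igraph::E(net0$graph)$weight == 0))
  expect_error(build_weighted_network(igraph::make_empty_graph(0),
                                      data.frame(gene = "A", z_dnam = 1)),
               "empty")
})

test_that("the network is restricted to its largest connected component", {
  g <- igraph::graph_from_edgelist(
    rbind(c("A", "B"), c("B", "C"), c("X", "Y")), directed = FALSE)
  expect_message(
    net <- build_weighted_network(g, data.frame(gene = "A", z_dnam = 1)),
    "largest connected component")
  expect_setequal(igraph::V(net$graph)$name, c("A", "B", "C"))
  expect_identical(net$n_dropped, 2L)
})

test_that("modularity is the arithmetic mean internal edge weight", {
  g <- igraph::make_graph(~ A - B, B - C)
  net <- build_weighted_network(g, data.frame(
    gene = c("A", "B", "C"), z_dnam = c(1, 3, 5)))  # edges weigh 2 and 4
  expect_equal(module_modularity(net, c("A", "B", "C")), 3.0)
  expect_equal(module_modularity(net, c("A", "B")), 2.0)
  expect_error(module_modularity(net, c("A", "C")), "no edges")

  # star with leaf statistics 1, 2, 3 and hub 0: mean leaf edge = 1
  gs <- igraph::make_graph(~ H - L1, H - L2, H - L3)
  nets <- build_weighted_network(gs, data.frame(
    gene = c("H", "L1", "L2", "L3"), z_dnam = c(0, 1, 2, 3)))
  expect_equal(module_modularity(nets, c("H", "L1", "L2", "L3")), 1.0)

  # property: equals a brute-force mean over the induced edge list
  set.seed(401)
  net <- make_random_network(12)
  el <- igraph::as_edgelist(net$graph)
  w <- igraph::E(net$graph)$weight
  for (i in 1:25) {
    S <- sample(igraph::V(net$graph)$name, sample(3:8, 1))
    inS <- el[, 1] %in% S & el[, 2] %in% S
    if (!any(inS)) next
    expect_equal(module_modularity(net, S), mean(w[inS]))
  }
})

test_that("the seeded search recovers the planted clique of the toy graph", {
  net <- make_clique_path_network()
  set.seed(402)
  mem <- grow_module(net, "A", fem_config(max_module_size = 8))
  expect_setequal(mem, c("A", "B", "C", "D"))
  # ... which the exhaustive oracle confirms is optimal
  oracle <- oracle_best_module(net, "A")
  expect_setequal(oracle$members, c("A", "B", "C", "D"))
  expect_equal(module_objective(net, mem), oracle$objective)
})

test_that("with gamma = 0 the objective is monotone and fills the cap", {
  set.seed(403)
  g <- igraph::sample_gnp(30, 0.2)
  while (!igraph::is_connected(g)) g <- igraph::sample_gnp(30, 0.2)
  igraph::V(g)$name <- paste0("g", 1:30)
  net <- build_weighted_network(g, data.frame(gene = paste0("g", 1:30),
                                              z_dnam = 1))
  mem <- grow_module(net, "g1", fem_config(gamma = 0, max_module_size = 12))
  expect_length(mem, 12)
})

test_that("growth errors on absent or isolated seeds", {
  net <- make_clique_path_network()
  expect_error(grow_module(net, "ZZZ"), "absent")
  g <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("X", "Y")),
                                   directed = FALSE)
  net2 <- suppressMessages(
    build_weighted_network(g, data.frame(gene = "A", z_dnam = 2)))
  expect_error(grow_module(net2, "X"), "absent")
})

test_that("rewiring preserves degree sequences and simplicity", {
  set.seed(404)
  net <- make_random_network(15, p = 0.25)
  deg0 <- igraph::degree(net$graph)
  cfg <- fem_config(B_rewire = 20, swaps_per_edge = 10)
  nulls <- rewire_null(net, cfg)
  for (nr in nulls) {
    expect_identical(igraph::degree(nr$graph), deg0)
    expect_false(igraph::any_multiple(nr$graph) || igraph::any_loop(nr$graph))
    # node weights untouched, edge weights recomputed from them
    expect_identical(nr$node_weight, net$node_weight)
  }

  # a triangle admits no double-edge swap: rewiring returns the triangle
  gt <- igraph::make_ring(3)
  igraph::V(gt)$name <- c("A", "B", "C")
  nett <- build_weighted_network(gt, data.frame(gene = "A", z_dnam = 1))
  for (nr in rewire_null(nett, fem_config(B_rewire = 5)))
    expect_equal(igraph::ecount(igraph::intersection(nr$graph, gt)), 3)

  g1 <- igraph::make_graph(~ A - B)
  net1 <- build_weighted_network(g1, data.frame(gene = "A", z_dnam = 1))
  expect_warning(rewire_null(net1, fem_config(B_rewire = 2)), "fewer than 2")
})

test_that("permutation p-values honour the add-one bounds", {
  net <- make_clique_path_network(z_hot = 8)
  set.seed(405)
  mem <- grow_module(net, "A", fem_config(max_module_size = 8))
  obs <- module_modularity(net, mem)
  cfg <- fem_config(B_perm = 99, max_module_size = 8)
  pp <- permutation_pvalue(net, "A", obs, cfg)
  expect_length(pp$null_modularity, 99)
  expect_true(pp$p_perm >= 1 / 100 && pp$p_perm <= 1)
  # an observed value above every null hits the add-one lower bound exactly
  expect_equal(permutation_pvalue(net, "A", 1e6, cfg)$p_perm, 1 / 100)
  # an observed value below every null is not significant at all
  expect_equal(permutation_pvalue(net, "A", -1, cfg)$p_perm, 1.0)
  # rescore mode needs the member set
  expect_error(permutation_pvalue(net, "A", obs, cfg, mode = "rescore"),
               "members")
  pr <- permutation_pvalue(net, "A", obs, cfg, mode = "rescore",
                           members = mem)
  expect_true(pr$p_perm >= 1 / 100 && pr$p_perm <= 1)
})

test_that("detection finds a planted hotspot and nothing in flat weights", {
  sim <- make_small_benchmark()
  st <- dmc_stats(sim$beta, sim$beta_samples)
  gs <- select_promoter_cpg(sim$annotation, st)
  net <- build_weighted_network(sim$interactome, gs)
  cfg <- fem_config(n_seeds = 8, B_perm = 60, B_rewire = 10)
  set.seed(406)
  ep <- detect_epimods(net, cfg)
  expect_s3_class(ep, "epimod_result")
  expect_gt(nrow(ep$summary), 0)
  top <- ep$summary[1, ]
  expect_identical(top$classification, "EpiMod")
  rec <- score_recovery(ep, sim$truth)
  expect_gte(rec$f1, 0.8)
  # the hotspot stands far above its degree-preserving rewirings
  expect_gt(top$rewire_gap, 0)
  # every member set induces a connected subgraph containing its seed
  for (i in seq_along(ep$modules)) {
    sub <- igraph::induced_subgraph(net$graph, ep$modules[[i]])
    expect_true(igraph::is_connected(sub))
    expect_true(names(ep$modules)[i] %in% ep$modules[[i]])
  }

  # all-zero statistics: no seeds, no modules
  net0 <- build_weighted_network(sim$interactome,
                                 transform(gs, z_dnam = 0))
  ep0 <- detect_epimods(net0, cfg, rewire_diagnostic = FALSE)
  expect_identical(nrow(ep0$summary), 0L)
})

test_that("detection is reproducible given the RNG seed", {
  sim <- make_small_benchmark(seed = 12, n_nodes = 80, planted = 6)
  st <- dmc_stats(sim$beta, sim$beta_samples)
  gs <- select_promoter_cpg(sim$annotation, st)
  net <- build_weighted_network(sim$interactome, gs)
  cfg <- fem_config(n_seeds = 5, B_perm = 30, B_rewire = 5)
  set.seed(77)
  ep1 <- detect_epimods(net, cfg)
  set.seed(77)
  ep2 <- detect_epimods(net, cfg)
  expect_identical(ep1$summary, ep2$summary)
  expect_identical(ep1$modules, ep2$modules)
})
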