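test_that("the scale-free generator has the stated edge count and planting", {
  set.seed(701)
  g <- simulate_interactome(500, "scale_free")
  expect_equal(igraph::vcount(g), 500)
  expect_equal(igraph::ecount(g), 996)  # m * (n - 2) for m = 2
  expect_true(igraph::is_connected(g))

  gp <- simulate_interactome(200, "scale_free", planted_size = 10)
  planted <- igraph::graph_attr(gp, "planted")
  expect_length(planted, 10)
  expect_true(igraph::is_connected(
    igraph::induced_subgraph(gp, planted)))
  expect_false(igraph::any_multiple(gp) || igraph::any_loop(gp))

  ger <- simulate_interactome(120, "erdos_renyi", planted_size = 6)
  expect_true(igraph::is_connected(ger))
  expect_error(simulate_interactome(3, "scale_free", planted_size = 5),
               "larger than the network")
})

test_that("simulated beta values respect the planted design", {
  set.seed(702)
  g <- simulate_interactome(100, "scale_free", planted_size = 6)
  truth <- synthetic_truth(igraph::V(g)$name, igraph::graph_attr(g, "planted"),
                           delta_beta = 0.3, n_cases = 30, n_controls = 30)
  sim <- simulate_beta(truth, cpgs_per_gene = 2)
  expect_identical(dim(sim$beta), c(200L, 60L))
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  expect_identical(nrow(sim$annotation), 200L)
  # every gene has cpgs_per_gene CpGs with distinct TSS distances
  tab <- table(sim$annotation$gene)
  expect_true(all(tab == 2))

  # planted promoter CpGs separate the groups; background CpGs do not
  st <- dmc_stats(sim$beta, sim$samples)
  gs <- select_promoter_cpg(sim$annotation, st)
  planted_q <- gs$q[gs$gene %in% truth$planted_genes]
  expect_lt(median(planted_q), 0.1)
  bg_z <- abs(gs$z_dnam[!gs$gene %in% truth$planted_genes])
  pl_z <- abs(gs$z_dnam[gs$gene %in% truth$planted_genes])
  expect_gt(median(pl_z), median(bg_z) + 3)
})

test_that("a null methylation simulation carries no planted signal", {
  set.seed(703)
  g <- simulate_interactome(80, "scale_free", planted_size = 6)
  truth <- synthetic_truth(igraph::V(g)$name, igraph::graph_attr(g, "planted"),
                           delta_beta = 0, n_cases = 20, n_controls = 20)
  sim <- simulate_beta(truth, cpgs_per_gene = 1)
  st <- dmc_stats(sim$beta, sim$samples)
  gs <- select_promoter_cpg(sim$annotation, st)
  pl <- abs(gs$z_dnam[gs$gene %in% truth$planted_genes])
  bg <- abs(gs$z_dnam[!gs$gene %in% truth$planted_genes])
  expect_gt(suppressWarnings(wilcox.test(pl, bg)$p.value), 0.05)
})

test_that("simulated expression is under-expressed only when planted", {
  set.seed(704)
  g <- simulate_interactome(100, "scale_free", planted_size = 10)
  truth <- synthetic_truth(igraph::V(g)$name, igraph::graph_attr(g, "planted"),
                           delta_expr = 1.5, n_expr_cases = 40,
                           n_expr_controls = 40)
  ex <- simulate_expression(truth)
  expect_identical(dim(ex$expr), c(100L, 80L))
  es <- expression_stats(ex$expr, ex$samples)
  zpl <- es$z_expr[es$gene %in% truth$planted_genes]
  expect_gte(sum(zpl < 0), 9)  # at least 9 of 10 planted genes point down

  truth0 <- truth
  truth0$delta_expr <- 0
  ex0 <- simulate_expression(truth0)
  es0 <- expression_stats(ex0$expr, ex0$samples)
  zpl0 <- es0$z_expr[es0$gene %in% truth$planted_genes]
  expect_gt(suppressWarnings(
    wilcox.test(zpl0, es0$z_expr[!es0$gene %in% truth$planted_genes])$p.value),
    0.05)
})

test_that("recovery scoring arithmetic is exact", {
  truth <- list(planted_genes = paste0("p", 1:10))
  class(truth) <- "synthetic_truth"
  perfect <- list(m1 = paste0("p", 1:10))
  expect_equal(score_recovery(perfect, truth)$f1, 1.0)
  expect_equal(score_recovery(list(), truth)$recall, 0)
  mixed <- list(m1 = c(paste0("p", 1:10), paste0("x", 1:10)))
  sc <- score_recovery(mixed, truth)
  expect_equal(sc$precision, 0.5)
  expect_equal(sc$recall, 1.0)
  expect_equal(sc$f1, 2 / 3, tolerance = 1e-9)
})

test_that("generation is reproducible and round-trips through the readers", {
  set.seed(705)
  sim1 <- simulate_fem_dataset(n_nodes = 60, planted_size = 5,
                               n_cases = 10, n_controls = 10,
                               n_expr_cases = 8, n_expr_controls = 8)
  set.seed(705)
  sim2 <- simulate_fem_dataset(n_nodes = 60, planted_size = 5,
                               n_cases = 10, n_controls = 10,
                               n_expr_cases = 8, n_expr_controls = 8)
  expect_identical(sim1$beta, sim2$beta)
  expect_identical(sim1$expr, sim2$expr)
  expect_identical(igraph::as_edgelist(sim1$interactome),
                   igraph::as_edgelist(sim2$interactome))

  fb <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(sim1$beta, fb)
  expect_equal(read_beta_matrix(fb), sim1$beta)
  fn <- withr::local_tempfile(fileext = ".tsv")
  write_interactome(sim1$interactome, fn)
  g2 <- read_interactome(fn)
  expect_identical(igraph::ecount(g2), igraph::ecount(sim1$interactome))
  deg <- function(g) sort(igraph::degree(g)[sort(igraph::V(g)$name)])
  expect_identical(deg(g2), deg(sim1$interactome))
})
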