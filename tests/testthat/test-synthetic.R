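# synthetic: generator properties, planted truth, determinism.

test_that("generate_network hits the requested size and degree", {
  g <- generate_network(500, mean_degree = 4, seed = 1)
  expect_true(igraph::is_connected(g))
  expect_gte(igraph::vcount(g), 450)  # largest component of 500 nodes
  md <- mean(igraph::degree(g))
  expect_lt(abs(md - 4), 0.5)
  # same seed -> identical edge list
  g2 <- generate_network(500, mean_degree = 4, seed = 1)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  # power-law model: heavier than Poisson degree tail
  d <- igraph::degree(g)
  expect_gt(stats::var(d) / mean(d), 2)
  expect_error(generate_network(30, 4), ">= 50")
  expect_error(generate_network(100, 0.5), "unreachable")
})

test_that("duplication-divergence model produces a usable network", {
  g <- generate_network(120, mean_degree = 4, model = "duplication-divergence",
                        seed = 3)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
  expect_lt(abs(mean(igraph::degree(g)) - 4), 1)
  g2 <- generate_network(120, mean_degree = 4,
                         model = "duplication-divergence", seed = 3)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
})

test_that("generate_genesets: sizes, designated connected core, overlap", {
  g <- generate_network(300, seed = 5)
  gs <- generate_genesets(g, n_sets = 50, size_range = c(15, 80),
                          seed = 6, designated_core = 12)
  expect_length(gs, 50L)
  expect_true(all(lengths(gs) >= 15 & lengths(gs) <= 80))
  des <- attr(gs, "designated")
  core <- attr(gs, "designated_core")
  expect_true(all(core %in% gs[[des]]))
  expect_length(core, 12L)
  sub <- igraph::induced_subgraph(g, core)
  expect_true(igraph::is_connected(sub))
  # a 17-gene set has the scale of small curated pathways (2 found + 15
  # not found is representable)
  gs2 <- generate_genesets(g, n_sets = 5, size_range = c(17, 17), seed = 7,
                           designated_core = 10)
  expect_true(all(lengths(gs2) == 17))
})

test_that("generate_study: CV control, planted folds, missingness, map", {
  sim <- simulate_experiment(seed = 77, n_genes = 150, n_sets = 10,
                             size_range = c(12, 20), planted_size = 6,
                             design = c(CIS = 14, CONTROL = 8))
  st <- sim$study
  expect_equal(nrow(st$intensities), igraph::vcount(sim$network))
  # missingness close to 2%, never below 3 observations per group
  expect_lt(abs(mean(is.na(st$intensities)) - 0.02), 0.01)
  for (g in unique(st$groups)) {
    expect_true(all(rowSums(!is.na(group_matrix(st, g))) >= 3))
  }
  # intra-group CV near the 24% target
  cvs <- apply(group_matrix(st, "CONTROL"), 1,
               function(v) coefficient_of_variation(v))
  expect_gt(stats::median(cvs), 18)
  expect_lt(stats::median(cvs), 30)
  # planted genes: fold magnitude in range, both directions possible
  f <- sim$truth$planted_folds
  expect_true(all(pmax(f, 1 / f) >= 2 & pmax(f, 1 / f) <= 4.2))
  # all planted genes inside the designated pathway
  expect_true(all(sim$truth$planted_genes %in%
                    sim$genesets[[sim$truth$designated_pathway]]))
  expect_error(generate_study(truth = list(network = sim$network,
                                           target_cv = -1)), "CV")
})

test_that("planted fold is recovered from the intensities across seeds", {
  ok <- 0L
  for (s in 1:10) {
    sim <- simulate_experiment(seed = 100 + s, n_genes = 60, n_sets = 4,
                               size_range = c(12, 15), planted_size = 1,
                               fold_range = c(4.2, 4.2),
                               design = c(CIS = 14, CONTROL = 8))
    gene <- sim$truth$planted_genes
    prot <- names(which(unclass(sim$map) == gene))
    realized <- fold_change(group_matrix(sim$study, "CIS")[prot, ],
                            group_matrix(sim$study, "CONTROL")[prot, ])
    mag <- max(realized, 1 / realized)  # direction is random per gene
    if (mag >= 3.4 && mag <= 5.0) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})

test_that("null design selects (almost) nothing", {
  sim <- simulate_experiment(seed = 31, n_genes = 150, n_sets = 10,
                             size_range = c(12, 20), planted_size = 0,
                             design = c(CIS = 12, CONTROL = 8))
  res <- group_differential(sim$study, sim$map, "CIS", "CONTROL")
  # selection needs BOTH >= 2-fold and p < 0.05: at CV 24% a 2-fold sampling
  # artefact is essentially impossible
  expect_lte(sum(res$selected), 2L)
})

test_that("truth manifest round-trips through TSV exactly", {
  sim <- simulate_experiment(seed = 19, n_genes = 80, n_sets = 5,
                             size_range = c(12, 15), planted_size = 5,
                             design = c(CIS = 6, CONTROL = 6))
  f <- tempfile()
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(sort(back$planted_genes), sort(sim$truth$planted_genes))
  expect_equal(back$planted_folds[sort(back$planted_genes)],
               sim$truth$planted_folds[sort(back$planted_genes)],
               tolerance = 1e-12)
  expect_identical(back$designated_pathway, sim$truth$designated_pathway)
  expect_identical(back$design, sim$truth$design)
  expect_equal(back$target_cv, sim$truth$target_cv)
})

test_that("everything flows from the master seed bit-identically", {
  a <- simulate_experiment(seed = 8, n_genes = 80, n_sets = 5,
                           size_range = c(12, 15), planted_size = 4,
                           design = c(CIS = 5, CONTROL = 5))
  b <- simulate_experiment(seed = 8, n_genes = 80, n_sets = 5,
                           size_range = c(12, 15), planted_size = 4,
                           design = c(CIS = 5, CONTROL = 5))
  expect_identical(a$study$intensities, b$study$intensities)
  expect_identical(igraph::as_edgelist(a$network),
                   igraph::as_edgelist(b$network))
  expect_identical(unclass(a$genesets), unclass(b$genesets))
  expect_identical(a$truth$planted_folds, b$truth$planted_folds)
})
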