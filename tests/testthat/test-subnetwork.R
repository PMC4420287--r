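# subnetwork: scoring, calibration, annealing search, overlap rule.

test_that("p_to_z values, monotonicity, clamping, errors", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.0227501), 2, tolerance = 1e-3)
  # extreme p is clamped, stays finite and equals the clamp boundary value
  expect_equal(p_to_z(1e-300), p_to_z(1e-16))
  expect_true(is.finite(p_to_z(1e-300)))
  expect_error(p_to_z(0), "inside")
  expect_error(p_to_z(1), "inside")
  p <- sort(stats::runif(50, 1e-6, 1 - 1e-6))
  expect_true(all(diff(p_to_z(p)) <= 0))  # monotone decreasing
})

test_that("aggregate_z: identities and null distribution", {
  expect_equal(aggregate_z(2), 2)
  expect_equal(aggregate_z(c(1, 1, 1, 1)), 2)
  expect_error(aggregate_z(numeric(0)), "empty")
  # z_i iid N(0,1) => z_A ~ N(0,1): KS on 10,000 draws
  za <- panet:::with_seed(123, {
    vapply(1:10000, function(i) aggregate_z(stats::rnorm(7)), numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(za, "pnorm")$p.value), 0.01)
  # monotonicity: lowering any member p never decreases z_A
  panet:::with_seed(5, {
    for (i in 1:20) {
      p <- stats::runif(6, 0.01, 0.99)
      j <- sample(6, 1)
      p2 <- p
      p2[j] <- p[j] * stats::runif(1)
      expect_gte(aggregate_z(p_to_z(p2)), aggregate_z(p_to_z(p)))
    }
  })
})

test_that("make_gene_scores aligns with the network", {
  g <- named_path_graph(5)
  expect_message(
    sc <- make_gene_scores(c(N01 = 0.01, N02 = 0.5, XX = 0.2), g),
    "dropped 1")
  expect_setequal(names(sc$p), igraph::V(g)$name)
  expect_equal(unname(sc$p[["N03"]]), 0.999)  # unscored genes disfavoured
  expect_equal(unname(sc$p[["N01"]]), 0.01)
})

test_that("calibration: null behaviour, exact k=1, degeneracy guard", {
  g <- connected_gnm(300, 700, seed = 2)
  p <- panet:::with_seed(31, stats::setNames(stats::runif(300),
                                             igraph::V(g)$name))
  sc <- make_gene_scores(p, g)
  cal <- calibrate_scores(sc, g, k_range = c(1, 4, 8), mc_samples = 2000,
                          seed = 17)
  # uniform p: the z_A background is near-standard-normal. The Monte-Carlo
  # mean conditions on the one realised z vector, so it carries a
  # O(sqrt(k/n)) offset on a finite network — hence the sanity band here;
  # the exact statement (standardised fresh draws ~ N(0,1)) follows.
  expect_true(all(abs(cal$mu) < 0.5))
  expect_true(all(abs(cal$sigma - 1) < 0.3))
  cv <- panet:::calibration_vectors(cal)
  s8 <- panet:::with_seed(99, {
    adj <- panet:::adj_index_list(g)
    z <- unname(sc$z[igraph::V(g)$name])
    vapply(1:500, function(i) {
      idx <- panet:::sample_connected_idx(adj, 8)
      (sum(z[idx]) / sqrt(8) - cv$mu[8]) / cv$sigma[8]
    }, numeric(1))
  })
  expect_lt(abs(mean(s8)), 0.15)
  expect_gt(stats::sd(s8), 0.85)
  expect_lt(stats::sd(s8), 1.15)
  # k = 1 row is the exact mean/sd over all gene z-scores
  expect_equal(cal$mu[cal$k == 1], mean(sc$z))
  expect_equal(cal$sigma[cal$k == 1], stats::sd(sc$z))
  # deterministic given seed
  cal2 <- calibrate_scores(sc, g, k_range = c(1, 4, 8), mc_samples = 2000,
                           seed = 17)
  expect_identical(cal, cal2)
  # all z equal -> degenerate
  sc0 <- make_gene_scores(stats::setNames(rep(0.5, igraph::vcount(g)),
                                          igraph::V(g)$name), g)
  expect_error(calibrate_scores(sc0, g, k_range = 1:3, mc_samples = 100),
               "degenerate")
  expect_error(calibrate_scores(sc, g, k_range = 1:3, mc_samples = 50),
               "mc_samples")
})

test_that("score_subnetwork centres and scales against the background", {
  g <- named_path_graph(6)
  z <- c(2, 1, 0, -1, 0.5, 1.5)
  p <- stats::setNames(stats::pnorm(z, lower.tail = FALSE),
                       igraph::V(g)$name)
  sc <- make_gene_scores(p, g)
  cal <- structure(data.frame(k = 1:3, mu = c(0.5, 0.2, 0.1),
                              sigma = c(1, 2, 0.5)),
                   class = c("sa_calibration", "data.frame"))
  s2 <- score_subnetwork(c("N01", "N02"), sc, cal, g)
  zA <- (z[1] + z[2]) / sqrt(2)
  expect_equal(s2$z_A, zA, tolerance = 1e-10)
  expect_equal(s2$s_A, (zA - 0.2) / 2, tolerance = 1e-10)
  # z_A == mu_k -> 0; z_A == mu_k + sigma_k -> 1 (constructed)
  cal0 <- structure(data.frame(k = 1:3, mu = c(z[1], 0, 0),
                               sigma = c(0.7, 1, 1)),
                    class = c("sa_calibration", "data.frame"))
  expect_equal(score_subnetwork("N01", sc, cal0, g)$s_A, 0)
  cal1 <- structure(data.frame(k = 1:3, mu = c(z[1] - 0.7, 0, 0),
                               sigma = c(0.7, 1, 1)),
                    class = c("sa_calibration", "data.frame"))
  expect_equal(score_subnetwork("N01", sc, cal1, g)$s_A, 1)
  # disconnected set and out-of-range size are rejected
  expect_error(score_subnetwork(c("N01", "N03"), sc, cal, g), "connected")
  expect_error(score_subnetwork(c("N01", "N02", "N03", "N04"), sc, cal, g),
               "calibrated range")
})

test_that("annealing finds the single hot gene on a path graph", {
  g <- named_path_graph(20)
  p <- stats::setNames(rep(0.99, 20), igraph::V(g)$name)
  p[["N07"]] <- 1e-6
  sc <- make_gene_scores(p, g)
  # path graphs with near-constant z have a degenerate background at large
  # k (every size-k window contains the hot gene); restrict to k <= 10
  cal <- calibrate_scores(sc, g, k_range = 1:10, mc_samples = 300, seed = 4)
  res <- anneal_search(g, sc, cal, search_params(sa_iterations = 3000,
                                                 restarts = 3, seed = 11))
  cv <- panet:::calibration_vectors(cal)
  oracle <- oracle_best_score(g, sc$z[igraph::V(g)$name], cv$mu, cv$sigma)
  expect_equal(res$s_A, oracle$score, tolerance = 1e-9)
  expect_true("N07" %in% res$genes)
  # determinism
  res2 <- anneal_search(g, sc, cal, search_params(sa_iterations = 3000,
                                                  restarts = 3, seed = 11))
  expect_identical(res$genes, res2$genes)
  expect_identical(res$s_A, res2$s_A)
})

test_that("planted 10-gene hot module scores s_A > 3 and is recovered", {
  sim <- simulate_experiment(seed = 41, n_genes = 200, n_sets = 10,
                             size_range = c(12, 20), planted_size = 10,
                             design = c(CIS = 6, CONTROL = 6))
  g <- sim$network
  planted <- sim$truth$planted_genes
  p <- panet:::with_seed(42, {
    pv <- stats::setNames(stats::runif(igraph::vcount(g)),
                          igraph::V(g)$name)
    pv[planted] <- stats::runif(length(planted), 1e-6, 1e-3)
    pv
  })
  sc <- make_gene_scores(p, g)
  cal <- calibrate_scores(sc, g, k_range = 1:20, mc_samples = 300, seed = 5)
  planted_mod <- score_subnetwork(planted, sc, cal, g)
  expect_gt(planted_mod$s_A, 3)
  found <- anneal_search(g, sc, cal,
                         search_params(sa_iterations = 10000, restarts = 5,
                                       seed = 6))
  expect_gte(jaccard(found$genes, planted), 0.5)
})

test_that("find_subnetworks respects the overlap rule and ordering", {
  sim <- simulate_experiment(seed = 13, n_genes = 150, n_sets = 8,
                             size_range = c(12, 20), planted_size = 8,
                             design = c(CIS = 6, CONTROL = 6))
  g <- sim$network
  p <- panet:::with_seed(14, stats::setNames(stats::runif(igraph::vcount(g)),
                                             igraph::V(g)$name))
  sc <- make_gene_scores(p, g)
  cal <- calibrate_scores(sc, g, k_range = 1:20, mc_samples = 200, seed = 15)
  params <- search_params(n_modules = 4, sa_iterations = 1500, restarts = 2,
                          seed = 16)
  mods <- find_subnetworks(g, sc, cal, params)
  expect_gte(length(mods), 1L)
  expect_lte(length(mods), 4L)
  sA <- vapply(mods, `[[`, numeric(1), "s_A")
  expect_true(all(diff(sA) <= 0))  # sorted descending
  if (length(mods) > 1) {
    for (i in seq_along(mods)) for (j in seq_len(i - 1L)) {
      expect_lte(overlap_fraction(mods[[i]]$genes, mods[[j]]$genes), 0.5)
    }
  }
  # every module is connected in the graph
  for (m in mods) {
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, m$genes)))
  }
  # n_modules = 1 -> singleton
  mods1 <- find_subnetworks(g, sc, cal,
                            search_params(n_modules = 1, sa_iterations = 1000,
                                          restarts = 2, seed = 16))
  expect_length(mods1, 1L)
})

test_that("overlap_fraction uses the smaller-set denominator", {
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_fraction(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_fraction(letters[1:5], letters[1:10]), 1)
  expect_error(overlap_fraction(character(0), "a"), "empty")
})
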