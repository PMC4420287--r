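# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths: the hypergeometric oracle recomputes pmfs
# from binomial coefficients, and the subgraph oracle enumerates every
# connected vertex set (ESU recursion) instead of annealing.

# Two-sided minimum-likelihood hypergeometric p by full enumeration with
# choose() ratios (independent of stats::dhyper).
oracle_two_sided_hypergeom <- function(x, N, K, n) {
  support <- max(0, K + n - N):min(K, n)
  prob <- vapply(support, function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, numeric(1)) / choose(N, n)
  px <- prob[support == x]
  min(1, sum(prob[prob <= px * (1 + 1e-7)]))
}

# Enumerate all connected vertex sets of a graph given its integer
# adjacency list (ESU: each set visited exactly once); calls f(members) on
# each.
for_each_connected_set <- function(adj, f) {
  n <- length(adj)
  rec <- function(sub, ext, cn) {
    f(sub)
    while (length(ext)) {
      w <- ext[1L]
      ext <- ext[-1L]
      nb <- adj[[w]]
      newc <- nb[nb > sub[1L] & !(nb %in% cn)]
      rec(c(sub, w), c(ext, newc), union(cn, nb))
    }
  }
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    rec(v, nb[nb > v], union(v, nb))
  }
  invisible(NULL)
}

# Best calibrated score over all connected sets (sizes with a usable
# sigma only). mu/sigma are lookup vectors indexed by k.
oracle_best_score <- function(graph, z, mu, sigma) {
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  best <- -Inf
  best_set <- integer(0)
  for_each_connected_set(adj, function(sub) {
    k <- length(sub)
    if (k <= length(sigma) && is.finite(sigma[k]) && sigma[k] > 0) {
      s <- (sum(z[sub]) / sqrt(k) - mu[k]) / sigma[k]
      if (s > best) {
        best <<- s
        best_set <<- sub
      }
    }
  })
  list(score = best, set = sort(igraph::V(graph)$name[best_set]))
}

# Connected 20-node random graph (resampled until connected).
connected_gnm <- function(n, m, seed) {
  g <- panet:::with_seed(seed, {
    repeat {
      gg <- igraph::sample_gnm(n, m)
      if (igraph::is_connected(gg)) break
    }
    gg
  })
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# Path graph with named vertices.
named_path_graph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# Small two-group study: planted fold on protein P1, null on the rest.
tiny_study <- function(n_case = 6, n_control = 6, n_proteins = 5,
                       fold = 1, cv = 20, seed = 1) {
  panet:::with_seed(seed, {
    sdlog <- sqrt(log(1 + (cv / 100)^2))
    base <- stats::rlnorm(n_proteins, log(1000), 0.5)
    eff <- rep(1, n_proteins)
    eff[1] <- fold
    m <- cbind(
      matrix(stats::rlnorm(n_proteins * n_case, -sdlog^2 / 2, sdlog),
             n_proteins) * base * eff,
      matrix(stats::rlnorm(n_proteins * n_control, -sdlog^2 / 2, sdlog),
             n_proteins) * base)
    dimnames(m) <- list(sprintf("P%d", seq_len(n_proteins)),
                        c(sprintf("c%02d", seq_len(n_case)),
                          sprintf("k%02d", seq_len(n_control))))
    grp <- stats::setNames(rep(c("CASE", "CONTROL"), c(n_case, n_control)),
                           colnames(m))
    intensity_study(m, grp)
  })
}

tiny_map <- function(n_proteins = 5) {
  protein_gene_map(sprintf("P%d", seq_len(n_proteins)),
                   sprintf("G%d", seq_len(n_proteins)))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
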