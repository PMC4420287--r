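# Active-subnetwork identification. Gene p-values are converted to
# standard-normal upper quantiles z_i = qnorm(1 - p_i); a candidate gene set
# A of size k is scored by the aggregate z_A = sum(z_i)/sqrt(k), standardised
# against a Monte-Carlo background of random connected size-k sets
# (s_A = (z_A - mu_k)/sigma_k) so that modules of different sizes are
# comparable. High-scoring connected modules are found by simulated
# annealing with geometric cooling; multiple modules are extracted by
# repeated restarts with an overlap-rejection rule.

P_EPS <- 1e-16

#' Convert a p-value to a z-score
#'
#' Standard-normal upper quantile `z = qnorm(1 - p)`, monotone decreasing in
#' p. Values are clamped into `[1e-16, 1 - 1e-16]` before inversion so z is
#' always finite.
#'
#' @param p numeric vector of p-values, each strictly inside (0, 1).
#' @return numeric vector of z-scores.
#' @export
#' @examples
#' p_to_z(0.5)  # 0
p_to_z <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("p-values must lie strictly inside (0, 1)", call. = FALSE)
  }
  stats::qnorm(clamp(p, P_EPS, 1 - P_EPS), lower.tail = FALSE)
}

#' Aggregate z-score of a gene set
#'
#' `z_A = sum(z_i) / sqrt(k)`: under independent standard-normal member
#' scores, z_A is again standard normal for every set size k.
#'
#' @param z_values numeric vector of member z-scores (non-empty).
#' @return the aggregate score.
#' @export
aggregate_z <- function(z_values) {
  if (!length(z_values)) stop("empty gene set", call. = FALSE)
  sum(z_values) / sqrt(length(z_values))
}

#' Build a gene score map on a network
#'
#' Aligns per-gene p-values with the network nodes: genes scored but absent
#' from the network are dropped (with a message reporting the count); network
#' genes without a score receive `unscored_p` (default 0.999) so they are
#' strongly disfavoured by the search but remain usable as connectors.
#' p-values equal to 1 (e.g. from a t-test on identical groups) are clamped
#' into the open interval before z-conversion.
#'
#' @param p named numeric vector of p-values (names = gene symbols).
#' @param network igraph PPI network with named vertices.
#' @param unscored_p p-value assigned to network genes without a score.
#' @return an object of class `gene_scores`: list with named vectors `p` and
#'   `z` covering exactly the network genes.
#' @export
make_gene_scores <- function(p, network, unscored_p = 0.999) {
  validate_network(network)
  if (is.null(names(p))) stop("`p` must be named by gene symbol", call. = FALSE)
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  genes <- igraph::V(network)$name
  dropped <- setdiff(names(p), genes)
  if (length(dropped)) {
    message(sprintf("make_gene_scores: dropped %d scored gene(s) absent from the network",
                    length(dropped)))
  }
  pv <- rep(unscored_p, length(genes))
  names(pv) <- genes
  keep <- intersect(names(p), genes)
  pv[keep] <- p[keep]
  pv <- clamp(pv, P_EPS, 1 - P_EPS)
  structure(list(p = pv, z = p_to_z(pv)), class = "gene_scores")
}

# Integer adjacency list of a network (index space 1..n).
adj_index_list <- function(network) {
  lapply(igraph::as_adj_list(network, mode = "all"), as.integer)
}

#' Sample a random connected gene set by random-walk growth
#'
#' Starts at a uniformly chosen node and repeatedly adds a uniformly chosen
#' boundary neighbour until the set has `k` members. This sampler defines
#' the calibration background; it is not uniform over all connected size-k
#' sets (documented limitation).
#'
#' @param network igraph network with named vertices.
#' @param k set size.
#' @param seed optional integer seed for a deterministic draw.
#' @return character vector of `k` gene symbols inducing a connected
#'   subgraph.
#' @export
sample_connected_set <- function(network, k, seed = NULL) {
  adj <- adj_index_list(network)
  draw <- function() sample_connected_idx(adj, k)
  idx <- if (is.null(seed)) draw() else with_seed(seed, draw())
  igraph::V(network)$name[idx]
}

# Random-walk growth in index space; retries if the start component is
# exhausted before reaching size k.
sample_connected_idx <- function(adj, k, max_tries = 100L) {
  n <- length(adj)
  if (k > n) stop("k exceeds network size", call. = FALSE)
  for (try in seq_len(max_tries)) {
    v <- sample.int(n, 1L)
    members <- integer(k)
    inset <- logical(n)
    members[1L] <- v
    inset[v] <- TRUE
    boundary <- adj[[v]]
    ok <- TRUE
    if (k > 1L) for (i in 2:k) {
      boundary <- boundary[!inset[boundary]]
      if (!length(boundary)) { ok <- FALSE; break }
      u <- boundary[[sample.int(length(boundary), 1L)]]
      members[i] <- u
      inset[u] <- TRUE
      boundary <- c(boundary, adj[[u]])
    }
    if (ok) return(members)
  }
  stop("could not sample a connected set of size ", k,
       " (component too small?)", call. = FALSE)
}

#' Monte-Carlo size calibration of aggregate scores
#'
#' For each k in `k_range`, estimates the mean and standard deviation of
#' `z_A` over `mc_samples` random connected size-k sets (random-walk grown).
#' k = 1 is computed exactly by enumeration over all genes. Sizes whose
#' background is degenerate (a single reachable set, sd 0) are recorded as
#' `NA` and excluded from the search range; if *all* gene scores are
#' identical the calibration is degenerate everywhere and an error is
#' raised.
#'
#' @param score_map a [make_gene_scores] object.
#' @param network igraph network the scores live on.
#' @param k_range integer vector of sizes to calibrate (must cover every
#'   size the search may visit).
#' @param mc_samples Monte-Carlo draws per size (>= 100).
#' @param seed integer seed; the table is deterministic given it.
#' @return object of class `sa_calibration`: data.frame with columns
#'   `k, mu, sigma` and attributes `mc_samples`, `seed`.
#' @export
calibrate_scores <- function(score_map, network, k_range = 1:20,
                             mc_samples = 1000, seed = 1) {
  stopifnot(inherits(score_map, "gene_scores"))
  validate_network(network)
  if (mc_samples < 100) stop("mc_samples must be >= 100", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L)) stop("k_range must be positive", call. = FALSE)
  n <- igraph::vcount(network)
  if (max(k_range) > n) stop("k_range exceeds network size", call. = FALSE)
  z <- score_map$z[igraph::V(network)$name]
  if (stats::sd(z) == 0) {
    stop("degenerate calibration: all gene scores are identical", call. = FALSE)
  }
  adj <- adj_index_list(network)
  tab <- with_seed(seed, {
    res <- lapply(k_range, function(k) {
      if (k == 1L) {
        return(c(mu = mean(z), sigma = stats::sd(z)))
      }
      za <- vapply(seq_len(mc_samples), function(i) {
        idx <- sample_connected_idx(adj, k)
        sum(z[idx]) / sqrt(k)
      }, numeric(1))
      c(mu = mean(za), sigma = stats::sd(za))
    })
    do.call(rbind, res)
  })
  out <- data.frame(k = k_range, mu = tab[, "mu"], sigma = tab[, "sigma"])
  deg <- !is.finite(out$sigma) | out$sigma <= 0
  if (all(deg)) {
    stop("degenerate calibration: zero score variance at every size",
         call. = FALSE)
  }
  if (any(deg)) {
    warning(sprintf("calibration degenerate at k = %s; excluded from search",
                    paste(out$k[deg], collapse = ", ")), call. = FALSE)
    out$mu[deg] <- NA_real_
    out$sigma[deg] <- NA_real_
  }
  structure(out, class = c("sa_calibration", "data.frame"),
            mc_samples = as.integer(mc_samples), seed = as.integer(seed))
}

# mu/sigma lookup vectors indexed by k (NA outside the calibrated range).
calibration_vectors <- function(calibration) {
  stopifnot(inherits(calibration, "sa_calibration"))
  kmax <- max(calibration$k)
  mu <- rep(NA_real_, kmax)
  sigma <- rep(NA_real_, kmax)
  mu[calibration$k] <- calibration$mu
  sigma[calibration$k] <- calibration$sigma
  list(mu = mu, sigma = sigma, kmax = kmax)
}

#' Score a connected gene set against its size-matched background
#'
#' @param genes character vector of gene symbols, connected in `network`.
#' @param score_map a [make_gene_scores] object.
#' @param calibration an [calibrate_scores] table covering `length(genes)`.
#' @param network igraph network.
#' @return object of class `subnetwork`: list with `genes`, `k`, `z_A`
#'   (aggregate score) and `s_A` (calibrated score).
#' @export
score_subnetwork <- function(genes, score_map, calibration, network) {
  stopifnot(inherits(score_map, "gene_scores"))
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("empty gene set", call. = FALSE)
  if (!all(genes %in% igraph::V(network)$name)) {
    stop("gene(s) not in network: ",
         paste(setdiff(genes, igraph::V(network)$name), collapse = ", "),
         call. = FALSE)
  }
  sub <- igraph::induced_subgraph(network, genes)
  if (!igraph::is_connected(sub)) {
    stop("gene set does not induce a connected subgraph", call. = FALSE)
  }
  k <- length(genes)
  cv <- calibration_vectors(calibration)
  if (k > cv$kmax || !is.finite(cv$sigma[k])) {
    stop("size ", k, " is outside the calibrated range", call. = FALSE)
  }
  z_A <- aggregate_z(score_map$z[genes])
  structure(list(genes = genes, k = k, z_A = z_A,
                 s_A = (z_A - cv$mu[k]) / cv$sigma[k]),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> k = %d, z_A = %.3f, s_A = %.3f\n", x$k, x$z_A,
              x$s_A))
  cat(" genes:", paste(sort(x$genes), collapse = ", "), "\n")
  invisible(x)
}

#' Simulated-annealing search parameters
#'
#' @param n_modules number of modules [find_subnetworks()] attempts to
#'   extract (>= 1).
#' @param max_overlap maximum allowed pairwise [overlap_fraction()] between
#'   reported modules, in `[0, 1)`. Default 0.5 — "at most 50% overlap".
#' @param sa_iterations annealing iterations per restart.
#' @param t_start,t_end geometric cooling schedule endpoints
#'   (`t_start > t_end > 0`).
#' @param restarts independent annealing restarts per module search.
#' @param seed integer master seed; all restart seeds derive from it.
#' @return a list of class `search_params`.
#' @export
search_params <- function(n_modules = 10, max_overlap = 0.5,
                          sa_iterations = 10000, t_start = 1, t_end = 1e-3,
                          restarts = 5, seed = 1) {
  if (n_modules < 1) stop("n_modules must be >= 1", call. = FALSE)
  if (max_overlap < 0 || max_overlap >= 1) {
    stop("max_overlap must be in [0, 1)", call. = FALSE)
  }
  if (!(t_start > t_end && t_end > 0)) {
    stop("need t_start > t_end > 0", call. = FALSE)
  }
  structure(list(n_modules = as.integer(n_modules), max_overlap = max_overlap,
                 sa_iterations = as.integer(sa_iterations),
                 t_start = t_start, t_end = t_end,
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "search_params")
}

#' Overlap fraction between two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`; the smaller-set denominator guards
#' against nested modules (a subset of a larger module overlaps it fully).
#'
#' @param genes_a,genes_b non-empty character vectors.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(genes_a, genes_b) {
  a <- unique(genes_a)
  b <- unique(genes_b)
  if (!length(a) || !length(b)) stop("empty gene set", call. = FALSE)
  length(intersect(a, b)) / min(length(a), length(b))
}

# Is the member set still connected after removing v? BFS over the induced
# subgraph, skipping v.
connected_without <- function(adj, members, inset, v) {
  k <- length(members)
  if (k <= 2L) return(TRUE)
  vis <- logical(length(adj))
  start <- if (members[1L] == v) members[2L] else members[1L]
  vis[start] <- TRUE
  stack <- start
  cnt <- 1L
  while (length(stack)) {
    x <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    nbs <- adj[[x]]
    new <- nbs[inset[nbs] & !vis[nbs] & nbs != v]
    if (length(new)) {
      vis[new] <- TRUE
      cnt <- cnt + length(new)
      stack <- c(stack, new)
    }
  }
  cnt == k - 1L
}

# One annealing run. Each restart starts from a random-size random
# connected set (random-walk grown), so restarts cover basins at different
# module sizes. Moves: add a uniformly chosen *boundary* gene (a non-member
# neighbour of the set — sampling the boundary directly keeps add-moves
# viable at every size), or remove a uniformly chosen member (rejected if
# it would disconnect the set). Metropolis acceptance exp(ds/T) under
# geometric cooling. Returns the best-seen member set (indices).
anneal_once <- function(adj, z, mu, sigma, kmax, iters, t_start, t_end, seed,
                        start = NULL) {
  n <- length(adj)
  score_of <- function(k, sumz) {
    if (k < 1L || k > kmax) return(-Inf)
    s <- sigma[k]
    if (!is.finite(s) || s <= 0) return(-Inf)
    (sumz / sqrt(k) - mu[k]) / s
  }
  with_seed(seed, {
    members <- if (!is.null(start)) {
      as.integer(start)
    } else {
      k0 <- sample.int(min(kmax, n), 1L)
      tryCatch(sample_connected_idx(adj, k0),
               error = function(e) sample.int(n, 1L))
    }
    inset <- logical(n)
    inset[members] <- TRUE
    k <- length(members)
    sumz <- sum(z[members])
    cur <- score_of(k, sumz)
    best_members <- members
    best_s <- cur
    cool <- (t_end / t_start)^(1 / max(iters - 1L, 1L))
    temp <- t_start
    for (it in seq_len(iters)) {
      # toggle move: draw uniformly from members + boundary, so the
      # proposal pressure towards growing or shrinking self-balances with
      # the current size
      boundary <- unique(unlist(adj[members]))
      boundary <- boundary[!inset[boundary]]
      pool_n <- k + length(boundary)
      j <- sample.int(pool_n, 1L)
      if (j > k) {
        u <- boundary[[j - k]]
        if (k < kmax) {
          new_s <- score_of(k + 1L, sumz + z[[u]])
          ds <- new_s - cur
          if (new_s > cur ||
              (is.finite(ds) && stats::runif(1) < exp(ds / temp))) {
            members <- c(members, u)
            inset[u] <- TRUE
            k <- k + 1L
            sumz <- sumz + z[[u]]
            cur <- new_s
            if (cur > best_s) {
              best_s <- cur
              best_members <- members
            }
          }
        }
      } else if (k > 1L) {
        v <- members[[j]]
        new_s <- score_of(k - 1L, sumz - z[[v]])
        ds <- new_s - cur
        if (new_s > cur ||
            (is.finite(ds) && stats::runif(1) < exp(ds / temp))) {
          if (connected_without(adj, members, inset, v)) {
            members <- members[-j]
            inset[v] <- FALSE
            k <- k - 1L
            sumz <- sumz - z[[v]]
            cur <- new_s
            if (cur > best_s) {
              best_s <- cur
              best_members <- members
            }
          }
        }
      }
      temp <- temp * cool
    }
    if (!is.finite(best_s)) {
      # no scorable state ever visited: fall back to the best single gene
      best_members <- which.max(z)
    }
    greedy_polish(adj, z, mu, sigma, kmax, best_members)
  })
}

# Deterministic first-class hill climb: repeatedly take the best improving
# add / remove / swap until the set is locally optimal. Keeps annealing
# output stable at a local optimum without extra stochastic iterations.
greedy_polish <- function(adj, z, mu, sigma, kmax, members) {
  score_of <- function(k, sumz) {
    if (k < 1L || k > kmax) return(-Inf)
    s <- sigma[k]
    if (!is.finite(s) || s <= 0) return(-Inf)
    (sumz / sqrt(k) - mu[k]) / s
  }
  n <- length(adj)
  repeat {
    k <- length(members)
    sumz <- sum(z[members])
    cur <- score_of(k, sumz)
    inset <- logical(n)
    inset[members] <- TRUE
    best_gain <- 0
    best_next <- NULL
    boundary <- unique(unlist(adj[members]))
    boundary <- boundary[!inset[boundary]]
    for (u in boundary) {
      s_add <- score_of(k + 1L, sumz + z[[u]])
      if (s_add - cur > best_gain) {
        best_gain <- s_add - cur
        best_next <- c(members, u)
      }
    }
    if (k > 1L) {
      for (i in seq_len(k)) {
        v <- members[[i]]
        if (!connected_without(adj, members, inset, v)) next
        rest <- members[-i]
        s_rem <- score_of(k - 1L, sumz - z[[v]])
        if (s_rem - cur > best_gain) {
          best_gain <- s_rem - cur
          best_next <- rest
        }
        cand <- unique(unlist(adj[rest]))
        cand <- cand[!inset[cand]]
        for (u in cand) {
          s_swap <- score_of(k, sumz - z[[v]] + z[[u]])
          if (s_swap - cur > best_gain) {
            best_gain <- s_swap - cur
            best_next <- c(rest, u)
          }
        }
      }
    }
    if (is.null(best_next) || best_gain <= 1e-12) break
    members <- best_next
  }
  members
}

#' Search for one high-scoring active subnetwork by simulated annealing
#'
#' Runs `params$restarts` independent annealing restarts (seeds derived from
#' `params$seed`) and returns the best-scoring connected module seen.
#' Deterministic given the seed; never errors on a valid scored network (in
#' the degenerate case it returns the best single gene).
#'
#' @param network igraph PPI network.
#' @param score_map a [make_gene_scores] object.
#' @param calibration a [calibrate_scores] table.
#' @param params a [search_params] object.
#' @return a `subnetwork` object.
#' @export
anneal_search <- function(network, score_map, calibration,
                          params = search_params()) {
  cands <- anneal_candidates(network, score_map, calibration, params,
                             n_runs = params$restarts)
  cands[[which.max(vapply(cands, `[[`, numeric(1), "s_A"))]]
}

# Run n_runs single anneals with derived seeds; return scored subnetworks.
anneal_candidates <- function(network, score_map, calibration, params,
                              n_runs) {
  validate_network(network)
  stopifnot(inherits(score_map, "gene_scores"),
            inherits(params, "search_params"))
  genes <- igraph::V(network)$name
  z <- unname(score_map$z[genes])
  adj <- adj_index_list(network)
  cv <- calibration_vectors(calibration)
  seeds <- derive_seeds(params$seed, n_runs)
  # odd runs are seeded at the top-z genes in rank order (the most
  # significant genes are the natural nuclei of active modules), even runs
  # at random connected sets for basin diversity
  hot <- order(z, decreasing = TRUE)
  lapply(seq_len(n_runs), function(i) {
    start <- if (i %% 2L == 1L) hot[[(i + 1L) %/% 2L]] else NULL
    idx <- anneal_once(adj, z, cv$mu, cv$sigma, cv$kmax,
                       params$sa_iterations, params$t_start, params$t_end,
                       seeds[i], start = start)
    score_subnetwork(genes[idx], score_map, calibration, network)
  })
}

#' Extract multiple active subnetworks with limited pairwise overlap
#'
#' Runs `n_modules * restarts` independent annealing searches, ranks all
#' candidate modules by decreasing calibrated score, and keeps a candidate
#' only if its [overlap_fraction()] with every already-kept module is at
#' most `max_overlap` ("subnetworks that overlap at most 50% with each
#' other"). At most `n_modules` modules are returned; fewer when the
#' landscape yields fewer sufficiently distinct optima.
#'
#' @inheritParams anneal_search
#' @return list of `subnetwork` objects sorted by decreasing `s_A`; all
#'   pairs satisfy the overlap constraint.
#' @export
find_subnetworks <- function(network, score_map, calibration,
                             params = search_params()) {
  cands <- anneal_candidates(network, score_map, calibration, params,
                             n_runs = params$n_modules * params$restarts)
  # drop duplicate gene sets
  keys <- vapply(cands, function(m) paste(sort(m$genes), collapse = "|"),
                 character(1))
  cands <- cands[!duplicated(keys)]
  ord <- order(vapply(cands, `[[`, numeric(1), "s_A"), decreasing = TRUE)
  cands <- cands[ord]
  kept <- list()
  for (m in cands) {
    if (length(kept) >= params$n_modules) break
    ok <- all(vapply(kept, function(km) {
      overlap_fraction(m$genes, km$genes) <= params$max_overlap
    }, logical(1)))
    if (ok) kept[[length(kept) + 1L]] <- m
  }
  kept
}
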