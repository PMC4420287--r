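# Ground-truth study generator. Emulates the design of a 2D-gel CSF
# proteomics cohort study: a scale-free PPI network stand-in, a collection
# of pathway-sized gene sets with one designated pathway harbouring a
# connected planted module, and log-normal spot intensities with
# group-specific >= 2-fold planted effects, ~24% intra-group CV and 2%
# missing cells. All randomness flows from a single master seed.

#' Generate a synthetic PPI network
#'
#' Models: `"configuration-powerlaw"` (default) draws a static power-law
#' fitness graph (degree exponent 2.2, the value typically reported for human PPI networks) with exactly `n_genes * mean_degree
#' / 2` edges before simplification; `"duplication-divergence"` grows the
#' network by node duplication with 50% edge retention plus an anchor edge,
#' then tops up / trims random edges toward the requested mean degree. In
#' both cases the largest connected component is kept and nodes are
#' relabelled `G0001, G0002, ...`.
#'
#' @param n_genes number of genes before component extraction (>= 50).
#' @param mean_degree target mean degree.
#' @param model generator model.
#' @param seed integer seed; the edge list is deterministic given it.
#' @return an undirected simple connected igraph network.
#' @export
generate_network <- function(n_genes, mean_degree = 4,
                             model = c("configuration-powerlaw",
                                       "duplication-divergence"),
                             seed = 1) {
  model <- match.arg(model)
  if (n_genes < 50) stop("n_genes must be >= 50", call. = FALSE)
  m_target <- round(n_genes * mean_degree / 2)
  if (m_target < n_genes - 1) {
    stop("unreachable parameters: mean_degree too small for a connected graph",
         call. = FALSE)
  }
  g <- with_seed(seed, {
    if (model == "configuration-powerlaw") {
      gg <- igraph::sample_fitness_pl(n_genes, m_target, exponent.out = 2.2)
      igraph::simplify(gg)
    } else {
      gg <- igraph::make_full_graph(4)
      while (igraph::vcount(gg) < n_genes) {
        src <- sample.int(igraph::vcount(gg), 1L)
        nbs <- as.integer(igraph::neighbors(gg, src))
        keep <- nbs[stats::runif(length(nbs)) < 0.5]
        new <- igraph::vcount(gg) + 1L
        gg <- igraph::add_vertices(gg, 1L)
        gg <- igraph::add_edges(gg, as.vector(rbind(new, unique(c(keep, src)))))
      }
      gg <- igraph::simplify(gg)
      m_cur <- igraph::ecount(gg)
      if (m_cur < m_target) {
        # top up with uniformly random non-edges
        need <- m_target - m_cur
        while (need > 0L) {
          u <- sample.int(igraph::vcount(gg), 1L)
          v <- sample.int(igraph::vcount(gg), 1L)
          if (u != v && !igraph::are_adjacent(gg, u, v)) {
            gg <- igraph::add_edges(gg, c(u, v))
            need <- need - 1L
          }
        }
      } else if (m_cur > m_target) {
        # trim non-bridge edges so the component survives
        for (i in seq_len(m_cur - m_target)) {
          br <- igraph::bridges(gg)
          cand <- setdiff(seq_len(igraph::ecount(gg)), as.integer(br))
          if (!length(cand)) break
          gg <- igraph::delete_edges(gg, cand[[sample.int(length(cand), 1L)]])
        }
      }
      gg
    }
  })
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership ==
                                           which.max(comp$csize)))
  igraph::V(g)$name <- sprintf("G%04d", seq_len(igraph::vcount(g)))
  validate_network(g)
  g
}

#' Generate a synthetic pathway collection over a network
#'
#' Samples `n_sets` gene sets from the network genes with sizes uniform in
#' `size_range` (the scale of curated pathway databases, ~15-80 genes). A
#' fraction of each set's genes is drawn from a common "popular gene" pool
#' so sets overlap, as real pathways do. The first set (`PW0001`) is the
#' designated pathway: it is built around a randomly grown *connected* seed
#' region of `designated_core` genes, so a connected planted module can
#' live entirely inside it.
#'
#' @param network igraph network.
#' @param n_sets number of gene sets.
#' @param size_range integer range of set sizes.
#' @param overlap_rate expected fraction of a set drawn from the shared
#'   popular-gene pool.
#' @param seed integer seed.
#' @param designated_core size of the connected core of the designated set.
#' @return a [gene_sets] collection with attributes `designated` (set ID)
#'   and `designated_core` (the connected core genes).
#' @export
generate_genesets <- function(network, n_sets = 50, size_range = c(15, 80),
                              overlap_rate = 0.2, seed = 1,
                              designated_core = 12) {
  validate_network(network)
  genes <- igraph::V(network)$name
  n <- length(genes)
  if (max(size_range) > n) stop("set sizes exceed network size", call. = FALSE)
  if (designated_core > min(size_range)) {
    stop("designated_core exceeds the minimum set size", call. = FALSE)
  }
  with_seed(seed, {
    popular <- sample(genes, max(10L, round(0.1 * n)))
    size_choices <- seq.int(size_range[1], size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), n_sets,
                                     replace = TRUE)]
    core <- sample_connected_set(network, designated_core)
    sets <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      sz <- sizes[i]
      n_pop <- stats::rbinom(1L, sz, overlap_rate)
      draw <- c(sample(popular, min(n_pop, length(popular))),
                sample(setdiff(genes, popular), sz - min(n_pop, length(popular))))
      if (i == 1L) {
        draw <- c(core, sample(setdiff(genes, core), sz - length(core)))
      }
      sets[[i]] <- unique(draw)
    }
    ids <- sprintf("PW%04d", seq_len(n_sets))
    names(sets) <- ids
    desc <- stats::setNames(
      c("designated synthetic pathway",
        rep("synthetic pathway", n_sets - 1L)), ids)
    structure(gene_sets(sets, desc), designated = ids[1L],
              designated_core = core)
  })
}

#' Generate a synthetic intensity study with planted ground truth
#'
#' Spot intensities are log-normal: protein baselines span several orders of
#' magnitude and the within-group noise sdlog is chosen from the target CV
#' via `sigma^2 = log(1 + CV^2)`, so the intra-group CV is directly
#' controlled. Planted genes carry a multiplicative fold effect (magnitude
#' uniform in `fold_range`, direction up or down per gene) in every
#' non-control group. Cells go missing completely at random at
#' `missing_rate`, with a floor of 3 retained observations per group so
#' every protein stays testable. Proteins map 1:1 onto network genes.
#'
#' @param design named integer vector of group sizes. The default
#'   `c(CIS = 12, RRMS = 14, PMS = 8, CONTROL = 8)` is a scaled-down analog
#'   of a 65/72/42/42 cohort for fast tests; pass the full-scale design
#'   where runtime allows.
#' @param truth list of generator parameters: `network` (igraph, required),
#'   `planted_genes` (character; default none), `fold_range` (default
#'   `c(2, 4.2)`), `target_cv` (percent, default 24), `missing_rate`
#'   (default 0.02), `control_group` (default `"CONTROL"`),
#'   `designated_pathway` (set ID recorded in the truth manifest).
#' @param seed integer master seed.
#' @return list with elements `study` ([intensity_study]), `map`
#'   ([protein_gene_map]) and `truth` (class `synthetic_truth`: planted
#'   genes, designated pathway, planted folds, design, target CV, seed).
#' @export
generate_study <- function(design = c(CIS = 12, RRMS = 14, PMS = 8,
                                      CONTROL = 8),
                           truth = list(), seed = 1) {
  network <- truth$network
  if (is.null(network)) stop("truth$network is required", call. = FALSE)
  validate_network(network)
  if (any(design < 4)) stop("each group needs >= 4 samples", call. = FALSE)
  design <- stats::setNames(as.integer(design), names(design))
  target_cv <- truth$target_cv %||% 24
  if (target_cv <= 0) stop("infeasible CV target", call. = FALSE)
  fold_range <- truth$fold_range %||% c(2, 4.2)
  if (any(fold_range < 2)) {
    stop("planted folds must be >= 2 (or the filter cannot see them)",
         call. = FALSE)
  }
  missing_rate <- truth$missing_rate %||% 0.02
  control_group <- truth$control_group %||% "CONTROL"
  planted <- unique(as.character(truth$planted_genes %||% character(0)))
  genes <- igraph::V(network)$name
  if (!all(planted %in% genes)) {
    stop("planted genes must be network genes", call. = FALSE)
  }

  n_prot <- length(genes)
  proteins <- sprintf("P%04d", seq_len(n_prot))
  map <- protein_gene_map(proteins, genes)
  groups <- rep(names(design), design)
  samples <- sprintf("%s_%02d", groups, unlist(lapply(design, seq_len)))
  sdlog <- sqrt(log(1 + (target_cv / 100)^2))

  out <- with_seed(seed, {
    folds <- if (length(planted)) {
      magnitude <- stats::runif(length(planted), fold_range[1], fold_range[2])
      up <- sample(c(TRUE, FALSE), length(planted), replace = TRUE)
      stats::setNames(ifelse(up, magnitude, 1 / magnitude), planted)
    } else stats::setNames(numeric(0), character(0))
    baseline <- stats::rlnorm(n_prot, meanlog = log(5e3), sdlog = 0.8)
    effect <- matrix(1, n_prot, length(samples),
                     dimnames = list(proteins, samples))
    case_cols <- groups != control_group
    if (length(planted)) {
      effect[match(planted, genes), case_cols] <- folds[planted]
    }
    noise <- matrix(stats::rlnorm(n_prot * length(samples),
                                  meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    n_prot, length(samples))
    m <- baseline * effect * noise
    dimnames(m) <- list(proteins, samples)
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(m)) < missing_rate, n_prot,
                     length(samples))
      # keep >= 3 observed values per protein per group
      for (g in unique(groups)) {
        cols <- which(groups == g)
        excess <- rowSums(mask[, cols, drop = FALSE])
        bad <- which(length(cols) - excess < 3L)
        for (i in bad) mask[i, cols] <- FALSE
      }
      m[mask] <- NA_real_
    }
    list(m = m, folds = folds)
  })

  study <- intensity_study(out$m, stats::setNames(groups, samples))
  truth_obj <- structure(
    list(planted_genes = planted,
         designated_pathway = truth$designated_pathway %||% NA_character_,
         planted_folds = out$folds,
         design = design, target_cv = target_cv, seed = as.integer(seed)),
    class = "synthetic_truth")
  list(study = study, map = map, truth = truth_obj)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d planted gene(s), designated pathway %s, seed %d\n",
              length(x$planted_genes), x$designated_pathway, x$seed))
  invisible(x)
}

#' Write / read a truth manifest TSV
#'
#' The manifest round-trips exactly: `read_truth(write_truth(x)) == x` for
#' the planted-gene table and scalar fields.
#'
#' @param truth a `synthetic_truth` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  head <- c(sprintf("#designated_pathway\t%s", truth$designated_pathway),
            sprintf("#target_cv\t%.15g", truth$target_cv),
            sprintf("#seed\t%d", truth$seed),
            sprintf("#design\t%s",
                    paste(sprintf("%s=%d", names(truth$design), truth$design),
                          collapse = ",")),
            "gene\tfold")
  g <- sort(truth$planted_genes, method = "radix")
  write_lines_utf8(c(head, sprintf("%s\t%.15g", g, truth$planted_folds[g])),
                   path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", meta), "\t", fixed = TRUE)
  meta_map <- stats::setNames(vapply(kv, `[[`, character(1), 2L),
                              vapply(kv, `[[`, character(1), 1L))
  body <- body[-1L]  # header
  parts <- strsplit(body, "\t", fixed = TRUE)
  genes <- vapply(parts, `[[`, character(1), 1L)
  folds <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  des <- strsplit(strsplit(meta_map[["design"]], ",", fixed = TRUE)[[1L]],
                  "=", fixed = TRUE)
  design <- stats::setNames(as.integer(vapply(des, `[[`, character(1), 2L)),
                            vapply(des, `[[`, character(1), 1L))
  structure(list(planted_genes = genes,
                 designated_pathway = meta_map[["designated_pathway"]],
                 planted_folds = stats::setNames(folds, genes),
                 design = design,
                 target_cv = as.numeric(meta_map[["target_cv"]]),
                 seed = as.integer(meta_map[["seed"]])),
            class = "synthetic_truth")
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper producing every pipeline input with planted ground
#' truth: a network, a pathway collection with a designated pathway, and an
#' intensity study whose planted module is the designated pathway's
#' connected core. With `planted_size = 0` the study is a global null (no
#' effect anywhere).
#'
#' @param seed master seed; all component seeds derive from it.
#' @param n_genes,mean_degree,model passed to [generate_network()].
#' @param n_sets,size_range,overlap_rate passed to [generate_genesets()].
#' @param planted_size number of planted genes (taken from the designated
#'   pathway's connected core; at most the core size).
#' @param fold_range,target_cv,missing_rate,design passed to
#'   [generate_study()].
#' @return list with `network`, `genesets`, `study`, `map`, `truth`.
#' @export
simulate_experiment <- function(seed = 1, n_genes = 400, mean_degree = 4,
                                model = "configuration-powerlaw",
                                n_sets = 50, size_range = c(15, 80),
                                overlap_rate = 0.2, planted_size = 12,
                                fold_range = c(2, 4.2), target_cv = 24,
                                missing_rate = 0.02,
                                design = c(CIS = 12, RRMS = 14, PMS = 8,
                                           CONTROL = 8)) {
  seeds <- derive_seeds(seed, 3L)
  network <- generate_network(n_genes, mean_degree, model, seed = seeds[1])
  core_size <- max(1L, min(max(planted_size, 12L), size_range[1]))
  genesets <- generate_genesets(network, n_sets, size_range, overlap_rate,
                                seed = seeds[2], designated_core = core_size)
  core <- attr(genesets, "designated_core")
  planted <- if (planted_size > 0) core[seq_len(min(planted_size, length(core)))]
  else character(0)
  gs <- generate_study(design,
                       truth = list(network = network,
                                    planted_genes = planted,
                                    fold_range = fold_range,
                                    target_cv = target_cv,
                                    missing_rate = missing_rate,
                                    designated_pathway = attr(genesets,
                                                              "designated")),
                       seed = seeds[3])
  list(network = network, genesets = genesets, study = gs$study,
       map = gs$map, truth = gs$truth)
}
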