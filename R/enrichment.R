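# Pathway enrichment of identified subnetworks: an exact two-sided
# (enrichment/depletion) hypergeometric test per pathway, Bonferroni
# correction over the pathways tested within each subnetwork, and
# aggregation across subnetworks into a per-pathway report (best corrected
# p, "times found", pathway genes found/not found in subnetworks).

#' Two-sided hypergeometric p-value (enrichment/depletion)
#'
#' Exact minimum-likelihood two-sided test (the Fisher-exact convention):
#' the p-value is the sum of hypergeometric probabilities of all overlap
#' counts whose probability does not exceed that of the observed count `x`,
#' for `n` draws from a universe of `N` genes of which `K` belong to the
#' pathway.
#'
#' @param x observed overlap count.
#' @param N universe size.
#' @param K pathway size within the universe.
#' @param n subnetwork size within the universe.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' two_sided_hypergeom(5, 10, 5, 5)  # 2/252
two_sided_hypergeom <- function(x, N, K, n) {
  if (any(c(x, N, K, n) < 0) || K > N || n > N ||
      x > min(K, n) || x < max(0, K + n - N)) {
    stop(sprintf("infeasible hypergeometric configuration (x=%d, N=%d, K=%d, n=%d)",
                 x, N, K, n), call. = FALSE)
  }
  support <- max(0, K + n - N):min(K, n)
  pmf <- stats::dhyper(support, K, N - K, n)
  px <- stats::dhyper(x, K, N - K, n)
  # relative tolerance guards ties computed in floating point
  min(1, sum(pmf[pmf <= px * (1 + 1e-7)]))
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests (the length of the input)
#' and caps at 1; order preserved.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return corrected p-values.
#' @export
bonferroni <- function(p_values) {
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  pmin(1, length(p_values) * p_values)
}

#' Default enrichment universe
#'
#' Network genes annotated to at least one pathway of the collection — the
#' default background the hypergeometric test draws from. (Configurable to
#' all network genes via `enrich_subnetwork(universe = ...)`; the universe
#' definition is recorded in run manifests because p-values depend on it.)
#'
#' @param network igraph PPI network.
#' @param collection a [gene_sets] collection.
#' @return character vector of universe genes.
#' @export
default_universe <- function(network, collection) {
  intersect(igraph::V(network)$name,
            unique(unlist(unclass(collection), use.names = FALSE)))
}

#' Hypergeometric enrichment of one subnetwork against a pathway collection
#'
#' For each pathway with at least one universe gene, counts the subnetwork
#' genes also annotated to the pathway and computes the two-sided
#' hypergeometric p-value; Bonferroni correction is applied over the `m`
#' pathways tested for this subnetwork. Pathways whose overlap falls below
#' its expectation are flagged `direction = "depletion"`.
#'
#' @param subnetwork a `subnetwork` object (or character vector of genes).
#' @param collection a [gene_sets] collection.
#' @param universe character vector of universe genes; pathways and the
#'   subnetwork are intersected with it.
#' @param subnetwork_id identifier stored in the result rows.
#' @return data.frame with one row per tested pathway: `pathway_id,
#'   subnetwork_id, x, K, n, N, p_raw, p_corr, m, direction`.
#' @export
enrich_subnetwork <- function(subnetwork, collection, universe,
                              subnetwork_id = "S1") {
  genes <- if (inherits(subnetwork, "subnetwork")) subnetwork$genes else
    as.character(subnetwork)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  sub_u <- intersect(genes, universe)
  if (!length(sub_u)) {
    stop("subnetwork has no genes in the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(sub_u)
  Ks <- vapply(unclass(collection), function(g) length(intersect(g, universe)),
               integer(1))
  tested <- names(Ks)[Ks >= 1L]
  m <- length(tested)
  if (!m) stop("no pathway intersects the universe", call. = FALSE)
  xs <- vapply(tested, function(id) {
    length(intersect(collection[[id]], sub_u))
  }, integer(1))
  p_raw <- vapply(seq_len(m), function(i) {
    two_sided_hypergeom(xs[i], N, Ks[tested[i]], n)
  }, numeric(1))
  data.frame(pathway_id = tested, subnetwork_id = subnetwork_id,
             x = unname(xs), K = unname(Ks[tested]), n = n, N = N,
             p_raw = p_raw, p_corr = pmin(1, m * p_raw), m = m,
             direction = ifelse(xs >= n * Ks[tested] / N, "enrichment",
                                "depletion"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate per-subnetwork enrichment results into a pathway report
#'
#' Per pathway: the best (minimum) Bonferroni-corrected p across
#' subnetworks ("if a pathway appears in more than one subnetwork analysis
#' only the most significant one is reported"), `times_found` = the number
#' of subnetworks in which the pathway is significantly enriched
#' (`p_corr < threshold`), and the pathway genes found in (the union of)
#' those significant subnetworks versus the remaining pathway genes. Only
#' pathways found at least once are reported; depletion-significant
#' pathways are excluded by default.
#'
#' @param all_results data.frame: row-bound [enrich_subnetwork()] outputs
#'   over all subnetworks.
#' @param subnetworks list of `subnetwork` objects (or gene vectors) named /
#'   ordered consistently with `subnetwork_id` in `all_results`.
#' @param collection the [gene_sets] collection.
#' @param threshold significance threshold on corrected p (default 0.05).
#' @param include_depleted also report depletion-significant pathways?
#' @return data.frame with columns `pathway_id, name, best_p_corr,
#'   times_found, genes_found, genes_not_found` (gene lists comma-joined,
#'   sorted), ordered by increasing `best_p_corr`.
#' @export
aggregate_pathways <- function(all_results, subnetworks, collection,
                               threshold = 0.05, include_depleted = FALSE) {
  stopifnot(is.data.frame(all_results), nrow(all_results) >= 1L)
  sub_genes <- lapply(subnetworks, function(s) {
    if (inherits(s, "subnetwork")) s$genes else as.character(s)
  })
  if (is.null(names(sub_genes)) || any(!nzchar(names(sub_genes)))) {
    names(sub_genes) <- unique(all_results$subnetwork_id)[seq_along(sub_genes)]
  }
  desc <- attr(collection, "descriptions")
  rows <- lapply(split(all_results, all_results$pathway_id), function(r) {
    sig <- r$p_corr < threshold &
      (include_depleted | r$direction == "enrichment")
    if (!any(sig)) return(NULL)
    found_in <- r$subnetwork_id[sig]
    union_genes <- unique(unlist(sub_genes[found_in], use.names = FALSE))
    pw <- collection[[r$pathway_id[1L]]]
    gf <- sort(intersect(pw, union_genes), method = "radix")
    data.frame(pathway_id = r$pathway_id[1L],
               name = desc[[r$pathway_id[1L]]] %||% r$pathway_id[1L],
               best_p_corr = min(r$p_corr),
               times_found = sum(sig),
               genes_found = paste(gf, collapse = ","),
               genes_not_found = paste(sort(setdiff(pw, gf), method = "radix"),
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(pathway_id = character(0), name = character(0),
                      best_p_corr = numeric(0), times_found = integer(0),
                      genes_found = character(0),
                      genes_not_found = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$best_p_corr, out$pathway_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}
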