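# Core S3 containers: intensity studies, gene-set collections, PPI networks,
# protein->gene maps. Networks are plain undirected simple igraph objects
# with a `name` vertex attribute; everything else is a light S3 wrapper.

#' Construct an intensity study
#'
#' Bundles a protein x sample intensity matrix (relative integrated optical
#' densities or any non-negative abundance measure, arbitrary units) with a
#' sample-to-group assignment. Missing cells (`NA`) are first-class: a spot
#' absent on one gel is missing, not zero.
#'
#' @param intensities numeric matrix, rows = proteins (rownames = protein
#'   IDs), columns = samples (colnames = sample IDs). Non-negative; `NA`
#'   allowed.
#' @param groups named character vector mapping every sample ID to a group
#'   label (e.g. `"CIS"`, `"RRMS"`, `"PMS"`, `"CONTROL"`).
#' @return an object of class `intensity_study`: a list with elements
#'   `intensities` and `groups`.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 40), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' intensity_study(m, c(s1 = "CASE", s2 = "CONTROL"))
intensity_study <- function(intensities, groups) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  pid <- rownames(intensities)
  sid <- colnames(intensities)
  if (is.null(pid) || is.null(sid)) {
    stop("`intensities` must have row (protein) and column (sample) names",
         call. = FALSE)
  }
  if (anyDuplicated(pid)) {
    stop("duplicate protein IDs: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample IDs: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  groups <- unlist(groups)
  missing_grp <- setdiff(sid, names(groups))
  if (length(missing_grp)) {
    stop("samples without a group assignment: ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  }
  groups <- as.character(groups[sid])
  names(groups) <- sid
  if (anyNA(groups) || any(!nzchar(groups))) {
    stop("empty group labels are not allowed", call. = FALSE)
  }
  if (length(unique(groups)) < 2L) {
    stop("at least two distinct groups are required", call. = FALSE)
  }
  structure(list(intensities = intensities, groups = groups),
            class = "intensity_study")
}

#' @export
print.intensity_study <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("<intensity_study> %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x$intensities), ncol(x$intensities),
              100 * mean(is.na(x$intensities))))
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set ID -> gene symbols).
#'   Gene symbols are case-sensitive opaque strings; duplicates within a set
#'   are removed.
#' @param descriptions optional named character vector of set descriptions;
#'   defaults to the set IDs.
#' @return an object of class `gene_sets`: the named list of de-duplicated
#'   gene vectors with a `descriptions` attribute.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set IDs: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene sets: ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  descriptions <- as.character(descriptions[names(sets)])
  descriptions[is.na(descriptions)] <- names(sets)[is.na(descriptions)]
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets, sizes %d-%d (median %d)\n",
              length(x), min(lengths(x)), max(lengths(x)),
              as.integer(stats::median(lengths(x)))))
  invisible(x)
}

# Canonical form: sets ordered by ID, genes sorted within each set.
# write_gmt() emits this form, so write-then-read is the identity on it.

#' Canonicalize a gene-set collection
#'
#' Orders sets lexicographically by ID and sorts genes within each set, the
#' form the writers emit (so write-then-read is the identity).
#'
#' @param collection a [gene_sets] object.
#' @return a canonical `gene_sets` object.
#' @export
canonicalize_gene_sets <- function(collection) {
  stopifnot(inherits(collection, "gene_sets"))
  ord <- order(names(collection), method = "radix")
  sets <- lapply(unclass(collection)[ord], function(g) sort(g, method = "radix"))
  gene_sets(sets, attr(collection, "descriptions")[names(sets)])
}

#' Validate a PPI network object
#'
#' The package represents protein-protein interaction networks as undirected
#' simple [igraph][igraph::graph] objects with a `name` vertex attribute.
#' This checks the invariants (undirected, named, no self-loops, no
#' multi-edges).
#'
#' @param network an igraph object.
#' @return the network, invisibly, or an error.
#' @export
validate_network <- function(network) {
  if (!igraph::is_igraph(network)) stop("not an igraph object", call. = FALSE)
  if (igraph::is_directed(network)) stop("network must be undirected", call. = FALSE)
  if (is.null(igraph::V(network)$name)) {
    stop("network vertices must be named with gene symbols", call. = FALSE)
  }
  if (anyDuplicated(igraph::V(network)$name)) {
    stop("duplicate gene symbols among network nodes", call. = FALSE)
  }
  if (!igraph::is_simple(network)) {
    stop("network must be simple (no self-loops or duplicate edges)",
         call. = FALSE)
  }
  invisible(network)
}

#' Construct a protein-to-gene map
#'
#' @param proteins character vector of protein IDs.
#' @param genes character vector of gene symbols, same length.
#' @return named character vector (protein ID -> gene symbol) of class
#'   `protein_gene_map`.
#' @export
protein_gene_map <- function(proteins, genes) {
  proteins <- as.character(proteins)
  genes <- as.character(genes)
  if (length(proteins) != length(genes)) {
    stop("`proteins` and `genes` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(proteins)) {
    stop("duplicate protein IDs in map: ",
         paste(unique(proteins[duplicated(proteins)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop("empty gene symbols in map", call. = FALSE)
  }
  structure(stats::setNames(genes, proteins), class = "protein_gene_map")
}

#' Extract samples of one group as a sub-matrix
#'
#' @param study an [intensity_study].
#' @param group one or more group labels; their samples are pooled.
#' @return numeric matrix of the member samples' columns.
#' @export
group_matrix <- function(study, group) {
  stopifnot(inherits(study, "intensity_study"))
  keep <- study$groups %in% group
  if (!any(keep)) {
    stop("no samples in group(s): ", paste(group, collapse = ", "),
         call. = FALSE)
  }
  study$intensities[, keep, drop = FALSE]
}
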