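# Readers and writers for the plain-text formats the pipeline touches:
# intensity TSV + group TSV, GMT gene sets, SIF / edge-list networks,
# protein->gene maps, and the result tables. All writers emit UTF-8,
# Unix line endings, and lexicographically sorted records so outputs diff
# deterministically.

#' Read an intensity table and group assignment
#'
#' The intensity file is a TSV with a header row of sample IDs and a first
#' column of protein/spot IDs. Empty cells (or `NA`) are parsed as missing
#' values; downstream mean computations skip them. The groups file is a
#' two-column TSV `sample_id<TAB>group` (a header line `sample\tgroup` is
#' tolerated).
#'
#' @param path path to the intensity TSV.
#' @param groups_path path to the sample-to-group TSV.
#' @return an [intensity_study].
#' @export
read_intensity_table <- function(path, groups_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("intensity table needs >= 1 sample column", call. = FALSE)
  pid <- raw[[1L]]
  if (anyDuplicated(pid)) {
    stop("duplicate protein ID(s) in ", path, ": ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  }
  sid <- colnames(raw)[-1L]
  mat <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sid),
                dimnames = list(pid, sid))
  for (j in seq_along(sid)) {
    cell <- trimws(raw[[j + 1L]])
    empty <- !nzchar(cell) | cell %in% c("NA", "na", "NaN")
    val <- suppressWarnings(as.numeric(cell))
    bad <- is.na(val) & !empty
    if (any(bad)) {
      stop(sprintf("non-numeric cell in %s: row '%s', column '%s' (value '%s')",
                   path, pid[which(bad)[1L]], sid[j], cell[which(bad)[1L]]),
           call. = FALSE)
    }
    val[empty] <- NA_real_
    mat[, j] <- val
  }
  grp <- utils::read.delim(groups_path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(grp) < 2L) stop("groups file must have two columns", call. = FALSE)
  if (nrow(grp) && tolower(grp[1L, 1L]) %in% c("sample", "sample_id")) {
    grp <- grp[-1L, , drop = FALSE]
  }
  groups <- stats::setNames(grp[[2L]], grp[[1L]])
  ungrouped <- setdiff(sid, names(groups))
  if (length(ungrouped)) {
    stop("sample(s) without a group in ", groups_path, ": ",
         paste(ungrouped, collapse = ", "), call. = FALSE)
  }
  intensity_study(mat, groups)
}

#' Write an intensity study to TSV files
#'
#' @param study an [intensity_study].
#' @param path output intensity TSV (rows sorted by protein ID).
#' @param groups_path output group TSV (rows sorted by sample ID).
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(study, path, groups_path) {
  stopifnot(inherits(study, "intensity_study"))
  m <- study$intensities
  m <- m[order(rownames(m), method = "radix"), , drop = FALSE]
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  lines <- c(paste(c("protein", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
             }, character(1)))
  write_lines_utf8(lines, path)
  sid <- sort(names(study$groups), method = "radix")
  write_lines_utf8(paste(sid, study$groups[sid], sep = "\t"), groups_path)
  invisible(path)
}

#' Read a GMT gene-set file (Broad dialect)
#'
#' Each line is `set_id<TAB>description<TAB>gene<TAB>gene...`. Genes are
#' de-duplicated within a set.
#'
#' @param path path to the GMT file.
#' @return a [gene_sets] collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields in %s", short[1L], path),
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  gene_sets(stats::setNames(sets, ids), stats::setNames(desc, ids))
}

#' Write a gene-set collection as GMT
#'
#' Emits the canonical form (sets sorted by ID, genes sorted within set), so
#' `read_gmt(write_gmt(x))` reproduces `canonicalize_gene_sets(x)` exactly.
#'
#' @param collection a [gene_sets] collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  collection <- canonicalize_gene_sets(collection)
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(id) {
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t")
  }, character(1))
  write_lines_utf8(lines, path)
  invisible(path)
}

#' Read a PPI network from an edge list or SIF file
#'
#' Accepts a two-column TSV edge list (`geneA<TAB>geneB`) or three-column SIF
#' (`geneA relation geneB`, tab- or whitespace-delimited). The result is an
#' undirected simple graph: reversed duplicates are collapsed and self-loop
#' lines are skipped with a warning reporting how many were dropped.
#'
#' @param path path to the network file.
#' @return an undirected simple igraph network with named vertices.
#' @export
read_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty network file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) == 1L)) {
    # whitespace-delimited SIF dialect
    fields <- strsplit(lines, "[[:space:]]+")
  }
  n_fld <- lengths(fields)
  if (any(!n_fld %in% c(2L, 3L))) {
    stop(sprintf("network line %d does not have 2 or 3 fields in %s",
                 which(!n_fld %in% c(2L, 3L))[1L], path), call. = FALSE)
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) == 3L) f[[3L]] else f[[2L]]  # SIF: node relation node
  }, character(1))
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("skipped %d self-loop line(s) in %s", sum(loops), path),
            call. = FALSE)
    a <- a[!loops]
    b <- b[!loops]
  }
  if (!length(a)) stop("no valid edges in ", path, call. = FALSE)
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  validate_network(g)
  g
}

#' Write a PPI network as a two-column edge-list TSV
#'
#' Each edge is written once with endpoints in lexicographic order; edges are
#' sorted, so write-then-read is the identity on simple undirected graphs.
#'
#' @param network an igraph network with named vertices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  validate_network(network)
  el <- igraph::as_edgelist(network, names = TRUE)
  if (nrow(el)) {
    lo <- pmin(el[, 1L], el[, 2L])
    hi <- pmax(el[, 1L], el[, 2L])
    ord <- order(lo, hi, method = "radix")
    lines <- paste(lo[ord], hi[ord], sep = "\t")
  } else {
    lines <- character(0)
  }
  write_lines_utf8(lines, path)
  invisible(path)
}

#' Read a protein-to-gene mapping TSV
#'
#' Two columns `protein_id<TAB>gene_symbol`; a header line starting with
#' `protein` is tolerated.
#'
#' @param path path to the map TSV.
#' @return a [protein_gene_map].
#' @export
read_protein_gene_map <- function(path) {
  d <- utils::read.delim(path, header = FALSE, sep = "\t",
                         colClasses = "character", quote = "",
                         comment.char = "")
  if (ncol(d) < 2L) stop("protein-gene map must have two columns", call. = FALSE)
  if (nrow(d) && tolower(d[1L, 1L]) %in% c("protein", "protein_id")) {
    d <- d[-1L, , drop = FALSE]
  }
  protein_gene_map(d[[1L]], d[[2L]])
}

#' Write a protein-to-gene mapping TSV
#'
#' @param map a [protein_gene_map].
#' @param path output path (rows sorted by protein ID).
#' @return `path`, invisibly.
#' @export
write_protein_gene_map <- function(map, path) {
  p <- sort(names(map), method = "radix")
  write_lines_utf8(paste(p, unclass(map)[p], sep = "\t"), path)
  invisible(path)
}

# ---- result tables -------------------------------------------------------

#' Write a gene-significance table
#'
#' Columns: gene, group, fold, p, selected — the interface between the
#' differential stage and the subnetwork stage.
#'
#' @param diff_table data.frame as returned by [group_differential()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_scores_tsv <- function(diff_table, path) {
  d <- diff_table[order(diff_table$gene, method = "radix"), , drop = FALSE]
  lines <- c("gene\tgroup\tfold\tp\tselected",
             sprintf("%s\t%s\t%.15g\t%.15g\t%s", d$gene, d$group, d$fold,
                     d$p, ifelse(d$selected, "TRUE", "FALSE")))
  write_lines_utf8(lines, path)
  invisible(path)
}

#' Write identified subnetwork modules as TSV
#'
#' Columns: module_id, k, z_A, s_A, genes (comma-joined, sorted).
#'
#' @param modules list of `subnetwork` objects ([find_subnetworks()] output).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modules_tsv <- function(modules, path) {
  lines <- c("module_id\tk\tz_A\ts_A\tgenes",
             vapply(seq_along(modules), function(i) {
               m <- modules[[i]]
               sprintf("M%03d\t%d\t%.15g\t%.15g\t%s", i, m$k, m$z_A, m$s_A,
                       paste(sort(m$genes, method = "radix"), collapse = ","))
             }, character(1)))
  write_lines_utf8(lines, path)
  invisible(path)
}

#' Write a pathway report as TSV
#'
#' Mirrors the report schema of pathway tables in differential-proteomics
#' studies: pathway ID and name, best Bonferroni-corrected p, times found,
#' pathway genes found in significant subnetworks, and the remaining pathway
#' genes.
#'
#' @param report data.frame from [aggregate_pathways()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_report <- function(report, path) {
  lines <- "pathway_id\tname\tbest_p_corr\ttimes_found\tgenes_found\tgenes_not_found"
  if (nrow(report)) {
    ord <- order(report$best_p_corr, report$pathway_id, method = "radix")
    r <- report[ord, , drop = FALSE]
    lines <- c(lines,
               sprintf("%s\t%s\t%.15g\t%d\t%s\t%s", r$pathway_id, r$name,
                       r$best_p_corr, r$times_found, r$genes_found,
                       r$genes_not_found))
  }
  write_lines_utf8(lines, path)
  invisible(path)
}
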