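# Label-shuffling specificity control: permute the sample -> group
# assignment, rerun the full differential -> subnetwork -> enrichment
# pipeline per shuffle, and tabulate how often each pathway recurs. A
# pathway that is genuinely tied to a group should appear in the unshuffled
# analysis but rarely across shuffled runs; generically reactive pathways
# recur regardless of the labels.

#' Shuffle sample-to-group labels
#'
#' Permutes the group labels uniformly at random while preserving the group
#' size multiset. With `scope = "all"` (default) labels are permuted across
#' every sample including controls, so case/control contrasts are fully
#' null; `scope = "ms-only"` permutes labels only among the non-control
#' (disease) samples, leaving the control group intact.
#'
#' @param groups named character vector (sample -> group).
#' @param seed integer seed; deterministic given it.
#' @param scope `"all"` or `"ms-only"`.
#' @param control_group control label(s) held fixed under `"ms-only"`.
#' @return a permuted named character vector with identical group sizes.
#' @export
shuffle_labels <- function(groups, seed, scope = c("all", "ms-only"),
                           control_group = "CONTROL") {
  scope <- match.arg(scope)
  if (length(unique(groups)) < 2L) stop("need >= 2 groups", call. = FALSE)
  out <- groups
  idx <- if (scope == "all") seq_along(groups) else
    which(!groups %in% control_group)
  out[idx] <- with_seed(seed, sample(groups[idx]))
  out
}

#' Label-shuffling randomization analysis
#'
#' Runs `R` independent shuffles of the group labels; for each shuffle the
#' full pipeline (differential statistics, subnetwork search, enrichment,
#' pathway report) is executed for every case group, and each pathway
#' present in a run's report (corrected p below `threshold`, found in at
#' least one subnetwork) counts as one occurrence. Per-run seeds derive
#' from the master seed and are stored in the result for replay. The
#' calibration table is computed once per run per group from the shuffled
#' scores.
#'
#' @param study an [intensity_study].
#' @param map a [protein_gene_map].
#' @param network igraph PPI network.
#' @param collection a [gene_sets] collection.
#' @param case_groups case group labels to analyse.
#' @param control_group control label(s), pooled.
#' @param fparams a [filter_params].
#' @param sparams a [search_params] (its seed is overridden per run).
#' @param threshold report-inclusion threshold on corrected p.
#' @param R number of shuffles (default 10).
#' @param seed master seed.
#' @param scope shuffle scope, see [shuffle_labels()].
#' @return object of class `randomization_summary`: data.frame with columns
#'   `pathway_id, group, count, R`, attributes `seeds` (per-run) and `R`.
#'   Pathways never observed are omitted (count 0).
#' @export
randomization_analysis <- function(study, map, network, collection,
                                   case_groups,
                                   control_group = "CONTROL",
                                   fparams = filter_params(),
                                   sparams = search_params(),
                                   threshold = 0.05, R = 10, seed = 1,
                                   scope = "all") {
  if (R < 1) stop("R must be >= 1", call. = FALSE)
  # interleaved (shuffle, search) pairs: the first R runs of a longer
  # randomization are exactly the runs of a shorter one (prefix property)
  run_seeds <- derive_seeds(seed, 2L * R)
  shuffle_seeds <- run_seeds[2L * seq_len(R) - 1L]
  search_seeds <- run_seeds[2L * seq_len(R)]
  counts <- list()
  for (r in seq_len(R)) {
    shuffled <- shuffle_labels(study$groups, shuffle_seeds[r], scope,
                               control_group)
    study_r <- intensity_study(study$intensities, shuffled)
    sp <- sparams
    sp$seed <- search_seeds[r]
    for (g in case_groups) {
      res <- tryCatch(
        run_group_analysis(study_r, map, network, collection, g,
                           control_group, fparams, sp, threshold),
        error = function(e) {
          stop(sprintf("randomization run %d, group %s: %s", r, g,
                       conditionMessage(e)), call. = FALSE)
        })
      for (pw in res$report$pathway_id) {
        key <- paste(pw, g, sep = "\r")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  if (length(counts)) {
    parts <- strsplit(names(counts), "\r", fixed = TRUE)
    out <- data.frame(pathway_id = vapply(parts, `[[`, character(1), 1L),
                      group = vapply(parts, `[[`, character(1), 2L),
                      count = as.integer(unlist(counts)), R = as.integer(R),
                      stringsAsFactors = FALSE)
    out <- out[order(out$group, -out$count, out$pathway_id, method = "radix"), ]
    rownames(out) <- NULL
  } else {
    out <- data.frame(pathway_id = character(0), group = character(0),
                      count = integer(0), R = integer(0),
                      stringsAsFactors = FALSE)
  }
  structure(out, class = c("randomization_summary", "data.frame"),
            seeds = data.frame(run = seq_len(R), shuffle_seed = shuffle_seeds,
                               search_seed = search_seeds), R = as.integer(R))
}

#' Write a randomization summary as TSV
#'
#' @param summary a `randomization_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_randomization_tsv <- function(summary, path) {
  lines <- "pathway_id\tgroup\tcount\tR"
  if (nrow(summary)) {
    s <- summary[order(summary$pathway_id, summary$group, method = "radix"), ]
    lines <- c(lines, sprintf("%s\t%s\t%d\t%d", s$pathway_id, s$group,
                              s$count, s$R))
  }
  write_lines_utf8(lines, path)
  invisible(path)
}
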