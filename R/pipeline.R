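# Pipeline composition: differential statistics -> gene scores -> calibrated
# subnetwork search -> per-subnetwork enrichment -> pathway report, per case
# group; plus the config-driven run_all() entry point that writes every
# result table and a reproducibility manifest.

#' Run the full analysis for one case group
#'
#' Chains the stages: [group_differential()] against the control group(s),
#' [make_gene_scores()], [calibrate_scores()] (unless a table is supplied),
#' [find_subnetworks()], [enrich_subnetwork()] per module, and
#' [aggregate_pathways()].
#'
#' @param study an [intensity_study].
#' @param map a [protein_gene_map].
#' @param network igraph PPI network.
#' @param collection a [gene_sets] pathway collection.
#' @param group case group label.
#' @param control_group control group label(s), pooled.
#' @param fparams a [filter_params].
#' @param sparams a [search_params]; its `seed` drives the search and (if
#'   needed) the calibration.
#' @param threshold significance threshold on corrected p for reporting.
#' @param calibration optional precomputed [calibrate_scores()] table (the
#'   calibration depends on the score map, so reuse only across runs with
#'   comparable score distributions, e.g. shuffles of one study).
#' @param mc_samples Monte-Carlo draws for calibration when computed here.
#' @param universe enrichment universe; default [default_universe()].
#' @return list with elements `differential` (gene table), `scores`,
#'   `calibration`, `modules` (list of subnetworks), `results` (all
#'   enrichment rows) and `report` (the aggregated pathway report).
#' @export
run_group_analysis <- function(study, map, network, collection, group,
                               control_group = "CONTROL",
                               fparams = filter_params(),
                               sparams = search_params(),
                               threshold = 0.05, calibration = NULL,
                               mc_samples = 200,
                               universe = default_universe(network, collection)) {
  diff_tab <- group_differential(study, map, group, control_group, fparams)
  scores <- make_gene_scores(stats::setNames(diff_tab$p, diff_tab$gene),
                             network)
  if (is.null(calibration)) {
    kmax <- min(20L, igraph::vcount(network) - 1L)
    calibration <- calibrate_scores(scores, network, k_range = seq_len(kmax),
                                    mc_samples = max(mc_samples, 100),
                                    seed = sparams$seed)
  }
  modules <- find_subnetworks(network, scores, calibration, sparams)
  ids <- sprintf("S%03d", seq_along(modules))
  results <- do.call(rbind, lapply(seq_along(modules), function(i) {
    enrich_subnetwork(modules[[i]], collection, universe, ids[i])
  }))
  names(modules) <- ids
  report <- aggregate_pathways(results, modules, collection, threshold)
  list(differential = diff_tab, scores = scores, calibration = calibration,
       modules = modules, results = results, report = report)
}

#' Read a pipeline configuration from JSON
#'
#' Fields: `study`, `groups`, `map`, `network`, `gmt` (input paths),
#' `case_groups`, `control_group`, `filter` (fold_threshold/alpha/
#' min_obs_per_group), `search` (n_modules/max_overlap/sa_iterations/
#' t_start/t_end/restarts), `threshold`, `randomization_runs`,
#' `shuffle_scope` (`"all"` or `"ms-only"`), `seed`, `outdir`. Referenced
#' input files must exist.
#'
#' @param path path to the JSON config.
#' @return a validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("study", "groups", "map", "network", "gmt")) {
    if (is.null(cfg[[f]])) stop("config field missing: ", f, call. = FALSE)
    if (!file.exists(cfg[[f]])) {
      stop("config input does not exist: ", f, " = ", cfg[[f]], call. = FALSE)
    }
  }
  if (is.null(cfg$seed)) stop("config field missing: seed", call. = FALSE)
  cfg$control_group <- cfg$control_group %||% "CONTROL"
  cfg$threshold <- cfg$threshold %||% 0.05
  cfg$randomization_runs <- cfg$randomization_runs %||% 0
  cfg$shuffle_scope <- cfg$shuffle_scope %||% "all"
  cfg$outdir <- cfg$outdir %||% "panet_out"
  structure(cfg, class = "pipeline_config")
}

#' Run the complete pipeline from a configuration
#'
#' Executes, per case group: differential statistics, subnetwork search and
#' pathway enrichment; then (optionally) the label-shuffling randomization
#' control; writes per-group gene tables, module tables and pathway
#' reports, a shared-pathways intersection table, the randomization table,
#' and a JSON run manifest (package version, seeds, universe definition,
#' parameter values) sufficient to reproduce every output byte-identically.
#'
#' @param config a `pipeline_config` (from [read_pipeline_config()]) or an
#'   equivalent in-memory list.
#' @return invisibly, a list of per-group results plus the randomization
#'   summary (if run).
#' @export
run_all <- function(config) {
  cfg <- config
  # fill defaults so in-memory configs behave like parsed ones
  cfg$control_group <- cfg$control_group %||% "CONTROL"
  cfg$threshold <- cfg$threshold %||% 0.05
  cfg$randomization_runs <- cfg$randomization_runs %||% 0
  cfg$shuffle_scope <- cfg$shuffle_scope %||% "all"
  cfg$outdir <- cfg$outdir %||% "panet_out"
  if (is.null(cfg$seed)) stop("config field missing: seed", call. = FALSE)
  study <- read_intensity_table(cfg$study, cfg$groups)
  map <- read_protein_gene_map(cfg$map)
  network <- read_network(cfg$network)
  collection <- read_gmt(cfg$gmt)
  case_groups <- cfg$case_groups %||%
    setdiff(unique(study$groups), cfg$control_group)
  fparams <- do.call(filter_params, as.list(cfg$filter %||% list()))
  sargs <- as.list(cfg$search %||% list())
  sargs$seed <- cfg$seed
  sparams <- do.call(search_params, sargs)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  universe <- default_universe(network, collection)

  res <- list()
  for (g in case_groups) {
    r <- tryCatch(
      run_group_analysis(study, map, network, collection, g,
                         cfg$control_group, fparams, sparams,
                         threshold = cfg$threshold, universe = universe),
      error = function(e) {
        stop(sprintf("stage 'group analysis' failed for group %s: %s", g,
                     conditionMessage(e)), call. = FALSE)
      })
    write_gene_scores_tsv(r$differential,
                          file.path(cfg$outdir, paste0("diff_", g, ".tsv")))
    write_modules_tsv(r$modules,
                      file.path(cfg$outdir, paste0("modules_", g, ".tsv")))
    write_pathway_report(r$report,
                         file.path(cfg$outdir, paste0("report_", g, ".tsv")))
    res[[g]] <- r
  }

  # shared-pathways intersection across case groups
  shared <- Reduce(intersect, lapply(res, function(r) r$report$pathway_id))
  write_lines_utf8(c("pathway_id", sort(shared, method = "radix")),
                   file.path(cfg$outdir, "shared_pathways.tsv"))

  rand <- NULL
  if ((cfg$randomization_runs %||% 0) > 0) {
    rand <- randomization_analysis(study, map, network, collection,
                                   case_groups, cfg$control_group,
                                   fparams, sparams,
                                   threshold = cfg$threshold,
                                   R = cfg$randomization_runs,
                                   seed = cfg$seed,
                                   scope = cfg$shuffle_scope)
    write_randomization_tsv(rand, file.path(cfg$outdir, "randomization.tsv"))
  }

  manifest <- list(
    package = "panet",
    version = as.character(utils::packageVersion("panet")),
    seed = cfg$seed,
    case_groups = case_groups,
    control_group = cfg$control_group,
    filter = unclass(fparams),
    search = unclass(sparams),
    threshold = cfg$threshold,
    randomization_runs = cfg$randomization_runs,
    shuffle_scope = cfg$shuffle_scope,
    universe = "network genes annotated to >= 1 pathway",
    universe_size = length(universe),
    inputs = cfg[c("study", "groups", "map", "network", "gmt")]
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(res, list(randomization = rand)))
}
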