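# panet

Active-subnetwork pathway analysis for differential proteomics, in R.

Comparative proteomics studies (2D-gel CSF proteomes of multiple-sclerosis
subtypes, for instance) end with a spot-intensity table and a question:
*which biological pathways separate the groups?* panet implements the full
analysis chain as a tested, deterministic pipeline:

1. **Differential statistics** — per-group fold changes
   (case mean / control mean), Welch t-tests, the "at least 2-fold and
   P < 0.05" selection filter, CV quality control, pairwise ANOVA with
   Bonferroni correction.
2. **Active-subnetwork search** — gene p-values become z-scores
   `z_i = qnorm(1 - p_i)` on a PPI network; a connected gene set A of size
   k is scored by `z_A = sum(z_i)/sqrt(k)`, standardized against a
   Monte-Carlo background of random connected size-k sets
   (`s_A = (z_A - mu_k)/sigma_k`); high-scoring modules are found by
   simulated annealing and reported with at most 50% pairwise overlap.
3. **Pathway enrichment** — exact two-sided (enrichment/depletion)
   hypergeometric test per module and pathway, Bonferroni-corrected,
   aggregated into a per-pathway report (best corrected p, "times found",
   pathway genes found / not found in subnetworks).
4. **Label-shuffling randomization** — the whole chain re-run on permuted
   group labels to show findings are group-specific.

A synthetic-study generator with planted ground truth (scale-free network,
pathway collection with a designated pathway, log-normal intensities with
controlled intra-group CV and planted ≥2-fold effects) makes the pipeline
verifiable end to end. See the methods vignette
(`vignettes/active-subnetwork-pathway-analysis.Rmd`) for models,
parameters, and design rationale.

## Worked example

```r
library(panet)

# a synthetic study: 400-gene network, 50 pathways, 12 planted genes with
# 2.5-4.2-fold effects inside the designated pathway PW0001
sim <- simulate_experiment(seed = 7, n_genes = 400, n_sets = 50,
                           planted_size = 12, fold_range = c(2.5, 4.2))

res <- run_group_analysis(sim$study, sim$map, sim$network, sim$genesets,
                          group = "CIS", control_group = "CONTROL",
                          sparams = search_params(n_modules = 5, restarts = 2,
                                                  sa_iterations = 2500,
                                                  seed = 7))

head(res$differential[order(res$differential$p), ], 3)
#>      gene group      fold            p selected
#> 203 G0203   CIS 0.3512949 5.920147e-11     TRUE
#> 201 G0201   CIS 5.2824950 2.195438e-09     TRUE
#> 307 G0307   CIS 3.4061244 1.379282e-07     TRUE

res$modules[[1]]
#> <subnetwork> k = 18, z_A = 15.393, s_A = 9.620
#>  genes: G0011, G0077, G0121, G0145, G0184, G0201, G0203, G0211, G0219, ...

res$report[, c("pathway_id", "name", "best_p_corr", "times_found")]
#>   pathway_id                         name  best_p_corr times_found
#> 1     PW0001 designated synthetic pathway 7.008101e-07           1
```

Reading the output: the two most significant genes are planted (G0203 is a
~2.8-fold *decrease*, G0201 a ~5-fold increase — realized folds scatter
around the planted magnitudes); the best module (calibrated score
`s_A = 9.6`, i.e. 9.6 background standard deviations above a random
connected 18-gene set) contains the planted module; and the designated
pathway tops the report with a Bonferroni-corrected hypergeometric p of
7×10⁻⁷, found significant in 1 of the extracted modules.

On real data, replace the simulated objects with
`read_intensity_table()`, `read_protein_gene_map()`, `read_network()`
(edge-list TSV or SIF) and `read_gmt()`, or drive everything from a JSON
config with `run_all()` / the CLI:

```sh
Rscript -e 'panet::cli_main()' simulate --outdir sim --seed 7
Rscript -e 'panet::cli_main()' run-all --config config.json
```

Subcommands: `simulate`, `diff`, `subnet`, `enrich`, `randomize`,
`run-all` (the same script is installed under `exec/panet`).

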