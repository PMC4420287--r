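---
title: "Active-subnetwork pathway analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-subnetwork pathway analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis panet implements

Comparative gel-based proteomics studies ask which biological pathways
separate patient groups — for example cerebrospinal-fluid proteomes of
multiple-sclerosis subtypes against neurological controls. The raw material
is a spot/protein intensity table (one row per protein spot, one column per
sample gel, arbitrary optical-density units) plus a sample-to-group
assignment. panet chains four stages:

1. **Differential statistics** per case group against a control group:
   fold changes, Welch t-tests, and a joint fold/significance selection
   filter.
2. **Active-subnetwork search**: gene-level p-values are laid over a
   protein–protein interaction (PPI) network and connected modules whose
   members are collectively more significant than chance are extracted by
   simulated annealing against a size-calibrated background.
3. **Pathway enrichment** of each module by an exact two-sided
   hypergeometric test with Bonferroni correction, aggregated across
   modules into a per-pathway report.
4. **Label-shuffling randomization**: the whole chain re-run on permuted
   group labels, counting how often each pathway recurs, to show that a
   finding is group-specific rather than generic.

A synthetic-study generator with planted ground truth makes the whole chain
testable end to end without any patient data.

# Differential stage

For protein $i$, case group $g$ and control samples $c$:

* **Fold change** is the ratio of arithmetic means on the raw intensity
  scale, $\mathrm{FC}_i = \bar{x}_{ig} / \bar{x}_{ic}$; missing cells
  (absent spots) are skipped, never treated as zeros — a zero would bias
  every downstream ratio.
* **Test**: Welch's unequal-variance t-test, the safer default when group
  sizes differ (the emulated design has 65 vs 42 samples at full scale).
  Two identical constant groups give $p = 1$; $p$ is floored at
  $10^{-300}$ so it stays in $(0, 1]$. The test is applied to raw
  intensities; the reported fold is descriptive. (Whether to test raw
  intensities or log-folds is genuinely open for this kind of data; raw
  intensities are the default and the choice is deliberately confined to
  one function, `welch_rows()`.)
* **Selection filter**: keep proteins at least `fold_threshold`-fold
  changed in either direction — boundary inclusive, so exactly 2.0 passes
  ("at least 2-fold") — with $p < \alpha$. Defaults: 2.0 and 0.05.
* **Isoform collapse**: 2D gels resolve one gene into several spots. Spots
  mapping to one gene are collapsed to the minimum p-value and that spot's
  fold (`collapse = "min"`), matching the "most significantly changing
  protein represents the gene" reading; a mean-collapse alternative is one
  argument away.
* **Testability**: at least `min_obs_per_group = 3` non-missing values per
  side; untestable proteins are excluded, unmapped proteins are excluded
  *with a reported count* — never silently.
* Two control cohorts (e.g. non-inflammatory + other neurological
  diseases) are pooled by default; `combine_controls = FALSE` tests
  against each separately.

The full gene list with p-values — not only the selected subset — feeds the
network stage; the filter matters for reporting, not for scoring.

# Active-subnetwork model

Gene p-values become upper-quantile z-scores $z_i = \Phi^{-1}(1 - p_i)$,
with p clamped to $[10^{-16}, 1 - 10^{-16}]$ so z stays finite. A candidate
connected gene set $A$ of size $k$ has aggregate score

$$z_A = \frac{1}{\sqrt{k}} \sum_{i \in A} z_i,$$

which is standard normal for every $k$ under independent null scores. Real
networks and real score vectors are not that null, so $z_A$ is standardized
against a Monte-Carlo background: $\mu_k, \sigma_k$ are the mean and sd of
$z_A$ over `mc_samples` random connected size-$k$ sets, and the calibrated
score is $s_A = (z_A - \mu_k)/\sigma_k$.

Numerical and sampling choices worth knowing:

* Background sets are grown by a uniform random walk (start node uniform,
  then repeatedly add a uniform boundary neighbour). This is *not* uniform
  over all connected size-$k$ sets — it over-weights hub-adjacent sets —
  but the same sampler defines both the calibration and any background
  comparison, so the standardization is self-consistent. $k = 1$ is
  computed exactly over all genes.
* $\mu_k$ conditions on the one realised z vector, so on a finite network
  it sits $O(\sqrt{k/n})$ away from zero even for uniform p-values; what
  is guaranteed (and tested) is that *calibrated scores of fresh draws
  from the same sampler* have mean $\approx 0$ and sd $\approx 1$.
* If every gene carries the same z the background is degenerate and
  calibration errors out; if only individual sizes are degenerate (e.g.
  $k$ equal to the network size, where exactly one connected set exists)
  those sizes are dropped from the searchable range with a warning.
* Network genes without a score are assigned $p = 0.999$: strongly
  disfavoured, but still usable as connectors; scored genes absent from
  the network are dropped with a reported count.

## Search

`anneal_search()` runs simulated annealing over connected sets:

* **Moves** are node toggles: a candidate is drawn uniformly from the
  current members plus the boundary (non-member neighbours). Drawing from
  the union — rather than flipping a coin between "add" and "remove" —
  keeps the growth/shrink pressure self-balancing at every size;
  a removal that would disconnect the set is rejected outright
  (connectivity is a hard constraint, checked by BFS).
* **Acceptance** is Metropolis, $\exp(\Delta s_A / T)$, under geometric
  cooling from `t_start = 1` to `t_end = 1e-3` over
  `sa_iterations = 10000` steps, with `restarts = 5` independent
  restarts.
* **Restart starts** alternate between the top-ranked z genes (the natural
  nuclei of active modules) and random connected sets of random size (for
  basin diversity).
* The best-seen set of each restart gets a deterministic greedy polish
  (best improving add / remove / swap until locally optimal), so reported
  modules are always local optima.
* Everything derives from one integer seed; two runs with the same seed
  are identical.

## Module size cap

The additive score has a known pathology: once a strong module exists, any
reachable gene with a moderately positive z *raises* $s_A$, so an
unconstrained optimizer returns the true module diluted with marginal
hangers-on (we observed k ≈ 30 supersets of a 12-gene planted module).
Established active-module tools guard this with size limits, and so does
panet: the default calibration range — hence the searchable range — is
$k \le 20$, about twice the size of the modules the emulated study design
plants and reports. Widen `k_range` deliberately if your biology expects
larger modules, and expect dilution when you do.

## Multiple modules

`find_subnetworks()` runs `n_modules × restarts` searches, ranks all
candidate modules by $s_A$, and keeps a candidate only if its overlap with
every kept module is at most `max_overlap = 0.5`. Overlap is
$|A \cap B| / \min(|A|, |B|)$ — the smaller-set denominator, so a module
nested inside a kept one counts as fully overlapping. Fewer than
`n_modules` modules is a normal outcome on landscapes with few distinct
optima.

# Enrichment stage

For each module, each pathway with at least one gene in the universe is
tested with the exact two-sided hypergeometric (enrichment/depletion) test
in the minimum-likelihood convention: the p-value sums the probabilities of
all overlap counts no more probable than the observed one (the Fisher-exact
convention; floating-point ties are compared with a $10^{-7}$ relative
tolerance). Bonferroni multiplies by $m$, the number of pathways tested
within that module's analysis, capped at 1.

* **Universe** $N$: network genes annotated to at least one pathway
  (configurable to any gene vector). The choice moves every p-value, so
  the run manifest records it.
* **Direction**: pathways with observed overlap below expectation are
  flagged `depletion` and excluded from the report by default — the
  report format mirrors published tables, which list enriched pathways.
* **Aggregation**: per pathway, the best (minimum) corrected p across
  modules is reported ("only the most significant one"), `times_found`
  counts the modules where the pathway is significantly enriched, and
  pathway genes are split into those found in (the union of) significant
  modules versus the rest.

# Randomization control

`randomization_analysis()` permutes the sample-to-group labels `R = 10`
times and reruns the entire pipeline per shuffle. A pathway "occurs" in a
run when it enters that run's report (corrected p < 0.05 in at least one
module). Two scopes are provided because the emulated design is ambiguous
about whether controls were shuffled too: `"all"` (default — every label
permuted, so case/control contrasts are fully null) and `"ms-only"`
(controls held fixed, disease labels permuted). Per-run (shuffle, search)
seed pairs are derived from the master seed in an interleaved layout, so
the first $R$ runs of a longer randomization are exactly the runs of a
shorter one, and the summary stores them for replay.

# The synthetic world

`simulate_experiment()` generates every pipeline input from one master
seed. What it emulates, and the defaults:

* **Network**: power-law fitness graph, degree exponent 2.2 (the value
  typically reported for human PPI networks), mean degree 4, largest
  component of 400 genes; a duplication–divergence alternative is
  available.
* **Pathways**: 50 sets of 15–80 genes with a shared "popular gene" pool
  (`overlap_rate = 0.2`) so sets overlap as curated databases do. One
  designated pathway is built around a randomly grown *connected* core so
  a connected planted module can live inside it.
* **Intensities**: log-normal. Baselines span orders of magnitude
  (sdlog 0.8 around a 5×10³ median); within-group noise uses
  $\sigma^2 = \ln(1 + \mathrm{CV}^2)$ so the intra-group CV is directly
  the `target_cv = 24`% knob — the emulated study reports intra-group CVs
  of 22–26%. Planted genes carry fold effects with magnitude uniform in
  `fold_range = c(2, 4.2)` (the reported effect range) and random
  direction, applied in every non-control group.
* **Design**: `c(CIS = 12, RRMS = 14, PMS = 8, CONTROL = 8)` — a
  scaled-down analog of the 65/72/42/42 cohort that keeps the test suite
  fast; the full-scale design is one argument away.
* **Missingness**: 2% completely at random, with a floor of 3 observed
  values per protein per group so everything stays testable. Informative
  spot absence is deliberately out of scope.

What the generator does *not* emulate: isoform spot trains, gel warping
and matching artifacts, informative missingness, correlated protein
abundances, and the real topology of curated PPI/pathway databases. A
green end-to-end test therefore establishes that the pipeline recovers a
planted signal of realistic effect size under realistic independent noise
— not that it reproduces any particular published table.

# Other numerical conventions

* p-values are clamped to $[10^{-16}, 1 - 10^{-16}]$ before z-conversion;
  `p_to_z()` rejects values outside $(0, 1)$.
* `two_fold_filter` is idempotent and order-invariant; the fold boundary
  is inclusive.
* All writers emit UTF-8, Unix line endings, and lexicographically sorted
  records, so outputs are byte-stable and diffable; `run_all()` writes a
  JSON manifest (seeds, parameters, universe definition, package version)
  sufficient to reproduce every output byte for byte.
* The pipeline is single-threaded by design: determinism is part of the
  contract.

# Known limitations

* The random-walk background sampler is not uniform over connected sets;
  calibration is self-consistent but not canonical.
* With Monte-Carlo calibration at `mc_samples = 200` (the pipeline
  default), $\sigma_k$ carries ~5% sampling noise, which the optimizer
  can exploit across sizes; raise `mc_samples` when comparing modules of
  different sizes is critical.
* Bonferroni within each module's analysis is conservative across many
  modules; no FDR alternative is provided by design.
* The randomization control is descriptive at R = 10, mirroring the
  emulated study; it is not a formal permutation test (larger R works,
  but no p-value machinery is attached).
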