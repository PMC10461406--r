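# crisprdiff

Statistical analysis of pooled CRISPRi fitness screens run in cell lines
from two closely related species, aimed at one question: which genetic
dependencies are shared between the species and which are specific to one
of them.

A pooled CRISPRi screen infects a cell population with a guide library
(~5 sgRNAs per gene plus non-targeting controls), grows it competitively,
and sequences guide abundances at the start (t0) and end (tfinal). Guides
against essential genes are depleted; guides against proliferation
suppressors are enriched. Comparing screens across species adds three
specific problems, each addressed here:

* **Cross-species guide validity.** A guide designed against genome A may
  mismatch genome B, mimicking a species difference. `crisprdiff` scans
  both genomes for perfect, NGG-adjacent protospacer matches and excludes
  guides (and sparsely covered genes) that do not match both.
* **A calibrated per-sgRNA test.** Counts are normalized by the
  median-of-ratios method and tested against a negative-binomial null,
  Var(X) = mu + alpha * mu^2, with the overdispersion alpha fitted on the
  non-targeting controls; the significance cutoff per screen is then chosen
  so that at least 95% of non-targeting guides are non-significant — a
  guarantee that holds by construction. Gene-level significance in the
  genome-wide arm comes from bootstrapping groups of 1-5 non-targeting
  guides, with Benjamini-Hochberg FDRs.
* **A replicated species contrast.** For validation screens across several
  individuals per species, each sgRNA gets a log-link NB GLM with
  individual fixed effects and species-specific time effects; the Wald
  contrast beta_B - beta_A is BH-adjusted and aggregated to genes with
  alpha-robust rank aggregation (alpha-RRA). A gene is called
  species-specific iff its contrast-term FDR < 0.01, at least three of its
  sgRNAs pass the alpha threshold, and the between-species gene log2FC
  difference (top-4 |LFC| convention) is at least 0.75 — unless a
  shared-effect exclusion removes genes strong in both species.

A synthetic two-species screen generator (`simulate_screen()`) with known
ground truth — guide activities, per-species fitness effects, cross-species
mismatches, overdispersed counts — makes the entire chain testable without
external data.

## Worked example

Simulate a validation-scale screen (300 genes, 10% with species-specific
effects, 3 individuals per species, 2 technical replicates) and run the
full contrast pipeline:

```r
library(crisprdiff)
library(dplyr)

cfg <- sim_config(n_genes = 300, n_nt_guides = 300, lines_per_species = 3,
                  reps_per_line = 2, frac_species_specific = 0.1, seed = 7)
sim <- simulate_screen(cfg, genomes = FALSE)
res <- run_validation_pipeline(sim$counts, sim$design, sim$library,
                               n_perm = 10000, seed = 7)
glance(res)
#> # A tibble: 1 × 6
#>   n_sgrna n_genes alpha_dispersion alpha_rra n_species_different_sgrna n_called
#>     <int>   <int>            <dbl>     <dbl>                     <int>    <int>
#> 1    1800     300           0.0498    0.0794                       143       28
```

The fitted dispersion (0.0498) recovers the simulator's 0.05; 143 sgRNAs
are flagged species-different (adjusted p < 0.01 and |delta-log2FC| >= 0.5)
and 28 genes are called species-specific. The gene table shows, per gene,
the contrast-term FDR, how many of its sgRNAs passed the alpha threshold,
and the per-species gene LFCs whose difference drives the call:

```r
tidy(res$genes) |>
  filter(call != "none") |>
  select(gene, fdr_diff, n_pass_diff, lfc_a_gene, lfc_b_gene, call) |>
  head(5)
#> # A tibble: 5 × 6
#>   gene  fdr_diff n_pass_diff lfc_a_gene lfc_b_gene call
#>   <chr>    <dbl>       <int>      <dbl>      <dbl> <chr>
#> 1 G0014  0.00115           5      0.138     -1.79  speciesB-specific
#> 2 G0021  0.00115           5      0.140     -1.95  speciesB-specific
#> 3 G0025  0.00115           5      0.291     -2.72  speciesB-specific
#> 4 G0050  0.00429           4      0.292     -1.10  speciesB-specific
#> 5 G0052  0.00115           5     -1.87      0.227  speciesA-specific
```

G0014, for example, has essentially no fitness effect in species A (gene
LFC 0.14) but strong depletion in species B (-1.79): a species-B-specific
dependency. Checking against the simulator's ground truth, all 28 calls in
this run are genes that truly carry species-specific effects (14 per
species). `autoplot(res$genes)` draws the corresponding volcano plot, and
`precision_recall()`, `replicate_correlation()`, `pca_profiles()` and
`variance_partition()` provide the standard screen quality metrics.

A thin command-line wrapper over the same functions ships in
`inst/cli/crisprdiff` (subcommands `simulate`, `count-reads`, `match`,
`analyze-primary`, `analyze-contrast`, `evaluate`).

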