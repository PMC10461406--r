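---
title: "Comparative analysis of two-species CRISPRi fitness screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of two-species CRISPRi fitness screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprdiff)
library(dplyr)
```

## The problem

Pooled CRISPR interference (CRISPRi) fitness screens measure how repressing
each gene changes a cell population's growth: cells carrying an sgRNA against
an essential gene are depleted from the pool between the start of the screen
(t0) and its end (tfinal), while sgRNAs against proliferation suppressors are
enriched. Run in cell lines from two closely related species, the same
readout can ask an evolutionary question: which genetic dependencies are
shared, and which are specific to one species?

Answering it requires more care than a single-species screen. Guides designed
against one genome may carry mismatches against the other, confounding
apparent species differences with knockdown failure; lines differ between
individuals of the same species, so species effects must be separated from
individual effects; and the final species-specific calls need stringent,
replicated statistical support. `crisprdiff` implements this full analysis
chain, together with a synthetic two-species screen generator that makes
every stage testable against known ground truth.

## Pipeline overview

1. **Cross-species guide filtering** (`find_target_sites()`,
   `cross_species_filter()`, `tss_coverage_filter()`): guides are kept only
   if their 20-nt protospacer has at least one perfect, NGG-adjacent match in
   *both* genomes, and genes only if at least three such guides remain.
2. **Per-sgRNA screen statistics** (`analyze_screens()`): median-of-ratios
   normalization, log2 fold-changes, a negative-binomial null calibrated on
   non-targeting (NT) controls, and per-screen significance calls.
3. **Gene scores and genome-wide candidates** (`gene_score()`,
   `bootstrap_gene_fdr()`, `direction_scores()`, `classify_essentiality()`,
   `candidate_selection()`).
4. **Validation-screen contrast** (`fit_sgrna_contrast()`, `alpha_rra()`,
   `call_species_specific()`): a species-by-time count model per sgRNA,
   alpha-robust rank aggregation to genes, and a three-condition
   species-specific caller with a shared-effect exclusion.
5. **Quality metrics** (`precision_recall()`, `replicate_correlation()`,
   `pca_profiles()`, `variance_partition()`, `flag_p53_dependence()`).

All user-facing functions take plain tibbles (counts as guides-by-samples
tables, a sample sheet with species/individual/replicate/timepoint) and
return tibbles, so steps compose with the pipe; fitted objects carry
`tidy()`/`glance()` methods and results have `autoplot()` methods.

## The per-sgRNA null model

Counts are normalized by the median-of-ratios method: the size factor of a
sample is the median, over guides with positive counts everywhere, of the
ratio of the guide's count to its geometric mean across samples.

Under the null of no fitness effect, a guide's expected abundance at tfinal
equals its t0 abundance. Both are measured with overdispersed counting
noise, which we model with the quadratic trend
$\mathrm{Var}(X) = \mu + \alpha\mu^2$. The trend parameter $\alpha$ is fitted
per screen on the NT guides' tfinal replicates. The default estimator
maximizes the conditional (Dirichlet-multinomial) likelihood of each guide's
replicate counts given their sum, which removes the unknown per-guide mean
from the problem; with only two replicates, the naive regression of sample
variance on squared sample mean is biased downward because the regressor
shares sampling noise with the variance estimate, and that bias is large
enough to distort downstream p-values. The moment regression remains
available via `method = "moments"`.

The test statistic compares the summed tfinal counts against the t0-derived
expectation. Because the expectation is itself estimated from counts with
the same noise structure, the comparison variance is
$(1 + R_f/R_0)\,(M + (\alpha/R_f)\,M^2)$ for $R_0$ t0 and $R_f$ tfinal
replicates; for the canonical two-plus-two design this reduces exactly to
the plain trend $M + \alpha M^2$. The two-sided tail probability
$p = 2\min\{P(X \le x),\, P(X \ge x),\, 0.5\}$ is evaluated with the
continuous gamma-Poisson mixture CDF so non-integer normalized counts are
handled smoothly; at integer observations it coincides with the discrete
negative-binomial tail, and at $\alpha = 0$ with the Poisson tail.

Rather than trusting the parametric tail at face value, each screen is
calibrated on its own controls: `calibrate_significance()` picks the largest
cutoff $c^\*$ such that at least 95% (configurable) of NT guides are
non-significant. The guarantee holds by construction on every input, making
per-sgRNA calls robust to residual model misfit.

## Gene-level inference in the genome-wide arm

A gene's score in one screen is the mean log2 fold-change of its guides that
pass both filters (perfect match in both genomes, per-sgRNA significance);
an alternative convention, the mean of the top-$k$ guides by absolute LFC
($k$ = 3 genome-wide, 4 in validation), is available via
`gene_score(mode = "top_k")`. Significance comes from a bootstrap of the NT
pool: a gene scored from $m$ retained guides is compared against 10,000
means of $m$ NT LFCs, with the two-sided empirical p-value using the add-one
correction and Benjamini-Hochberg FDRs across genes. Matching the null
group size to $m$ preserves the variance of the mean; group sizes drawn
uniformly from 1-5, and sampling without replacement, are exposed as flags
because the published description fixes neither.

Direction scores (significantly depleted minus significantly enriched guides
per gene and screen, summed within species) support a complementary,
magnitude-free family of selection criteria. `candidate_selection()`
evaluates the full published set of twelve magnitude and direction-score
criteria plus the per-line 10%/25% FDR rule, exactly as printed. One
published criterion (species-B essential, set 2) is kept verbatim even
though its printed conditions are jointly unsatisfiable — its opening term
references the species-A direction-score sum, which contradicts the
difference and ratio conditions that follow; the test suite documents the
infeasibility over an exhaustive grid. Essentiality classes per screen
(essential: within the top 3,000 most depleted *and* more than 4-fold mean
depletion; nonessential: less than 2-fold) feed intersection sets built with
the dual rule: essential in every member screen and nonessential in every
non-member.

## The validation contrast

Each sgRNA's counts across all validation samples are modeled with a
log-link negative-binomial GLM:

$$\log \mu_{ij} = \beta_{d(j)} + \beta_A\,t_j\,[s_j = A] +
\beta_B\,t_j\,[s_j = B] + \log f_j$$

with individual fixed effects $\beta_{d(j)}$ nested within species, a
species-specific time effect, and size-factor offsets $\log f_j$. The
dispersion is the NT trend value (a single pooled trend; no per-guide
shrinkage or LFC moderation — a documented simplification relative to
shrinkage-based count frameworks). The species terms are contrasted by a
Wald test on $\beta_B - \beta_A$, reported in log2 units with BH-adjusted
p-values; sgRNAs at adjusted p below 0.01 and $|\Delta \mathrm{LFC}| \ge
0.5$ are flagged species-different. Guides with all-zero counts are dropped;
non-converged fits are retained with p = 1 and flagged.

Adjusted sgRNA p-values are aggregated to genes with alpha-robust rank
aggregation (alpha-RRA): sgRNAs are converted to percentile ranks; only
ranks at or below the threshold $\alpha$ — set to the fraction of sgRNAs
with adjusted p below 0.01, so insignificant guides cannot drive gene calls
— contribute; the gene statistic is the minimum over the Beta CDFs of the
contributing order statistics; and gene p-values come from a permutation
null stratified by gene size (draws shared within a stratum for
efficiency), with BH FDRs. Genes with no contributing sgRNA receive p = 1
by construction, so gene p-values are uniform on their continuous part and
carry an atom at 1 — valid (super-uniform) everywhere.

The final caller requires, in the contrast term: gene FDR below 0.01, at
least three sgRNAs passing $\alpha$, and a between-species gene LFC
difference of at least 0.75, where each species' gene LFC is the mean of
its four largest-|LFC| sgRNAs (all available are used, with a warning, for
genes with fewer than four; measuring the difference on the contrast-term
deltas instead is exposed as `use_contrast_lfc`). A shared-effect exclusion
then removes genes strong in both species: within each species term, the
threshold is the highest FDR reached by any gene with at least one
alpha-passing sgRNA, and a gene whose FDR falls below that threshold in
*both* species terms is discarded as shared. The published description does
not say in which term "the highest FDR" is measured; computing it per term
is this package's reading. The called species is the one with the larger
absolute gene LFC.

Two companion analyses mirror the validation workflow: a per-gene Welch
t-test comparing p53-unresponsive against p53-responsive lines of one
species (exploratory flag, default threshold 0.05), and a per-sgRNA variance
partition across species, individual (nested) and timepoint. The variance
partition uses a sequential-ANOVA (Henderson method-of-moments) estimator:
expected sums of squares from the projection decomposition are equated to
their observed values, giving one small linear solve shared by all sgRNAs;
components are truncated at zero and reported as fractions, and gene values
are the means over each gene's sgRNAs. With only two species the species
stratum has a single degree of freedom, so per-sgRNA species fractions are
noisy and slightly shrunk by the truncation; they are meaningful averaged
over many sgRNAs, which is how they are reported.

## The synthetic screen generator

`simulate_screen()` draws a guide library (distinct random 20-nt spacers,
five per gene by default, plus NT controls), toy single-contig genomes that
embed every targeting protospacer once with an NGG PAM (with 1-3
substitutions introduced in the species-B copy for a configurable guide
fraction, and NT spacers verified absent), and counts for the full design.
A gene's ground-truth effect $\gamma$ is its total log2 change in relative
abundance over the screen — matching the two-timepoint readout rather than
a per-day rate — applied in one or both species according to its class, and
attenuated linearly (in log2 space) by each guide's knockdown activity.
tfinal expected abundances are renormalized to constant sequencing depth,
and all counts are negative-binomial with variance $\mu + \alpha\mu^2$.
Each artifact (library, genomes, counts) consumes its own RNG stream
derived from the master seed, so changing one component's parameters leaves
the others' draws intact.

Defaults describe a realistic desk-scale screen and were fixed once:
sequencing depth of 500 expected reads per guide at t0 (deep coverage);
dispersion $\alpha = 0.05$, a typical value for well-powered pooled screens
— the reference screens do not report their dispersion, so this is the
package's own choice, not a published value; guide activities uniform on
(0.5, 1), reflecting partial knockdown; effect sizes drawn from
$N(-3, 1)$ log2 units; 20% of genes with shared effects (negative draws are
shared-essential, positive ones proliferation suppressors), 10%
species-specific; and a 0.226 mismatch fraction in genome B, which
reproduces a 77.4% perfect-match retention rate.

The simulator emulates the statistical structure the analysis relies on —
overdispersed counts, library composition bias, species-by-individual-by-
replicate-by-timepoint design, cross-species mismatches, partial guide
activity — and deliberately not: sequencing errors in reads, chromatin or
TSS-position effects on knockdown efficiency, clone-specific artifacts
beyond what per-line labels can express, or growth dynamics between the two
timepoints. Tests passing on these simulations therefore validate the
statistical machinery, not robustness against every artifact of real
screens.

## Numerical choices

* Ties break deterministically everywhere: descending score then
  lexicographic guide id in guide selection and top-$k$ scores; candidate
  cutoffs in calibration come from the sorted unique NT p-values.
* The LFC pseudocount (0.5) applies only to log2 fold-changes, never inside
  the count test, so it cannot bias the NB null.
* Empirical p-values (bootstrap, permutation) use the add-one correction
  and so are never zero.
* Tail probabilities count the observed point once in each tail and are
  capped at 1; null means of zero yield p = 1 with a warning.
* Rank ties at the essentiality `top_n` boundary are all included.
* Degenerate inputs error with specific messages (aliased design factors,
  unpaired samples, negative or non-integer counts, all-zero normalization
  references) rather than propagating silently.

## Problem sizes used in the packaged checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen to be comfortably informative on a single CPU: null-calibration
checks use 5,000-guide screens with large NT pools (the trend estimate,
not the test, is the accuracy bottleneck, and calibration-scale NT pools
number in the thousands in real libraries); the end-to-end false-discovery
check runs twenty replicate screens of 1,000 genes x 5 guides plus 500 NT
guides across 3 individuals per species with 2 technical replicates;
oracle-equivalence checks (negative-binomial tails against direct pmf
summation, alpha-RRA against closed-form Beta order statistics, BH against
a reference step-up, site search against a naive scanner) run on small
enumerable instances.

## Known limitations

* The Wald NB GLM with a single pooled dispersion is a deliberate
  simplification: no empirical-Bayes dispersion moderation and no LFC
  shrinkage. With few replicates per individual, very low-count sgRNAs have
  less reliable per-term p-values; the alpha-RRA aggregation and the
  calibration-by-controls step are the mitigations.
* Genome matching targets desk-scale genomes (toy contigs, validation
  constructs); no index structure is built, so genome-wide mammalian scans
  are out of scope.
* The conditional dispersion estimator treats normalized counts as
  exchangeable across replicates after size-factor correction; with wildly
  unequal replicate depths the approximation degrades.
* The p53-dependence flag is exploratory: with two lines in the
  unresponsive group the t-test has minimal power, and the flag threshold
  is not multiplicity-adjusted.
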