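---
title: "Genotype-contrast differential expression with permutation robustness diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-contrast differential expression with permutation robustness diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pisasterDE)
```

## The problem

The ochre sea star *Pisaster ochraceus* carries an overdominant insertion
allele (*ins*) in an intron of elongation factor 1-alpha (EF1A). The allele
is homozygous-lethal, so natural populations contain only two genotype
classes — *ins* heterozygotes and *wild* homozygotes — and the heterozygotes
show reduced incidence of sea star wasting disease. `pisasterDE` implements
the expression side of that question as a reusable pipeline: given
fragment-by-library RNA-seq counts for a handful of individuals of each
genotype, sampled at ambient and at +3 °C elevated water temperature, it
asks which fragments differ constitutively between genotypes, how each
genotype responds to warming, how robust the genotype partition is to
relabeling individual libraries, and whether any single library behaves
like a member of the other class. A righting-response module covers the
accompanying behavioral assay.

The design the package targets is small: five individuals per genotype,
each contributing one library per temperature treatment. Everything in the
statistical machinery is chosen for that regime.

## The model

Counts are modeled as negative binomial,
$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi_g)$ with
$\mathrm{Var}(y) = \mu + \phi\mu^2$, where $\mu_{gj}$ is proportional to the
library's effective size and the fragment's relative abundance in the
library's class. The analysis chain for one two-class contrast is:

1. **Filter**: keep fragments with CPM strictly above 1 (unnormalized) in
   at least two libraries.
2. **TMM normalization**: per-library factors from the weighted trimmed
   mean of log2 ratios against a reference library (30% trim on M, 5% on A,
   delta-method precision weights, factors rescaled to geometric mean one).
   The reference is the library whose upper-quartile CPM is closest to the
   mean upper-quartile.
3. **Library equalization**: counts are quantile-mapped to a common
   effective size (the geometric mean), averaging a normal and a gamma
   approximation of the NB quantile function, with per-group fragment means
   from a one-group NB fit. The exact conditional test below requires
   exchangeable library sizes; this step provides them.
4. **Common dispersion** by conditional maximum likelihood on the
   pseudo-counts: the likelihood of within-group counts conditional on
   their sum depends only on $\phi$, and the summed conditional
   log-likelihood is maximized over $\phi \in [10^{-6}, 10]$ on the log
   scale. One round of alternation is used — equalize at a small starting
   dispersion (0.01), estimate, re-equalize at the estimate, re-estimate —
   and then the procedure stops, so behavior is bounded and deterministic.
5. **Tagwise dispersions** by weighted-likelihood empirical Bayes: each
   fragment maximizes $\ell_g(\phi) + W\,\bar\ell(\phi)$, where
   $\bar\ell$ is the mean conditional log-likelihood over all fragments and
   $W = \mathrm{prior\_df} / \mathrm{residual\_df}$ with prior_df = 10 and
   residual df $\sum_k (n_k - 1)$. $W \to \infty$ collapses every fragment
   onto the common maximizer; $W = 0$ gives per-fragment ML. Profiles are
   evaluated on a 64-point log grid with a quadratic refinement around the
   maximum.
6. **Exact test**: conditional on a fragment's total pseudo-count $Z$, the
   class-A sum follows a beta-binomial law with shapes $n_A/\phi$ and
   $n_B/\phi$ (both class sums are NB with a shared success probability
   under the null). The two-sided p-value sums the probabilities of all
   outcomes no more likely than the observed one. The implementation
   locates the two tails of that rejection region by binary search around
   the mode (the pmf is log-concave) and sums them inward by ratio
   recursion, so cost is proportional to the tail widths rather than to
   $Z$; unit tests pin it to brute-force enumeration at $10^{-12}$.
7. **BH adjustment** per contrast, never pooled across contrasts.

Reported per fragment: `logFC` = log2 of class-B over class-A mean
pseudo-counts with a prior of 0.5 per class mean (so zero counts stay
finite), `logCPM` = log2 mean CPM with prior 0.25, `pvalue`, `fdr`. Class A
is *wild* and class B is *ins*, so positive logFC means higher expression
in heterozygotes; `positive_class = "wild"` flips the displayed sign for
figures drawn in the opposite orientation.

The genotype contrast uses ambient-treatment libraries only by default —
it is the constitutive-expression comparison — with `treatment =
"elevated"` or `"both"` available. The temperature contrast runs within one
genotype, ambient versus elevated, as an exact test or, with `paired =
TRUE`, as a likelihood-ratio test in the NB log-linear model
$\log \mu = \log(\text{effective size}) + \text{individual} +
\text{treatment}$, fitted by IRLS at fixed tagwise dispersion and compared
against the individual-only null on one degree of freedom. The IRLS fit is
unit-tested against a fixed-theta NB GLM fit and calibrates to nominal
type-I error in null simulation.

## Permutation robustness of the partition

The DE-count statistic — the number of fragments with FDR below a
threshold, default 0.01 — scores any two-class partition of the libraries
by re-running the *entire* chain above (normalization and dispersions are
recomputed for every partition, never frozen from the observed one).

* The **sorted** test enumerates all near-observed reassignments: each
  single library moved to the other class (`move1`, $n_A + n_B$ of them,
  which makes the class sizes 6-vs-4 — the statistic supports unequal
  sizes), every reciprocal single swap (`swap1`, $n_A n_B$), and every
  reciprocal double swap (`swap2`, $\binom{n_A}{2}\binom{n_B}{2}$): 135
  partitions for the 5-vs-5 design.
* The **unsorted** test draws K random equal-size splits (default 500)
  with a run seed.

The observed statistic's percentile counts permutations with *strictly*
fewer DE fragments; ties count as non-exceeding. That convention makes
"exceeding" partitions exactly the ones with more signal than the truth,
and the union of their moved libraries is the influence diagnostic: a
library that appears in every exceeding partition is expressing like the
other class. A `ties = "midpoint"` variant is exposed because the
convention is a genuine choice.

One calibration subtlety: under a null simulation the DE-count statistic
is almost always zero, so the strictly-less percentile is degenerate at
zero and cannot be uniform. The calibration diagnostics therefore use the
randomized probability integral transform
$(\#\{x < x_0\} + U(\#\{x = x_0\} + 1))/(K+1)$ (`pit_randomized()`), which
is exactly uniform for any discrete statistic when the observed partition
is exchangeable with the permuted ones. The reported percentile keeps the
strict convention.

Complementing the permutations, `influence_analysis()` re-runs the
genotype contrast with one library excluded, or with its individual's
genotype label flipped (labels are constant within an individual). For a
library that truly carries the other class's expression profile, exclusion
raises the DE count — the outlier was inflating within-class variance — and
reassignment raises it at least as much, since the information is retained
on the correct side.

## The synthetic-data generator

`simulate_experiment()` emulates the study design, not any particular
dataset: 5 + 5 individuals, paired ambient/elevated libraries, NB counts.
Defaults, chosen once:

* **Depth**: expected library size $= 250 \times G$ (lognormal, sdlog
  0.25), i.e. a mean per-fragment depth near 250. A NextSeq run of this
  design yields roughly $2\times 10^7$ read pairs per library over
  $\sim 10^5$ expressed regions, and the simulated fragment set stands for
  the post-filter analysis set, which is deeper than the average region.
* **Abundance**: lognormal relative abundance, sdlog 1.2.
* **Dispersion**: $\phi_0 = 0.2$ (biological CV ≈ 0.45, typical of
  outbred wild-caught animals) with mild tagwise spread (sdlog 0.1). At
  this spread the weighted-likelihood shrinkage is calibrated: null
  simulations at FDR < 0.01 stay at (approximately) zero discoveries.
  Stronger heterogeneity is exercised explicitly where the tagwise
  estimator is under test.
* **Genotype effect**: fraction $\pi_{DE} = 0.02$ of fragments affected,
  $|\mathrm{log_2FC}| = 2$, with $\rho = 0.85$ of the affected fragments
  *lower* in heterozygotes — the direction asymmetry the analysis is meant
  to recover. The multiplier is applied to the *ins* class, wild being the
  reference.
* **Temperature response**: 46 responsive fragments in wild, 6 in ins,
  half of the ins responders shared with the wild set; log2FC drawn from
  $N(-0.5, 1.9)$ in wild and $N(+0.3, 1.9)$ in ins. The means encode the
  opposite average directions of the two classes' responses, the spread
  the across-loci variability of reported significant responders.
* **Outlier**: with `outlier_library = TRUE`, one wild individual's
  genotype-affected fragments are drawn with the *ins* means in both of
  its libraries — a recombinant-like animal whose marker genotype
  contradicts its expression profile. Its strength follows the planted
  effect size, which is a free parameter; nothing in the emulated study
  quantifies it.
* **Individual random effects** default to zero: the NB dispersion already
  carries the between-individual biological variation. A per-individual,
  per-fragment lognormal effect (`individual_log_sd`) is available to
  induce within-pair correlation when probing the paired analysis.

A single seed expands into per-stage substreams (sizes, abundances,
dispersions, effects, outlier choice, counts), so any stage is reproducible
in isolation. What the generator does **not** emulate: read-level error,
positional/GC bias, assembly artifacts, isoform-level ambiguity,
composition shifts large enough to stress TMM, or correlated fragment
modules. Tests passing on this generator show the pipeline recovers what
it is designed to recover under its own model assumptions; they do not
certify behavior on real libraries, where those unmodeled features are the
interesting failure modes.

`simulate_righting()` mirrors the behavioral assay: three periods (ambient,
elevated, ambient again), three replicate trials each, lognormal individual
(sd 0.3) and replicate (sd 0.15) noise, wild times `ratio` (default 1.8)
times the ins times, a 25% slowdown during the elevated period, and a 1%
per-trial chance of an unresponsive (> 3600 s) trial to exercise the
one-hour exclusion rule. At these settings the Welch t-test on 5 + 5
individuals rejects at $\alpha = 0.05$ in roughly two-thirds to
three-quarters of seeds — consistent with an assay that was reported
significant in a complete 5 + 5 comparison but noisy in larger samples.

## Aggregation levels

Transcript-level counts collapse by summation (never averaging) to Trinity
cluster, gene, or homology level. Homology collapse keys annotated rows by
their shared homology id and *keeps unannotated rows under their gene id*,
so the row count shrinks only among annotated genes. Column totals are
conserved at every level, collapse is idempotent at its own level, and row
counts are monotone non-increasing along transcript → gene → homology.

## Numerical choices and degenerate inputs

* Dispersion search bounds $[10^{-6}, 10]$; Poisson-like data land on the
  lower boundary region rather than at zero.
* Fragments with total pseudo-count zero get $p = 1$ and logFC 0.
* The exact-test tie comparison is evaluated through the same `dnbinom`
  code path on both sides, so exactly tied outcome probabilities (the
  symmetric outcome under equal class sizes) fall inside the rejection
  region and the balanced observation yields $p = 1$ exactly.
* `q2qnbinom` adds 0.25 to zero means, as the quantile mapping is
  undefined at zero.
* Non-converged IRLS fits are flagged and reported at $p = 1$ rather than
  dropped.
* BH is computed on all filtered fragments of the contrast at hand.
* Righting-time sd over a single trial is reported missing, not zero.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run entirely on the
generator. Monte-Carlo sections use: 200 random small instances for the
enumeration oracle; 50 seeds at $G = 2000$ for null calibration (10 random
repartitions per seed for the PIT); 20 seeds at $G = 500$, $\pi_{DE} =
0.04$ for the sorted-permutation outlier diagnostics; 20 seeds at defaults
for direction-asymmetry recovery; and 20 seeds for dispersion-shrinkage
MSE at $G = 400$. These sizes give stable Monte-Carlo estimates for every
property while keeping a full run in a few minutes on one core.

## Known limitations

* The exact test conditions on equalized pseudo-counts; with severe
  library-size imbalance the quantile adjustment is an approximation, and
  the paired LRT (which uses offsets, not pseudo-counts) is the better
  tool.
* Tagwise shrinkage uses a global shared likelihood, not an
  abundance-trend; fragments whose dispersion co-varies with abundance are
  shrunk toward a single center.
* The permutation tests re-run the full chain per partition by design;
  cost grows linearly in the number of partitions.
* `genotype_permutation()` covers the behavioral genotype effect
  distribution-free; a mixed-effects decomposition of period and genotype
  is out of scope.
* With 5 + 5 individuals the smallest attainable two-sided permutation
  p-value is $2/\binom{10}{5} \approx 0.008$; exact-test p-values below
  that rest on the NB model, not on randomization.
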