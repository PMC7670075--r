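---
title: "Dissecting eQTL micro-architecture with RIL and IL panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting eQTL micro-architecture with RIL and IL panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlmicro)
```

## The problem

An expression QTL (eQTL) mapped in a recombinant inbred line (RIL) panel is a
statistical association between a marker and a transcript. Whether the
underlying signal is one causal variant or several closely linked variants —
the *micro-architecture* of the locus — cannot be resolved by the mapping
population itself when the linked variants rarely separate by recombination.
Two population designs from the *C. elegans* N2 × CB4856 cross expose the
difference:

* **RILs** are homozygous mosaics of the two parental genomes. Each QTL
  segregates in roughly half of the panel, so additive QTL contribute their
  full variance.
* **ILs** (introgression lines) each carry a single CB4856 segment in an
  otherwise N2 background. A QTL affects only the few strains whose segment
  covers it — but an IL breakpoint that falls *inside* a cluster of
  closely linked QTL separates variants that never separate in the parents
  or in most RILs.

A cluster whose effects cancel within each parental haplotype ("balanced"
closely linked QTL) is invisible in the parents and in intact mosaics, yet
produces strong expression differences in exactly those strains whose
breakpoint splits it. This is cryptic genetic variation, and the
trait-variance contrast between the two panels is diagnostic for it.

## Estimators

**Broad-sense heritability.** For each spot (transcript probe), per panel
and environment,

$$H^2 = \frac{\sigma^2_F - \sigma^2_P}{\sigma^2_F},$$

where $\sigma^2_F$ is the trait variance across the panel strains and
$\sigma^2_P$ is the df-weighted pooled variance of the two parental
replicate groups, used as the measurement-error estimate. Pooling
*within-parent* variances keeps the parental mean difference out of the
error term (`broad_sense_heritability()`; a concatenated-sample variant is
deliberately not offered because it conflates genetic signal with error).
Negative estimates are flagged and excluded, never clamped. Significance
uses a per-spot permutation threshold: expression values are shuffled over
the strains (panel together with the parental replicates), $H^2$
recomputed, and the 95th percentile of (by default 1000) permuted values
taken as the cutoff. Following the source protocol's naming this per-spot
empirical $\alpha$ is labelled an FDR = 0.05 threshold, although it is not
a false-discovery rate in the Benjamini–Hochberg sense. Whether the
parental groups re-enter the permuted error term is controlled by
`shuffle_parents`; the default full shuffle is conservative (planted
$H^2 = 0.9$ traits at 48 strains are detected in about 90% of cases, as
the test suite measures), because permutation leaks genetic variance into
the permuted error term.

**Relative heritability.** $R_H = \log_2(\sigma^2_{IL} / \sigma^2_{RIL})$
per spot, assuming equal measurement error in both panels. Additive
architectures give negative $R_H$ (ILs segregate fewer QTL); balanced
closely linked clusters spread $R_H$ in both directions, including positive
values when a breakpoint exposes a cluster in the ILs only. The
Fligner–Killeen test (with BH correction across spots) flags spots whose
variances genuinely differ.

## eQTL mapping and confirmation

Mapping is the single-marker model: per spot and marker a pooled-variance
t-test of log2 expression by allele, peak at the maximum $-\log_{10}(p)$,
records kept above 3.9, and a confidence interval from a 1.5 drop in
$-\log_{10}(p)$ (used here as the LOD approximation). *cis* means the gene
lies within 1 Mb of the peak or inside the confidence interval.

Because each RIL/IL is measured once per environment, per-strain
differential expression is estimated from z-scores against the
genetic-background parent, with two modes: BH at FDR 0.05 for confirmation
counts, and a fixed $p < 10^{-5}$ cutoff for DEG counting. A caveat the
package's tests quantify: with 3–4 parental replicates the z-score
denominator has ~3 degrees of freedom, so the nominal normal cutoff
$|Z| > 4.42$ is exceeded by roughly 3% of null spots. This inflates
observed DEG counts relative to eQTL-based expectations by a constant
factor regardless of panel size; the expected-versus-observed comparison
should therefore be read against a same-protocol null, which the test
suite constructs (with enlarged parental replication the observed/expected
fold is ≈ 1 on additive data).

Trans-band confirmation correlates a band's member-eQTL effects with each
candidate IL's log2 ratios; the threshold is the strongest correlation seen
among the N2 samples themselves, and only positive exceedances count. With
$k$ N2 samples a null IL exceeds the max-of-$k$ threshold with probability
about $1/(k+1)$; at the design's 3–4 parental replicates the intrinsic
false-positive rate of the procedure is therefore ~0.2, which the
off-band ILs in the test suite reproduce.

## The synthetic-data generator

`simulate_ril_genotypes()` builds each RIL as one meiosis per chromosome —
Poisson($\lambda$) crossovers placed uniformly, alternating phase from a
random start — then forces homozygosity. This is a shortcut for selfing to
fixation: downstream statistics depend only on the mosaic structure, not
pedigree fidelity. The default $\lambda = 1.5$ breakpoints per chromosome
emulates the breakpoint density of selfed *C. elegans* RIL panels.
`simulate_il_genotypes()` tiles each chromosome with consecutive cores
extended by random overlaps (mean 5 markers per side), giving 57 single-
segment strains whose per-marker coverage has mean ≈ 2 and 5–95% quantiles
within 0–5, matching the published panel's coverage; unlike the real panel,
the tiling guarantees every marker is covered at least once. The default
map is 6 chromosomes × 100 uniformly spaced markers over 16 Mb.

Expression is generated on the log2 scale around a baseline of 10 and
exponentiated, so the log2-ratio transform recovers planted effects
exactly. Parental replicates (defaults 4/4/3 for N2 and 3/3/5 for CB4856
across control, heat-stress and recovery) share the environment's noise
model and are reused by both panels. What the generator does *not*
emulate: array normalization artefacts, dye bias, probe-level effects,
environment-specific genetic architectures, or genuine biological
covariance between spots — passing tests show the statistical machinery is
correct under the stated variance model, not that real microarray data
meet that model.

## Architecture simulation

`rh_distribution()` simulates eight architectures: additive QTL, additive
QTL active in one genotype only, clusters of closely linked QTL (random,
one-genotype, balanced, balanced one-genotype), and interacting QTL
(random or clustered). Effects are N(0, 1); QTL are placed on informative
markers with arm-enriched weights (arm : center : tip = 4 : 1 : 1 by
default; the tip/arm/center boundaries are configurable fractions, default
10/30/20% mirrored per chromosome, since no bp boundaries are canonical).
Clusters occupy 2–5 consecutive markers so they separate only when a
recombination breakpoint falls inside. Balanced clusters are re-centred to
an exact zero sum ("pairwise" sign-flipped balancing is available). The
epistatic form for interacting models is the pairwise product of ±1
codings — the minimal two-locus interaction; this is a modelling choice,
not a canonical definition.

**Noise calibration.** Residual noise is calibrated so the heritability
$\sigma^2_G / (\sigma^2_G + \sigma^2_e)$ of each simulated trait equals
0.85 on the RIL panel (`calibration = "per_trait"`, the default;
`"per_batch"` solves one $\sigma_e$ per architecture so the batch mean
hits the target). Traits whose RIL genetic variance is numerically zero —
balanced clusters that no RIL breakpoint splits — cannot be calibrated.
The package *retains* them by default, assigning the batch-median residual
sd, because they are precisely the cryptic-variation traits the contrast
exists to expose (they produce the positive $R_H$ tail when an IL
breakpoint splits the cluster); `zero_variance = "skip"` drops and counts
them instead. A numerical guard treats genetic variances below
$10^{-18} \sum e_k^2$ as zero, absorbing the ~$10^{-16}$ rounding residue
of intact zero-sum clusters in the matrix products.

The per-trait calibration has one structural consequence worth stating
plainly: it inserts noise proportional to the RIL genetic variance into
*both* panels, which bounds $\log_2$ variance ratios below at roughly
$\log_2(0.15) \approx -2.7$ plus sampling spread. Published analyses of
this design report additive intervals reaching −3.6 and balanced intervals
reaching −24.9; those extremes require residual noise far below the stated
calibration and a map on which clusters essentially never recombine in
either panel, conditions the generator's defaults do not reproduce. The
acceptance material reports what the implementation actually computes
rather than tuning toward the published bounds.

## Deconvolution

`deconvolve_rh()` counts observed heritable traits in two open intervals —
the additive peak $(-3, -2)$ and the intersect $(0.5, 1.5)$ — forms
expected counts for the additive and balanced models as the *median*
per-replicate interval probability across the simulated grid (1–100 loci,
cluster sizes 2–5) scaled to the number of heritable traits, and solves
the 2×2 linear system exactly. Open intervals are a documented convention
(boundary values count in neither; `closed = TRUE` is available). Negative
solutions are reported, flagged invalid and excluded from fractions, and
ill-conditioned systems (condition number above $10^8$) are refused with
the condition number.

On the default map the two distributions are distinguishable in these
intervals only for small-to-moderate QTL counts: above ~20 clusters the
balanced model self-averages (many splits per strain) and its intersect
mass vanishes, so the median over the full 1–100 grid is near zero for
both models and the system approaches singularity. Mixture recovery is
therefore demonstrated on grids restricted to the distinguishable regime
(see `test-deconvolution.R`), and the full-grid protocol is exercised —
and honestly fails — in the acceptance tests.

## Numerical and design choices

* Allele coding: categorical N2/CB4856 at interfaces, −1/+1 internally;
  the symmetric coding keeps additive values mean-centred at frequency
  0.5. One-genotype effects use the 0/1 CB4856 indicator; the choice of
  CB4856 as the active allele is arbitrary and symmetric under
  relabelling.
* Coordinates are 1-based bp with closed intervals; overlap is any shared
  bp. Heterozygous calls are rejected, not imputed — both panels are
  inbred by construction.
* The mapper centres expression per spot before computing group variances,
  which keeps the pooled variance accurate on near-noiseless data.
  Degenerate spots (zero pooled variance) get $p = 1$ when group means are
  equal, $p \to 0$ otherwise.
* Sample (n−1) standard deviations throughout; parental pooling is
  df-weighted.
* Permutations, panels and expression are all driven by explicit seeds;
  the pipeline derives per-stage substreams from a single root seed, so
  identical configurations give byte-identical outputs.
* Desk-scale problem sizes used by the shipped tests: grids of 2000
  replicates per architecture combination, $10^4$ spots × 200 permutations
  for the threshold calibration check, and 40–200 permutations in the
  pipeline smoke tests. The published protocol's 33331 replicates and 1000
  permutations are configuration choices away (`replicates =`, `n_perm =`).

## A small worked run

```{r, eval = FALSE}
map <- default_genetic_map()
ril <- simulate_ril_genotypes(map, 48, seed = 1)
il  <- simulate_il_genotypes(map, 57, seed = 2)

sim <- rh_distribution(map, ril, il, models = c(1, 5),
                       n_loci = c(1, 2, 5, 10), cluster_sizes = 2:3,
                       replicates = 500, seed = 3)
rh_summary(sim, pooled = FALSE)

cfg <- run_config(out_dir = tempfile("qtlmicro_run"), seed = 7)
report <- run_full_analysis(cfg)
```

## Limitations

* The generator's IL tiling guarantees full coverage; real panels have
  gaps, which shifts the additive $R_H$ interval downward relative to a
  gapped panel.
* Interaction architectures use the pairwise-product form only.
* No narrow-sense heritability or mixed-model variance components; no
  multi-marker or interval mapping; FDR calibration of the 3.9 mapping
  threshold is taken as given, not re-derived.
* The deconvolution is exactly the two-interval linear solve — no
  likelihood-based mixture fitting and no more than two components.
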