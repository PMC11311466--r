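---
title: "Perturbation profiles and combinatorial barcodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation profiles and combinatorial barcodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peepbarcode)
library(dplyr)
```

## The problem

Human mast cells cultured from different blood donors release very
different fractions of their histamine when their IgE receptors are
cross-linked: across a healthy cohort the percent release is unimodal but
wide. `peepbarcode` implements a pipeline for asking whether a small panel
of genes, measured by qPCR in the *unstimulated* cultures, carries a
genomic signature of that functional responsiveness. The pipeline has four
statistical stages, each deliberately simple and each exposed as a
pipe-friendly function over tibbles:

1. **Responder stratification.** The cohort mean $m$ and sample SD $s$ of
   percent histamine release define two cutoffs, $m \pm s$. A donor
   releasing strictly more than $m + s$ is a *High* responder, strictly
   less than $m - s$ a *Low* responder, everyone else *Average* ("Ave").
   Boundary values fall to Average because the High/Low definitions are
   strict inequalities. The SD uses the $n-1$ denominator, the
   conventional estimator for cohort statistics. Fitting
   (`fit_release_stats()`) is separate from classification
   (`classify_responder()`), so a baseline fitted on one cohort can
   classify samples from another — that is how external patient-derived
   cultures are referenced against a normal-donor baseline.

2. **qPCR normalization.** Transcript quantities come off the instrument
   per plate; plate-to-plate drift is removed by a reference cDNA control
   run on every plate. For a sample $s$ on plate $p$, with target-gene
   quantity $Q_s$ and GAPDH quantity $G_s$, and plate controls $Q_c$,
   $G_c$:

   $$\text{level} = \frac{Q_s / NF_q}{G_s / NF_g}, \qquad
     NF_q = \frac{Q_c}{\overline{Q_c}}, \quad
     NF_g = \frac{G_c}{\overline{G_c}},$$

   where the averages run over plates, per target gene. The level is then
   $\log_2$-transformed, so expression above the reference is positive and
   below is negative. Because every correction is a ratio to a cross-plate
   mean, any *multiplicative* plate effect cancels exactly — that is the
   design assumption under which this normalization is complete, and the
   synthetic generator (below) makes plate effects multiplicative for
   precisely that reason. Ct-level input is supported through standard
   curves (`fit_standard_curve()`, `ct_to_quantity()`: least squares of Ct
   on $\log_{10}$ quantity), but quantities are the canonical internal
   representation. Zero or negative quantities are an error, never
   imputed: no limit-of-detection rule is part of the model.

3. **Personalized perturbation profiles (PEEP).** Instead of comparing
   group means, each donor is compared to the *control range*: per gene,
   the mean $M$ and sample SD $S$ of the $\log_2$ levels over the combined
   Average + Low donors define a normal range $[M - S,\, M + S]$. A
   donor's level strictly above it is called "Up", strictly below "Down",
   otherwise "Norm"; "perturbed" means Up or Down. Ties at a cutoff
   resolve to Norm (the definitions are strict). High responders never
   contribute to the control range. Under a normal null the expected
   perturbed fraction among controls is $2(1 - \Phi(1)) \approx 31.7\%$,
   which the test suite verifies by simulation; the calls are invariant to
   adding any constant to one gene's levels (controls refit), so per-gene
   scale conventions do not matter.

4. **Combinatorial barcodes.** The per-gene calls of a signature panel
   (default: the four up-regulated genes NELL2, ITM2C, AKAP12, IL13RA1)
   are collapsed into a count composition $(u, n, d)$ written `"uUnNdD"`.
   For a panel of $k$ genes there are $\binom{k+2}{2}$ such patterns —
   15 for $k = 4$, 45 for $k = 8$ — which `enumerate_patterns()` lists
   and the tests cross-check against a brute-force $3^k$ collapse.
   Patterns map to categories by a rule induced from the 4-gene reference
   table and valid for any panel size: $u \ge 1, d = 0 \Rightarrow$
   "$u$-Up"; $u = d = 1 \Rightarrow$ "1-Up-1-Down"; everything else
   "Others". Category frequencies per responder group
   (`category_frequencies()`) are the final readout: a "4-Up" barcode
   concentrated in High responders is the signature of interest.

A simplified marker screen (`screen_genes()`) is included for pipeline
completeness: signed linear fold change ($2^{\Delta \overline{\log_2}}$,
folded to $-1/r$ below 1) plus a two-sided Welch $t$-test on the $\log_2$
levels, selection at unadjusted $p < 0.05$ and $|FC| > 1.2$ with strict
inequalities. This deliberately replaces the original microarray
mixed-model ANOVA, whose raw data and factor structure are not available;
the screen is a surrogate for exercising the pipeline on synthetic data,
not a replication of any published gene list.

## What the synthetic generator emulates

The donor-level data behind the reference analysis are not public, so the
package ships a first-class generator (`simulate_cohort()`) that produces
cohorts with the statistical structure the analysis assumes:

* **Release.** A normal distribution truncated to $[0, 100]$, drawn by
  inverse CDF, with parent parameters mean 24.1% and SD 15.1%. Truncation
  is the simplest way to keep a unimodal shape while respecting the
  physical range; note that the left truncation at 0 makes the *realized*
  moments of the truncated law roughly 25.9% / 13.5%, and the tests check
  against those analytic truncated moments, not the parent parameters.
* **Labels.** The cohort is stratified by the same mean ± SD rule the
  analysis uses, refit on the simulated cohort.
* **Expression.** Per donor and gene:
  $\text{baseline} + \text{shift} \cdot \mathbb{1}[\text{High}] +
  \mathcal{N}(0, \sigma)$. The default panel is the eight signature genes
  with signs matching their reported direction (six up in High, two
  down). No effect sizes are published, so the defaults — baseline 0,
  $|\text{shift}| = 1$ $\log_2$ unit, $\sigma = 0.5$ — were fixed once as
  a realistic strong qPCR signature (a two-fold change at two noise SDs of
  separation).
* **Plates.** Donors are assigned round-robin to plates (3 by default);
  control quantities $Q_c$ (per plate × gene) and $G_c$ (per plate) are
  log-normal with log-scale SD `plate_factor_sd` (0.25 by default), donor
  GAPDH log-normal around 10. $Q_s$ is then *solved* from the
  normalization equation so that normalizing the emitted table returns
  the generating $\log_2$ levels to within $10^{-9}$ — a round-trip
  oracle that pins the normalization code independently of any example.
  Triplicates are not modelled: the equation consumes triplicate means,
  so means are what the generator emits. One sample per donor.

The default cohort size is 94 donors, the size of the reference qPCR
cohort. Everything is seed-deterministic bit for bit.

What passing tests on this generator do **not** show: real qPCR data have
amplification-efficiency differences, within-triplicate variance,
detection limits, and non-normal, possibly correlated expression across
genes; real plate effects need not be purely multiplicative (additive
background would *not* cancel). Results on synthetic cohorts validate the
arithmetic and the logic, not the biology.

## Numerical and design choices

* **Rounding.** Printed percentage tables use half-up rounding (14/17 →
  82.4%), so the package implements half-up explicitly rather than using
  `round()`'s round-half-even. Frequency tables carry exact fractions
  alongside nearest-integer percentages.
* **"Average of all $Q_c$"** is read as the unweighted mean over plates
  within a target gene — each plate contributes one control value. With a
  single plate both factors are 1.
* **Rescaling one plate** (samples and controls together, each channel by
  its own constant) multiplies that gene's levels by one common factor —
  the plate's control moves the cross-plate mean — so absolute levels are
  identifiable only up to a per-gene constant under plate rescaling.
  Donor-to-donor ratios, and therefore all PEEP calls, are exactly
  invariant, which is the invariance that matters downstream.
* **Degenerate inputs.** Zero-variance release cohorts give equal cutoffs
  and classify everyone Average; zero-variance control genes give a
  zero-width normal range (only exact equality is Norm); a zero-variance
  gene in the screen gets $p = 1$ when the group means agree and $p = 0$
  when they differ. Empty cohorts flow through as empty tibbles.
* **Category rule as a rule, not a table.** The 15-row reference mapping
  is reproduced exactly by the induced rule at $k = 4$ (tested
  row-for-row), and the same rule scales to any panel size.
* **Provenance without timestamps.** The run report records seed, package
  version and a config hash, but no wall-clock time, so identical
  config + seed yields byte-identical outputs.

## Problem sizes

The test suite runs cohorts of up to 10,000 donors for the Monte-Carlo
null checks (perturbation rate, screen false-positive rate), 1,000 genes
for the screen calibration, and 94-donor cohorts for end-to-end runs;
the full suite completes in well under a minute. These sizes were chosen
so Monte-Carlo standard errors are a few tenths of a percent, tight
enough to detect an implementation error of one donor or one call.

## Worked example

```{r example}
report <- run_pipeline(list(n_donors = 94, seed = 1, quiet = TRUE))
report$group_counts
report$category_frequencies |> filter(count > 0)
```

## Known limitations

* The screen is a two-group Welch test; it does not model batch, culture
  or array factors and will not reproduce any published differential
  gene list.
* The PEEP threshold is fixed at ±1 control SD; no multi-SD or quantile
  variant is provided, and no significance test is attached to group
  differences in perturbation rates.
* Panel selection is manual; the package does not search for optimal
  gene subsets.
* The generator draws genes independently; correlated expression
  modules, which would change barcode-category null frequencies, are out
  of scope.
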