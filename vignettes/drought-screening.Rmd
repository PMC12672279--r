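---
title: "Methods: seedling-stage drought screening of genotype panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seedling-stage drought screening of genotype panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtscreen)
```

## The screening problem

Seedling-stage drought screens expose a panel of genotypes to graded
osmotic stress — here three PEG 6000 regimes, `T0` (0 %, control), `T1`
(10 % w/v) and `T2` (20 % w/v) — in a completely randomized design with a
fixed number of replicates, and record growth, root and biochemical traits
(germination time, leaf and secondary-root counts, shoot/root lengths,
fresh and dry biomass, survival rate, photosynthetic pigments, proline,
and the oxidative markers MDA and H2O2 under the two extreme regimes
only).  The analysis questions are always the same: which traits respond
to stress, how trait coupling changes with stress intensity, and which
genotypes tolerate stress — answered here by factorial ANOVA with Tukey
treatment comparison, per-treatment correlation matrices, a cumulative
mean ± SD efficiency score, seven dry-weight tolerance indices with a
composite score, and a PCA of the index matrix.

`droughtscreen` implements that pipeline on a long-format
genotype × treatment × replicate trait table, plus two supporting pieces:
a calibrated synthetic-cohort generator (no replicate-level data is
distributed with screens of this kind, only summary tables) and an
algebraic auditor for published index tables.

## Derived traits and descriptive layer

The root-to-shoot ratio is computed per replicate as `RL / SL` and only
then averaged.  The two orders of aggregation differ: with the packaged
summary table, the ratio of treatment means under control is
`6.14 / 8.27 = 0.7424` while the published per-genotype aggregation
prints 0.75 — which is why per-replicate derivation is the default and
ratio-of-means is not offered as a silent alternative.

Pigments follow the standard acetone-extract equations
(`Chla = 12.25 A663.2 − 2.79 A646.8`, `Chlb = 21.21 A646.8 − 5.1 A663.2`,
`ChlT = Chla + Chlb`,
`CAR = (1000 A470 − 1.82 Chla − 85.02 Chlb)/198`).  Negative results are
returned but flagged: they indicate readings outside the equations'
calibration range, and silently clipping them would hide assay problems.

Summaries use the sample SD (n − 1); a population-SD flag exists.  The CV
is `100·sd/mean` and is undefined (NA, with a warning) at zero mean.
Percent changes are signed (`100·(after − before)/before`); when auditing
printed claims against rounded summary means, deviations up to about half
a percentage point must be tolerated because published percentages are
computed from unrounded means.

One packaged descriptive row (shoot length under control) prints a
minimum above its maximum; the fixture keeps the row verbatim with a
`suspect` flag rather than correcting data it cannot verify.

## The synthetic cohort

The generator's defaults are the study conditions: 37 genotypes × 3
treatments × 3 replicates, calibrated to the packaged per-trait,
per-treatment means and SDs.  Each observation is

\[ y_{gtr} = \mu_{t} + \sigma_t\,(\sqrt{f_G}\,u_g + \sqrt{f_{GT}}\,w_{gt}
   + \sqrt{f_E}\,e_{gtr}) \]

with independent standard-normal draws and a variance partition
\(f_G + f_{GT} + f_E = 1\), default (0.4, 0.2, 0.4).  The partition is a
declared assumption — summary tables carry no replicate-level variance
decomposition — loosely motivated by the relative magnitudes of the
genotype, interaction and error mean squares in published variance
tables, and fully user-configurable.  A two-moment Gaussian model with
family post-processing was chosen over trait-specific GLMs because the
calibration targets supply only a mean and an SD per cell; anything
richer would be invented structure.

Three deliberate design points:

* **Genotype main effects under heteroscedastic treatments.**  The target
  SDs differ per treatment, so a strictly additive genotype effect cannot
  reproduce all three marginal SDs.  The generator draws one standardized
  genotype deviate per genotype and scales it by each treatment's target
  SD: genotype effects are perfectly correlated across treatments
  (a true main effect in rank terms) while every trait × treatment cell
  hits its target mean and SD exactly in expectation.
* **Cross-trait correlation.**  Growth and root traits are strongly
  positively coupled among genotypes under control conditions; the
  generator gives the designated trait set (default
  NOL, SL, TFW, TDW, SR, NSR, RL, RFW, target 0.7) a common factor in
  *every* variance component, so the realized correlation of genotype
  means equals the target.  Correlating only the genotype component would
  attenuate the realized correlation to about half the target under the
  default partition.  The cost is that the correlation persists under
  stress, whereas real screens show it collapsing and reversing at severe
  stress — the generator does not emulate that reversal (archetype
  injection, below, is what creates treatment-dependent structure).
* **Family constraints.**  Counts are rounded to non-negative integers,
  proportions clipped to [0, 1], and positive continuous traits truncated
  at zero by resampling the residual draw (clipping would put a point
  mass at zero).  Resampling biases the realized mean upward for
  high-CV cells — the root-fresh-weight cell under severe stress (CV
  120 %) is the worst case — and this is accepted and documented rather
  than corrected, because the bias is a property of honest truncation.
  The ratio trait is derived from the generated lengths, so its marginal
  moments are implied, not calibrated.

`inject_archetypes()` shifts the stress-treatment target means of chosen
genotypes by a given number of target SDs, favourably for "tolerant" IDs
(direction set by each trait's biological polarity) and unfavourably for
"susceptible" IDs, leaving control untouched.  This provides ground truth
for recovery experiments.

A seed is mandatory; the same configuration and seed give a bit-identical
table.

### What recovery simulations can and cannot show

With the default configuration and a 2 SD archetype shift, the injected
tolerant genotypes do *not* reliably occupy the top four overall
efficiency scores (recovery is roughly 40 % of seeds).  The cause is the
default cross-trait correlation: the shared genotype factor creates
"naturally superior" genotypes whose advantage spans all treatments and
all correlated traits, and it reduces the effective number of independent
scored traits, so score totals are noisy.  With the correlation removed
the same experiment recovers the archetypes in the large majority of
seeds.
Ranking by the composite index score is weaker still: the composite's
susceptibility components (SSI rises as stress performance falls) largely
cancel its productivity components, making the plain-sum composite nearly
flat in stress dry weight at severe stress and actually favouring
susceptible genotypes at moderate stress.  Passing or failing these
simulations is therefore informative about the scoring schemes, not about
the generator; the package reports both honestly rather than tuning the
conditions until recovery looks clean.

## Inference

The ANOVA engine is balanced-only by construction: sources Genotypes,
Treatments, Replication (a crossed 2-df block, not nested in treatment),
Genotypes × Treatments, Error; `F = MS/MS_error`.  On balanced data
sequential and marginal sums of squares coincide, so refusal of
unbalanced tables (with a cell report) is safer than silently switching
SS types.  Traits measured under two treatments get a 1-df treatment
term; the full design gives df (36, 2, 2, 72, 220; total 332) and the
two-treatment design totals 221.  A constant response reports zero SS
and NA statistics.  p-values below 1e-16 print as "<1e-16".

Tukey comparisons use the studentized range with the ANOVA error mean
square on genotype × replicate values; the compact letter display is
assigned greedily from the largest mean, ties broken by descending mean
then label order.

Correlation matrices are computed on genotype means within treatment
(n = panel size) by default, since trait relationships are interpreted
among genotypes; replicate-level correlation is available behind a flag.
Zero-variance traits give flagged NA entries.  The trajectory summary
classifies each trait pair across treatments as strictly increasing,
strictly decreasing, or non-monotone (ties included, so identical
matrices are non-monotone with zero span).

## Efficiency scoring

Per trait × treatment, thresholds are the mean ± SD of genotype means;
strictly above the upper bound is Efficient (3), strictly below the
lower bound Inefficient (1), Medium (2) otherwise — boundary values are
Medium, following the strict inequalities of the rule.  Fifteen traits
are scored (the two-treatment oxidative markers are excluded), giving
totals out of 45 per treatment and 135 overall.

Two documented interpretation points:

* **Polarity.**  The published rule is literal — higher is always
  Efficient — even for germination delay, where more days are
  biologically worse.  The default is the literal rule, for fidelity; a
  `"biological"` mode swaps polarity for DSG, MDA and H2O2.
* **The per-treatment overall letter.**  Published score cards attach one
  E/M/I letter per treatment to each genotype without stating its rule.
  The package reconstructs it by applying the same mean ± SD rule to the
  distribution of treatment totals themselves; this is a documented
  assumption, not a printed definition.

Ranking is dense (ties share a rank) by overall total, ties displayed
alphabetically.

## Tolerance indices, the composite, and the auditor

For control and stress dry weights C and T and cohort means xC, xT (per
stress level, from the analyzed dry-weight trait):
SSI = (1 − T/C)/(1 − xT/xC); MPI = (C+T)/2; GMPI = √(CT);
HMI = 2CT/(C+T); STI = CT/xC²; TI = C − T; SI = T/C.  The composite STS
is the plain sum of the seven — that is what published composite columns
equal row by row; a z-score-summing "standardized" mode is provided and
labelled, since the accompanying text can be read either way.

GMPI has a second mode because published tables of this family sometimes
tabulate the plain product CT in the geometric-mean column despite
stating the square-root definition.  The packaged tables do exactly
that — the auditor finds the product matches every printed cell to
rounding precision while the square root misses by two orders of
magnitude — so `"formula"` is the default (the stated definition) and
`"as_published"` reproduces the tables.  The discrepancy is surfaced,
never silently reconciled, and neither convention is asserted as the
intended one.

The auditor inverts MPI and SI exactly (C = 2·MPI/(1+SI), T = SI·C),
recomputes all indices under both conventions, infers xC by least
squares from the STI column and xT from the SSI column, and flags cells
deviating beyond half a printed unit (0.0015 for 3-decimal columns,
slightly loosened for input rounding).  Two findings from the packaged
tables are worth knowing before using this tolerance on other tables:

* STI recomputed from 3-decimal MPI/SI inherits amplified rounding error
  (deviations up to ~0.005), so STI flags at the 0.0015 band are
  expected even in a perfectly consistent table.
* The packaged SSI column is not reproducible from the printed MPI and
  SI under any single (xC, xT) pair — deviations are orders of magnitude
  beyond rounding, and consequently the xT inferred from it does not
  match the published stress-mean dry weight.  The auditor reports this
  rather than repairing it; all conclusions driven by SSI (including the
  composite ranking) should be read with that caveat.

## PCA of the index matrix

Correlation-matrix PCA (explicit eigendecomposition, not SVD) is the
default: the seven indices span orders of magnitude, and with
standardization the eigenvalue-sum invariant (= number of variables) is
exact.  Covariance mode is retained for sensitivity analysis.  Component
signs are fixed so each component's largest-magnitude loading is
positive; contributions are squared-loading shares (each component sums
to 100 %).  Kaiser flags mark eigenvalues above one.  On the packaged
matrices PC1 carries ~71 % (moderate stress) / ~70 % (severe) and the
first two components ~97 %, with the mean-productivity index the top
PC1 contributor and the TI/SI pair dominating PC2.

## Orchestration and reproducibility

`run_pipeline()` drives all stages on one input (a CSV or a synthetic
configuration plus mandatory seed), writes every numeric output at full
precision exactly once, and records a manifest with per-stage status,
timing, warnings and file checksums; the report layer alone applies
2-3-decimal display rounding, so audits never compare doubly rounded
values.  Identical configuration and seed give byte-identical numeric
outputs.

## Problem sizes used in the test suite

Unit tests run on small constructed tables (3-12 genotypes) and the
default-size cohort (37 × 3 × 3).  Property checks use 10^4 random pairs
for the index inversion, ~10^4 draws per treatment for marginal
calibration (3-SE tolerance), 1000 genotypes for the correlation target
(±0.05), 100 random cohorts for scale invariance, and 200 seeds for
archetype-recovery rates.  These sizes were chosen so each property's
sampling error is well below its asserted tolerance.

## Known limitations

* The generator is a two-moment model: no skewness, no genotype-specific
  variance, no treatment-dependent correlation structure, no seed
  mortality; passing tests show the pipeline's arithmetic and the
  declared statistical structure, not realism of any particular screen.
* The literal efficiency rule scores unfavourable extremes of
  lower-is-better traits as Efficient; the biological mode changes
  totals and ranks, and neither is "correct" — they answer different
  questions.
* The composite index score inherits the cancellation structure
  described above; it should not be used as a tolerance ranking on its
  own, which the recovery simulations make quantitative.
* Survival rate is modelled as a continuous proportion per pot, not a
  binomial count; with small per-pot seed numbers a binomial model would
  differ.
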