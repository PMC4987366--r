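---
title: "Methods: QTL detection in introgression-line libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL detection in introgression-line libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilqtl)
```

## The design and its model

`ilqtl` analyzes genomic libraries of introgression lines (ILs): lines
that each carry one or a few homozygous donor-genome segments in a uniform
recurrent-parent background, with the segments jointly tiling the donor
genome. The reference design the package emulates is a 54-line
wild-tomato library grown at three Mediterranean locations in a
randomized complete block design (RCBD) with eight blocks per location,
one IL plot and six recurrent-parent ("control") plots per block. The
over-replication of the control is what gives the many-to-one comparisons
their power; the imbalance it creates is handled explicitly throughout
(least-squares means, Type III sums of squares, Searle's effective
replicate number).

The plot-level model behind every stage is additive Gaussian:

$$y_{ijk} = \mu + g_i + \ell_j + b_{k(j)} + (g\ell)_{ij} +
\varepsilon_{ijk}.$$

Everything downstream — variance partitioning, heritability, Dunnett
screening, contrasts — is a fixed-effects least-squares analysis of this
model or of its per-location restriction. Mixed models (random blocks),
REML components and spatial field models are deliberately out of scope.

## Trial statistics

**Variance partitioning** (`partition_variance`). Two-way ANOVA of
`value ~ genotype * location` on plot-level data. Because of the unequal
control replication the effect sums of squares are Type III (marginal,
sum-to-zero contrasts, as `car::Anova` computes them); percentages are
taken over the sum of the three effect SS plus the residual SS, so they
always total 100 together with the residual share. Whether published
"effect (%)" tables of this kind are SS fractions or variance-component
fractions is usually unstated; the SS convention is implemented and the
choice is recorded in the run metadata (`ss_type: III`). On balanced data
the decomposition is exact (tested to 1e-8 relative) and Type III
coincides with the sequential decomposition; for constructed degenerate
data with zero residual the sequential fallback is used, since the
marginal tests are undefined there.

**Heritability** (`heritability`). Broad-sense, within one location, from
the one-way genotype ANOVA: $V_g = \max(0, (MS_G - MS_e)/n_0)$ with
$n_0 = (N - \sum n_i^2/N)/(a-1)$, $V_t = V_g + MS_e$, $h^2 = V_g/V_t$.
The truncation at zero keeps $V_g$ a variance; the naive between-group
variance would confound replication with genetics. A block covariate can
be absorbed first (`block_adjust = TRUE`), but the default is the plain
one-way analysis. At 50 genotypes × 8 replicates the estimator recovers a
true $h^2 = 0.5$ to within ±0.05 on average over 200 simulated trials
(tested).

**Correlations** (`trait_correlations`). Pearson correlations among
traits are computed on genotype means within each location,
pairwise-complete, with the number of complete pairs recorded. Genotype
means (not plot values) match the genetic-correlation intent of such
tables; plot-level correlations would be diluted by residual noise.

## Color traits

Chroma $C^* = \sqrt{a^{*2} + b^{*2}}$ and hue angle
$H = (180/\pi)\arccos(a^*/C^*)$ in degrees are derived per plot from
measured CIELab $a^*$, $b^*$ records (`derive_color_traits`), separately
for the external and internal color families. The arccos form is defined
only for $b^* > 0$ (it cannot distinguish the lower half-plane): plots
with $b^* \le 0$ get an explicitly missing hue and their count is
attached to the result. The source formula for the hue conversion is
sometimes printed with a typographically mangled constant ("180/p"); it
is read here as $180/\pi$. Note that the chroma of trait *means* is not
the mean of plot chromas — a nonlinear function of means differs from the
mean of the function — so derived records are always computed at plot
level before any averaging.

## Dunnett screening

Per location and trait, `fit_location_model` fits
`value ~ block + genotype` with the control as reference level. The
genotype coefficients are exactly the least-squares IL-minus-control
differences; their covariance (from the fit) yields the standard errors
and the correlation matrix of the comparison statistics, which the
unequal replication makes non-equicorrelated. `dunnett_compare` turns the
$t$ statistics into two-sided many-to-one adjusted p-values,
$p_i = 1 - P(\max_j |T_j| \le |t_i|)$, under the multivariate $t$
distribution with the fit's correlation matrix and residual df. The
integral is evaluated by `mvtnorm`'s quasi-Monte-Carlo algorithm with a
fixed, recorded seed (default tolerance 5e-4), so adjusted p-values are
reproducible to the integrator tolerance; a monotonicity pass removes
residual QMC jitter so $p$ is non-increasing in $|t|$. At $k = 1$ the
computation reduces exactly to the two-sided $t$ p-value. Screening is
two-sided because introgressions both increase and decrease traits in
practice; each trait is screened independently, with no multiplicity
correction beyond Dunnett within a location — this mirrors standard IL
screening practice.

For large simulation studies on a *fixed* design the package exposes the
equicoordinate critical constant (`dunnett_critical`): a comparison is
significant iff $|t|$ exceeds it, which is provably the same decision as
the adjusted p-value threshold and avoids re-integrating per replicate.
The test suite asserts this equivalence on fitted screens and uses the
constant for the 1000-replicate family-wise error-rate calibration, which
lands inside the 99% binomial interval around the nominal 0.05.

**Consistency filter.** A (line, trait) effect becomes a QTL candidate if
it is Dunnett-significant in at least `min_locations = 2` locations, by
default with the same sign in all qualifying locations (published IL QTL
tables report a single signed percent difference per QTL, implying
directional consistency; the requirement is switchable). A line with no
data in a location — e.g. a line that failed to set fruit there — simply
cannot qualify through that location. The reported effect size is the
mean percent difference over the qualifying locations, with percent
computed against the location's adjusted control mean.

## Overlap resolution

Candidates are grouped per (trait, chromosome) among lines carrying
segments there (`build_overlap_groups`). Within a group, every physically
overlapping pair of ILs is compared by a contrast test
(`contrast_test`): the difference of their block-adjusted means, pooled
over the locations where both qualify by inverse-variance weighting with
Welch–Satterthwaite degrees of freedom (a per-location option exists; the
pooled test uses all the shared evidence). `resolve_qtls` then builds a
graph with an edge between overlapping pairs whose contrast is *not*
significant; each connected component becomes one QTL:

* component interval = intersection of the members' segments (their
  shared region), or their union if the intersection is empty (flagged);
* overlapping pairs in *different* components (significant contrast)
  subtract the shared overlap from each side, so two distinct QTLs flank
  the boundary; if the subtraction would empty an interval the full
  introgression is kept and flagged;
* non-overlapping members always yield separate QTLs.

The two-IL merge-or-split rule is the published procedure; components
generalize it to larger overlap chains (documented as an extrapolation —
with more than two ILs the pairwise rule does not define a unique
partition, and connected components are its transitive closure). The
subtraction convention for split QTLs is chosen because published
adjacent QTL pairs partition cleanly at the overlap boundary. Two hard
invariants are asserted on every run: each QTL interval lies within the
union of its supporting lines' introgressions, and the component
partition is independent of member order. On groups of up to five members
the partition is tested against an exhaustive oracle over all contrast
patterns. A line with segments on several chromosomes cannot be localized
by the IL design at all; it joins every compatible group flagged
ambiguous rather than being silently assigned.

QTL names are `<trait prefix><chromosome>.<serial>` with serials by
ascending physical start within (trait, chromosome) — `fw1.1`, `fw1.2`,
`ic_L5.1` — and reported percent differences are rounded to integer
percent, matching the conventions of published IL QTL tables.

## The simulator

`simulate_library`/`simulate_trial` generate exactly the structure the
analysis assumes, so every stage is testable without external data.
Design defaults are the reference trial: 54 lines, 12 chromosomes (~760
Mb, physical lengths close to the SL2.40 tomato assembly), 3 locations,
8 blocks, 1 IL and 6 control plots per block, block 8 drawn as a pooled
mean of three plants. Segment geometry: per-chromosome line counts are
allocated proportionally to physical length; lengths are truncated-normal
(mean 25 Mb, sd 8, minimum 0.7 — the published library's range is
0.7–75 Mb with a 25 Mb mean); anchors are evenly spaced and lengths are
inflated to at least $(1+\text{overlap\_frac})$ times the spacing, so
consecutive segments overlap and coverage is complete by construction
(the configured floor errors only when genuinely infeasible). This yields
a mean per-line donor fraction near 3%, close to the published 3.7%.

Trait parameters default to fruit weight (control mean 98.2 g) and
soluble solids (4.48 °Brix). The fruit-weight residual SD is 12 g; the
location, block and G×L variances (67, 16, 18 g²) were set once so the
non-genetic variance shares resemble the published trial's effect table
(location ≈ 19%, interaction ≈ 5%, residual ≈ 41% of total). Planted QTL
effects are percentages of the control trait mean, converted to trait
units additively — so a zero-noise trial recovers the planted percent
exactly (tested). Because the percent is anchored to the grand control
mean while the screen computes percent against each location's control
mean, estimated percentages vary with the drawn location effects; this
is the realistic behavior, not an estimator bias. A per-line, per-location
missingness mask emulates lines that fail in a location.

What the generator does *not* emulate: non-Gaussian and heteroscedastic
residuals, spatial field trends within blocks, genetic linkage between
planted QTLs, epistasis, and measurement artifacts of image-based
phenotyping. Passing recovery tests therefore demonstrate the
correctness of the statistical machinery under its own assumptions, not
robustness to real-data pathologies.

## Numerical choices and degenerate inputs

* Physical coordinates are 0-based half-open Mb throughout; cM
  coordinates are reporting metadata only (all overlap computations are
  physical). BED export converts to integer base pairs; the Mb text mode
  round-trips bit-exactly.
* Interval algebra treats touching intervals (`[a,b) + [b,c)`) as
  non-overlapping but coalesces them under union.
* Zero-residual fits (constructed data): ANOVA falls back to the
  sequential decomposition and significance flags are off; heritability
  returns 0 when total variance is 0 and 1 when residual variance is 0
  with genetic spread.
* Correlations need ≥ 3 complete pairs, else `NA`; constant traits give
  `NA`.
* The multivariate-$t$ integrator seed, tolerance and α are recorded in
  outputs; all simulator randomness derives from the single config seed
  with stage-local derived seeds, and the caller's RNG state is restored.
* Problem sizes in the test suite (1000-replicate null calibration, 200
  heritability trials, ten planted QTLs on the full 54-line design,
  exhaustive ≤ 5-member contrast patterns) were chosen as the smallest
  sizes at which the calibration intervals are meaningfully narrow.

## Known limitations

* Fixed-effects blocks only; no REML/mixed-model variance components.
* The contrast pooling assumes independent per-location fits.
* Generalizing the two-IL merge rule by connected components can chain
  A–B–C into one QTL even when A and C do not overlap; the intersection
  then falls back to the union, flagged, rather than inventing a
  position.
* The packaged registry preserves the published table verbatim,
  including three internally inconsistent row pairs (identical physical,
  different genetic intervals); these produce warnings, not corrections.
* Descriptive (categorical) loci are curated records only; the package
  does not detect them from data.
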