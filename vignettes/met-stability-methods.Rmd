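---
title: "Methods: phenology, variance partitioning and yield stability in a multi-environment wheat trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenology, variance partitioning and yield stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Durum wheat flowering time is controlled jointly by major photoperiod
sensitivity genes (*Ppd-A1*, *Ppd-B1*) and by residual genetic variation
among genotypes carrying the same alleles, usually attributed to *earliness
per se* (Eps). In a multi-environment trial (MET) spanning contrasting
latitudes, both sources of flowering variation expose the crop to different
temperature, radiation and day-length regimes during spike formation and
grain filling, and thereby shape grain number (GN, grains/m²), single-grain
weight (GW, mg) and grain yield (GY, g/m², with the definitional identity
GN = 1000·GY/GW).

`metstab` implements the full analysis chain for such a trial — a series of
randomised complete block experiments (RCBD, 3 blocks) for 23 genotypes in
five *Ppd-A1*/*Ppd-B1* allele combinations (acronyms I0I, I5I, I5S, SI, SS;
a sixth, singleton combination is excluded), grown at 3 sites × 5 years =
15 environments.

## Environmental covariates

Each plot is characterised by aggregates of daily weather over its own
phenology windows (closed intervals, both stage dates included, so a one-day
window is never empty): mean temperature and radiation from emergence to
flowering and from flowering to maturity, accumulated radiation before
flowering, mean maximum temperature over the 11 days centred on flowering,
mean day length for both phases, and photo-thermal units from terminal
spikelet to flowering.

Day length uses the CBM model (a Forsythe-style formulation): with
$\theta = 0.2163108 + 2\arctan(0.9671396 \tan(0.00860(J - 186)))$ and solar
declination $\phi = \arcsin(0.39795\cos\theta)$,
$$D = 24 - \frac{24}{\pi} \arccos\left[\frac{\sin(p\pi/180) +
\sin(L\pi/180)\sin\phi}{\cos(L\pi/180)\cos\phi}\right],$$
with the arccos argument clamped to $[-1, 1]$. The twilight coefficient $p$
is the solar depression angle defining the edges of the day. We default to
$p = 6°$ (civil twilight) for "day length including twilight", and expose it
as a parameter, since the underlying model presents $p$ as the tunable part
of the day-length definition. At the study's latitudes (below 45°) clamping
never triggers; it only matters beyond ~66°.

Photo-thermal units are the accumulated product of daily thermal forcing
above a base temperature and day length,
$\mathrm{PTU} = \sum_d \max(T_{mean,d} - T_{base}, 0)\, D(L, d, p)$ in
°C·h. Published PTU variants differ in capping rules; the printed unit
(°C·h) forces a temperature × hours product, so we implement the plain
degree-hour product with $T_{base} = 0$ °C by default and both the base and
the twilight coefficient configurable. Covariates whose stage dates were not
recorded (double ridge, terminal spikelet and heading exist in only 3 of the
5 years) are reported absent, never imputed.

## Combined ANOVA and the genotype split

For each trait the package computes the sequential ANOVA of the complete
series: site, year, site×year, genotype, genotype×site, genotype×year,
genotype×site×year, block nested in site×year (30 df for 15 experiments × 2),
and residual. On balanced data these closed-form, marginal-mean sums of
squares coincide with sequential and Type-III SS; strict-balance mode
(default) refuses incomplete designs because every closed-form identity
assumes balance. A lenient path exists for cell means only
(`cell_means(strict = FALSE)`).

The genotype SS is split exactly into a between-allele-combination part
(4 df) and a within-combination part (18 df), and the genotype×site and
genotype×site×year interactions are split analogously. The percentage-SS
column divides by the total corrected SS including the residual, so it sums
to 100 over the primary (non-split) rows.

One denominator is non-standard by design: the between-combination F test
uses the within-combination mean square as its error term, a deliberately
conservative choice that guards against shared-pedigree bias within
combinations. All other F ratios use the residual mean square. Because a
year- and genotype-random EMS scheme for the remaining rows would be
guesswork, each row's denominator is labelled in the output so users can
re-form quasi-F ratios as they see fit.

Means are compared by Fisher's protected LSD:
$LSD = t_{1-\alpha/2,\,df_e}\sqrt{2\,MS_e/n}$, with a compact letter display
built by an insert-and-absorb pass over the descending means ("a" = highest
mean). Because the threshold is common to all pairs, maximal intervals of
mutually non-separated means are exact; ties are processed in descending
order. If the protecting omnibus F is not significant, all entities share
one letter and the output is flagged.

## Earliness per se: the per-experiment mixed model

Within each experiment the model
$$Y_{ij} = AC_i + G(AC)_{ij} + R_j + E_{ij}$$
has fixed allele-combination effects $AC_i$, random genotype-within-
combination effects $G(AC)_{ij} \sim N(0, \sigma^2_g)$, random replicates
$R_j \sim N(0, \sigma^2_r)$ and residual $E_{ij} \sim N(0, \sigma^2_e)$.
The BLUPs of $G(AC)$ are the Eps signal: removing the photoperiod-gene
effect is achieved exactly by the fixed $AC$ term, so BLUPs are
combination-centred by construction. In the balanced case the BLUP is the
raw genotype deviation from its combination mean shrunk by
$k_g = \sigma^2_g/(\sigma^2_g + \sigma^2_e/n_{rep})$.

REML estimation is delegated to `lme4::lmer` (with a tightened optimizer
tolerance), the field-standard engine; the balanced closed-form ANOVA
estimator with boundary truncation serves as an independent test oracle, not
as the production path. Negative variance iterates are truncated at zero
(the REML boundary) and flagged. Each of the 15 experiments is fitted fully
separately — the trait was analysed "by site and year", and pooling replicate
variances across experiments would impose an unstated homogeneity
assumption.

Pearson correlations between BLUP vectors of trait pairs (phase durations
versus yield-formation traits) are computed per experiment across genotypes,
with two-sided p values from the t transform on $n-2$ df. Degenerate pairs
(a numerically constant BLUP vector, which happens when $\hat\sigma^2_g = 0$)
are excluded and recorded rather than reported as spurious r values; fits
with fewer than four genotypes keep r but flag p as unreliable.

## Yield stability indices

All five indices operate on the complete entity × environment cell-mean
matrix $x_{ij}$ ($p$ entities, $q$ environments):

* **Joint regression (Finlay–Wilkinson)**: slope $b_i$ of entity $i$ on the
  environment index $I_j = \bar x_{.j}$, with a t test of $b = 1$ on $q-2$
  df. Genotype-level slopes average exactly 1.
* **Superiority measure (Lin–Binns)**:
  $P_i = \sum_j (x_{ij} - M_j)^2 / (2q)$ against the per-environment maximum
  $M_j$; zero iff the entity is best everywhere.
* **Ecovalence (Wricke)**: $W_i^2 = \sum_j (x_{ij} - \bar x_{i.} -
  \bar x_{.j} + \bar x_{..})^2$; the $W_i^2$ sum to the G×E interaction SS.
* **Stability variance (Shukla)**: the linear transform
  $\sigma^2_i = \frac{p}{(p-2)(q-1)} W_i^2 - \frac{\sum_k W_k^2}
  {(p-1)(p-2)(q-1)}$. Negative estimates are reported as-is (they are part
  of the estimator's sampling behaviour and published tables print them).
  Significance is an approximate F test of $\sigma^2_i$ against the pooled
  plot-level error variance of a cell mean on $(q-1, df_e)$ df — only when
  replicate-level error information exists; stars are never fabricated.
* **Kang rank-sum (YS)**: yield rank (highest mean = $p$, ties averaged),
  plus an LSD-step adjustment (±k when the mean sits more than k LSDs from
  the grand mean), plus a stability penalty (0/−2/−4/−8 for σ² not
  significant/0.05/0.01/0.001); entities with YS above the mean YS are
  selected. The cited rank-sum method is not restated in the source
  analysis, so this standard published formulation is documented as our
  variant rather than claimed identical.

Indices are computed per genotype on the 23×15 matrix and then summarised
per allele combination as unweighted means of member-genotype values — the
published combination-level slopes have a genotype-count-weighted mean of
≈ 1, which is the signature of genotype-level computation. The direct
variant on the 5×15 combination-mean matrix is also emitted, labelled, for
transparency.

## Environment PCA

Environment-level means (covariates plus GN, GW, GY averaged over genotypes
and replications; n = 15) feed a correlation-matrix PCA. Variables that are
numerically constant are dropped; of any pair with |r| above the screen
threshold (default 0.95, configurable — the source analysis says only "not
strongly correlated", without listing the pruned set) the first in column
order is kept. Eigenvectors are sign-fixed (largest-magnitude element
positive) because biplot axes are sign-ambiguous, making output
deterministic and row-order invariant.

## The synthetic trial generator

No field data are deposited for this class of study, so the package carries
a first-class simulator whose defaults state the emulated world:

* 3 sites at 41.63° N (autumn-sown, ~160 days emergence→flowering), 27.35° N
  (autumn-sown, ~110 days) and 19.52° N (spring-sown, ~75 days); 5 years;
  24-genotype roster (23 retained, one singleton combination excluded);
  3 blocks.
* Allele-combination flowering shifts I0I 0, I5I +2, I5S +5, SS +7, SI +9
  days — anchored to the reported nine-day span between the extreme
  combinations.
* Eps flowering SD of 3 days between genotypes within combinations; year
  (SD 2 d) and plot (SD 1.5 d) noise; flowering generated additively in
  whole days rather than through a mechanistic thermal-time model, because
  the downstream statistics need realistic marginal structure while the
  ground truth must stay exactly known.
* GW declines 0.5 mg per day of flowering delay (the negative
  flowering→grain-weight association), around a 40 mg base with a strong
  genotype effect (SD 4 mg) — grain weight is the trait under strongest
  genetic control.
* GN (base 15 000 grains/m²) carries combination effects (I5S and SS
  highest) and a single compensation coefficient (0.4) that docks grains
  from genotypes with heavier grains; one switch turns the GN–GW
  compensation off for null tests.
* Yield adds a per-genotype sensitivity multiplier (SD 0.12 around 1,
  normalised to mean 1) times a shared environment-quality term
  (site means +150/+50/−200 g/m², year SD 60), so that true
  joint-regression slopes are known exactly. To keep the truth exact, the
  yield equation uses the genotype-expected grain weight (photoperiod + Eps
  shifts only); the stored per-plot GW keeps its full environmental
  dependence, and stored GN is derived as 1000·GY/GW — its definitional
  identity in the data-recording protocol.
* Weather: sinusoidal annual mean temperature with AR(1) noise, fixed
  tmax/tmin half-range, radiation = clear-sky scale × (day length/12) ×
  cloud attenuation, truncated at zero. Within-genotype plot-level noise
  SDs have no published counterpart; they were chosen once to make the
  percentage-SS pattern of the published ANOVA qualitatively reproducible
  and are documented as arbitrary.

Randomness is organised as one stream per experiment, derived from the
master seed and the (site, year) identity, so adding an experiment never
perturbs the others; genotype-level effects come from the master seed
directly. Identical configuration and seed give byte-identical CSV output.

What the generator does **not** emulate: mechanistic crop growth, spatial
field structure, pests/stress, missing plots, or any correlation between
weather realisations and trait values (phenology and weather are generated
independently, so covariate–trait regressions across the three sites are
structural, not physiological). A green test therefore establishes that the
statistical machinery recovers known ground truth under the stated design —
not that the biology is simulated faithfully.

## Numerical choices and edge cases

* Dates are calendar dates; durations are whole days; all window aggregates
  use closed intervals.
* Division-by-zero traps: GW = 0 or spikelets/spike = 0 are hard errors;
  a zero grains/spike numerator yields 0, not NaN.
* ANOVA internal consistency (SS additivity to 1e-8 relative; percentage
  sum = 100; split additivity) is asserted on every run.
* The between-combination type-I error is verified by Monte Carlo under a
  null simulation (no combination effects, Eps variance > 0).
* Shukla significance and the Kang LSD step are skipped — flagged, not
  defaulted — when no replicate-level error is available.
* Letter displays resolve ties by processing means in descending order.

## Known limitations

* Strict mode requires complete balance; the published residual df (651 vs
  660 for a complete design) shows the original data had missing plots
  handled in an unstated way that we deliberately do not guess.
* The fixed-effects ANOVA reproduces the one explicitly stated non-default
  error term only; users needing a full random-effects EMS scheme should
  re-form quasi-F ratios from the labelled output.
* Published headline values (the actual index magnitudes) derive from
  undeposited field data and are not reproducible; the package's claims are
  therefore structural and property-based.
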