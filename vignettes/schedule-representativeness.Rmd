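---
title: "Do partial-night mist-net schedules representatively sample a bat assemblage?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Do partial-night mist-net schedules representatively sample a bat assemblage?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightnets)
```

## The question

Neotropical bat surveys overwhelmingly rely on understory mist-nets kept
open from sunset (about 18:00) to sunrise (about 06:00), checked every 30
minutes. Because all-night netting is exhausting, many field protocols only
sample the first six hours, on the common-sense assumption that early-night
activity peaks make that window representative of the whole night.
`nightnets` implements a complete analysis for interrogating that
assumption on any capture dataset, separating two competing explanations
for what a shortened schedule loses:

* the **sample-area (SA) effect** — a null expectation: smaller samples
  contain fewer individuals and, for any abundance distribution, fewer
  species, regardless of *which* hours are sampled;
* the **differential species activity pattern (DSAP) effect** — a
  biological one: species differ in when they fly, so a schedule biases
  *which* species are caught, not just how many.

The package compares three canonical schedules over the 720-minute night:
the full night (`12h`, minutes `[0, 720)`), the classic first half (`6h`,
`[0, 360)`), and a split alternative covering the first and last three
hours (`6hB`, `[0, 180) + [540, 720)`). All intervals are half-open, with
minute 0 at nominal 18:00; real sunset drift is ignored because captures
are pooled by clock time. A capture logged exactly at midnight (minute 360)
therefore belongs to the second half-night — an arbitrary but unambiguous
partition.

## Pipeline overview

1. **Capture matrices** (`read_captures()`, `restrict_to_schedule()`,
   `build_matrix()`). One row per captured individual; times are snapped
   *down* to the start of their 30-min net-check interval (the recorded
   time is taken to be the check time, since field protocols log captures
   when nets are checked). Schedule restriction never removes night
   replicates: a night that catches nothing under a schedule stays as an
   all-zero matrix row, so catastrophic schedule failure remains visible
   downstream rather than being silently dropped.
2. **Rarity profiles** (`rarity_profiles()`).
3. **Activity change points** (`titan_analysis()`).
4. **Richness at common effort** (`richness_curve()`).
5. **Compositional congruence and its null model**
   (`strategy_congruence()`, `null_model()`).

`run_pipeline()` chains all stages, writes every stage table as CSV plus a
JSON manifest, and is reproducible byte-for-byte from its seed.

## Rarity index

Three complementary metrics are computed per species and dataset:

* `LA` (local abundance): for each occupied site, the species' mean
  captures per replicate night divided by the site's total captures; `LA`
  is the median across occupied sites. The denominator is the *site* total
  (not a per-night total) — the site-level reading of "relative abundance
  at a site".
* `RA` (regional abundance): total records in the dataset divided by the
  number of occupied sites.
* `GR` (geographic range): the area, in km², of the minimum convex polygon
  around occupied-site coordinates, computed on the WGS84 ellipsoid via
  `geosphere`. By default `GR` uses only the focal dataset's sites;
  `gr_records`/`gr_sites` accept pooled multi-region tables when ranges
  should reflect every surveyed region.

Each metric is `log(x + 1)`-transformed and min–max standardized to
`[0, 1]` across species. The `+1` offset keeps single-site species
(`GR = 0`) finite; the price is that the index is only *approximately*
invariant to rescaling a raw metric (exactly invariant under a pure log).
The three standardized metrics are combined as a weighted mean,

`RI = (LA_s ω_LA + RA_s ω_RA + GR_s ω_GR) / (ω_LA + ω_RA + ω_GR)`,

where each weight rewards a metric for being *independent* of the other
two. The published rendering of the weight formula is typographically
ambiguous, so both readings are provided: the default

`ω_LA = 1/2 + (1 − |r_LARA|)/2 + (1 − |r_LAGR|)/2`

(`r` = Pearson correlation across species of the log-standardized
metrics — correlations are computed on the quantities actually averaged,
not the raw metrics), and a squared-correlation variant
(`weight_variant = "squared"`) replacing `|r|` with `r²`. Both map two
independent companions to `ω = 1.5` and two collinear ones to `ω = 0.5`.
Species are then classed **R**are (`RI ≤ Q1`), **C**ommon (`RI ≥ Q3`) or
**U**ncommon, with inclusive quartile boundaries (linear-interpolation
quantiles) so that distinct RI values always produce non-empty R and C
classes. The classification is dataset-relative by construction: the same
species may be rare in one region and common in another.

## Threshold indicator taxa analysis

Activity change points along the night are located with a
threshold-indicator analysis implemented from scratch (with its
permutation/bootstrap engine in compiled code).

* **Sample units** are (site, night, 30-min interval) cells — every check
  interval of every sampled night, empty ones included — and the gradient
  value of a unit is its interval midpoint. This is the finest unit the
  net-check protocol defines, and it provides enough observations for
  midpoint candidates and minimum split sizes; ordinary nights-as-units
  would collapse the time gradient entirely.
* Species with fewer than 9 records are pooled into composite taxa keyed
  by (guild, rarity class); pooling happens once, and a composite that is
  still sparse is analysed as-is.
* **Candidates** are midpoints between consecutive distinct observed
  capture times of the taxon; any candidate leaving fewer than `minSplt =
  4` units on a side is discarded. Units exactly at a candidate value
  count as the left (early) side.
* For each candidate the Dufrêne–Legendre indicator value is computed on
  both sides (`IndVal = 100 ×` specificity `×` occurrence fidelity); the
  candidate and side with the largest IndVal give the observed change
  point and its direction — left-side indicators are *negative*
  (early-night) responders, right-side *positive* (late-night). Ties go to
  the earlier candidate and the negative side.
* The observed maximum is standardized against `n_perm` permutations of
  the unit labels, with the candidate set held fixed and the selection
  (max over candidates and sides) recomputed per permutation — a
  selection-adjusted null. The permutation p uses the `(1 + #≥)/(n_perm +
  1)` convention. Constant taxa yield zero permutation variance and are
  flagged, never significant.
* `n_boot` bootstrap resamples of units (candidates re-derived from each
  resample) give **purity** (fraction agreeing in direction), and
  **reliability** (fraction with permutation `p ≤ 0.05`), and a 90%
  change-point interval (5th/95th percentiles). A taxon is significant
  when purity ≥ 0.95 *and* reliability ≥ 0.95. Defaults `n_perm = 250`,
  `n_boot = 500` follow the method's reference implementation; both are
  configurable.
* **Community thresholds** are peaks of the cumulative sums of z-scores of
  negative and positive responders ordered by change point; by default
  only pure-and-reliable taxa enter the sums (`filter_significant`
  switches this off). A direction with no responders is flagged rather
  than given a spurious peak.

## Richness at common effort

The sample-area effect is quantified by analytic rarefaction:
individual-based `E[S(m)] = S_obs − Σ C(n − n_i, m)/C(n, m)` and its
sample-based analogue on incidence counts, both evaluated in log-gamma
arithmetic. Extrapolation beyond the observed effort uses Chao-type
estimates of undetected species, `f0 = f1²/(2 f2)` (with the
bias-corrected `f1(f1 − 1)/2` convention when no doubletons exist), inside
the closed form `S(n + g) = S_obs + f0 (1 − (1 − f1/(n f0 + f1))^g)`; the
sample-based version mirrors the same form with uniques/duplicates `Q1`,
`Q2`. The curve is continuous at the reference point, monotone, and
asymptotes at `S_obs + f0`. Confidence intervals come from a percentile
bootstrap over sample units (default 200 resamples) rather than an
analytic unconditional variance: the bootstrap is assumption-light,
directly testable, and applies unchanged to both modes. Schedules are
compared at the *full-night* reference effort, so a shorter schedule's
curve is extrapolated to the number of individuals (or nights) the full
night observed; "significantly different" is operationalized as
non-overlapping 95% intervals there.

## Compositional congruence

The DSAP effect is isolated compositionally. Night replicates — not
sites — are the ordination rows: schedule matrices describe the same
sampling events as the full-night matrix, and five ordination axes are
impossible with only a handful of sites, while 24–66 nights support them
comfortably. For each schedule and each of two dissimilarities (Jaccard on
presence/absence, emphasizing identity change; Bray–Curtis on counts,
integrating abundance):

1. all-zero nights are dropped *per matrix* and reported;
2. each matrix is ordinated by principal coordinates (double-centering and
   eigendecomposition; negative eigenvalues are dropped without
   Cailliez/Lingoes correction, their magnitude reported — the most common
   default, and the choice least likely to distort the leading axes);
3. the configurations are intersected on shared nights and the first five
   axes (fewer when fewer positive axes exist) are superimposed by
   symmetric Procrustes rotation (both configurations centered and scaled
   to unit sum of squares, reflection allowed), via `vegan`;
4. congruence is `r = √(1 − m²)`; significance comes from the PROTEST
   permutation test (999 permutations, `(1 + #≥)/(n + 1)` p-values).

A comparison is **degenerate** when fewer than 3 usable nights or fewer
than 2 positive axes remain — the "too many zeros" failure mode that a
sparse split schedule can produce in small datasets, reported explicitly
as very poor performance rather than a number.

The **null model** asks how much congruence would be lost by sampling
fewer *species* rather than fewer *hours*: each draw keeps `k` uniformly
chosen species of the full-night matrix (all nights, full-night counts)
and measures that subset's congruence with the whole community. In
`curve` mode `k` sweeps a grid; in `matched` mode all draws (default
1,000 — the published procedure names 1,000 sub-samples without fixing
the per-`k` allocation, so both modes are provided) use a schedule's own
species count, and `null_percentile()` places the schedule's `r` within
the null distribution. A schedule whose `r` sits far below the matched-`k`
null median is losing composition to *when* it samples, not merely to how
many species it happens to include.

## The synthetic generator

Because the original three-biome capture data have no public accession,
every stage is validated on synthetic data with known truth
(`simulate_dataset()`), emulating the study conditions:

* multi-site, multi-night sampling over the 720-min window at 30-min
  checks;
* a skewed lognormal species-abundance distribution. Drawn rates are
  rescaled so the *expected* community total matches a configured target —
  the fixed-total, lognormal-relative-abundance convention — because the
  survey templates are defined by their realized totals (e.g. about 1,740
  individuals over 66 nights for the Amazonian template) and an
  uncalibrated lognormal sum varies far too much across seeds to stand in
  for a named survey;
* per-species Bernoulli site occupancy, and uniform site coordinates in a
  per-biome bounding box;
* per-species activity densities built from a uniform floor plus truncated
  normal peaks on `[0, 720)`: all-night, early-peaking (center 100 min,
  sd 80 — the busy first four hours), late-peaking (center 680 min, sd
  45 — the pre-dawn hour), or bimodal mixtures of the two. These shapes
  are the simplest that reproduce the bimodal community profile real
  surveys show;
* Poisson nightly counts by default, with a negative-binomial
  overdispersion switch for robustness checks.

The `amazonia_like_preset()` (10 sites, 66 nights, 45 species, expected
total 1,742) assigns late peaks preferentially to frugivores — about a
quarter of species — and early peaks to nectarivores, matching the guild
associations reported for such assemblages; `atlantic_like_preset()` (4
sites, 59 nights) and `cerrado_like_preset()` (6 sites, 24 nights, sparse
and weakly structured) complete the three survey templates.

What the generator does *not* emulate: net shyness and trap-avoidance
learning, within-night weather, vertical stratification, or spatial
autocorrelation among sites. Passing tests therefore demonstrate that the
statistical machinery recovers known structure under the stated sampling
model — not that any particular field protocol is free of those further
biases.

## Numerical choices and degenerate inputs

* Quantiles everywhere use R's default linear-interpolation rule.
* Zero-variance metrics in the rarity weights are treated as correlation
  0, with a warning.
* Fewer than 4 species cannot be quartile-classified (all Uncommon, with a
  warning); a single species cannot be standardized (error).
* PCoA eigenvalues below `1e-9` of the largest are treated as null space.
* Rarefaction at `m = n` reproduces `S_obs` exactly; extrapolation with no
  singletons returns a flat curve.
* All Monte-Carlo stages (permutations, bootstraps, null draws,
  simulation) are driven by explicit seeds and are bit-reproducible.

## Problem sizes used in the shipped checks

The package's own validation runs at deliberately modest sizes chosen to
exercise every code path while keeping the whole suite quick: the
worked-example pipeline uses the Amazonia-like preset (66 nights, ~1,700
captures) with full TITAN defaults; recovery studies use 48-unit gradients
over 50 seeds with 100 permutations and 150 bootstraps; calibration
studies use 200 seeds with 99–199 permutations or draws. Those counts are
statistical choices — enough replication for the 95%/5% criteria being
checked to be stable — and all are configurable upward.

## Known limitations

* The analysis pools nights by clock time; surveys spanning strong
  seasonal sunset shifts would need time-since-actual-sunset inputs.
* `GR` is a raw convex hull: no land clipping or alpha shapes, so
  coastal or elongated ranges are overestimated.
* Sample-based extrapolation mirrors the individual-based closed form
  exactly (no small-sample `(R − 1)/R` factor), which slightly inflates
  `Q0` for very few sampling units.
* Effort is assumed standardized per night (equal net-hours); no
  net-level modeling is attempted.
* The community z-sum thresholds carry no bootstrap intervals; they
  summarize, rather than test, the per-taxon results.
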