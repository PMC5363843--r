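# nightnets

Tools for deciding whether **partial-night mist-net schedules**
representatively sample a nocturnal bat assemblage.

Neotropical bat surveys keep understory mist-nets open from sunset
(~18:00) to sunrise (~06:00), checked every 30 minutes — but many field
protocols only sample the first six hours and assume the early activity
peak makes that window representative. `nightnets` turns that assumption
into a measurable question for any capture dataset, disentangling:

* the **sample-area (SA) effect** — smaller samples hold fewer individuals
  and hence fewer species, whatever the hours;
* the **differential species activity pattern (DSAP) effect** — species fly
  at different times, so a schedule biases *which* species are caught.

It is aimed at community ecologists and survey designers who have (or plan
to collect) capture records with times of night, and want to know what a
shortened schedule costs.

## What it computes

Given capture records (one row per individual: dataset, site, night,
species, family, guild, time), the package:

1. builds night × species abundance matrices for the full night (`12h` =
   minutes `[0,720)`), the classic first half (`6h` = `[0,360)`), and a
   split alternative (`6hB` = `[0,180) ∪ [540,720)`);
2. scores each species on a three-metric **rarity index**
   `RI = (LA·ω_LA + RA·ω_RA + GR·ω_GR)/(ω_LA+ω_RA+ω_GR)` — local
   abundance, regional abundance, and minimum-convex-polygon range, each
   log-transformed, min–max standardized, and weighted by its independence
   from the other two (`ω = 1/2 + Σ(1−|r|)/2`) — then classes species
   Common/Uncommon/Rare by RI quartiles;
3. locates per-species activity **change points** along the night with a
   threshold-indicator analysis (Dufrêne–Legendre
   `IndVal = 100·specificity·fidelity` maximized over capture-time
   midpoints, permutation z-scores, bootstrap purity/reliability at the
   95% level, minimum split size 4, species under 9 records pooled by
   guild × rarity), plus community-level `z−`/`z+` threshold curves;
4. compares schedules by individual- and sample-based **rarefaction**
   `E[S(m)] = S_obs − Σ C(n−n_i, m)/C(n, m)` with Chao-type extrapolation
   `S(n+g) = S_obs + f0(1−(1−f1/(n f0+f1))^g)` to the full-night effort;
5. measures compositional **congruence** of each schedule with the full
   night: Jaccard/Bray–Curtis dissimilarities → principal coordinates →
   symmetric Procrustes rotation on the first five axes, `r = √(1−m²)`,
   PROTEST permutation significance — against a **null model** of 1,000
   random species subsets that isolates the SA effect from the DSAP
   effect.

A synthetic-data generator (`simulate_dataset()` and three survey-template
presets) provides datasets with known activity and rarity structure for
validation.

## Worked example

```r
library(nightnets)

sim <- simulate_dataset(amazonia_like_preset(seed = 1))  # 10 sites, 66 nights
sp  <- sort(unique(sim$records$species))
sch <- canonical_schedules()
mats <- lapply(sch, function(s)
  build_matrix(restrict_to_schedule(sim$records, s), sp, sim$nights))

sapply(mats, sum)
#>  12h   6h  6hB
#> 1722  821 1271
```

The full night catches 1,722 individuals; the split schedule (`6hB`)
recovers 1,271 of them (the full night still yields 35.5% more than the
best half-night), while the classic first six hours gets only 821 — the SA
effect in raw numbers.

```r
rar <- rarity_profiles(sim$records, sim$sites, nights = sim$nights)
head(rar[order(-rar$RI), c("species","LA","RA","GR","RI","rarity_class")], 5)
#>    species      LA   RA    GR    RI rarity_class
#> 16   sp016 0.03533 46.3 16320 0.993            C
#> 25   sp025 0.02783 34.3 16947 0.902            C
#> 11   sp011 0.01982 26.2 11267 0.790            C
#> 23   sp023 0.01273 17.2  9466 0.682            C
#> 42   sp042 0.00873 10.6 17519 0.630            C
table(rar$rarity_class)
#>  C  R  U
#> 12 12 21
```

`RI` runs from 0 (rarest) to 1 (most common); `GR` is in km². Quartile
classes split the assemblage into 12 common, 21 uncommon and 12 rare
species.

```r
for (m in c("jaccard", "bray"))
  for (nm in c("6h", "6hB")) {
    sc <- strategy_congruence(mats[["12h"]], mats[[nm]], m,
                              n_perm = 999, seed = 7)
    cat(sprintf("%-8s %-4s r = %.3f  (p = %.3f, k = %d species)\n",
                m, nm, sc$r, sc$p, sc$n_species_strategy))
  }
#> jaccard  6h   r = 0.761  (p = 0.001, k = 41 species)
#> jaccard  6hB  r = 0.886  (p = 0.001, k = 45 species)
#> bray     6h   r = 0.771  (p = 0.001, k = 41 species)
#> bray     6hB  r = 0.941  (p = 0.001, k = 45 species)
```

Congruence `r = √(1−m²)` measures how faithfully a schedule reproduces the
full-night compositional geometry (1 = perfectly). The split schedule
clearly outperforms the first-half schedule under both metrics — it
samples both activity peaks — yet both sit far below random species
subsets of the same size (`null_model()` medians ≈ 0.96–1.00), showing a
genuine time-of-night bias on top of the sample-area effect.

The whole analysis, including the threshold analysis and all output CSVs,
runs as one call:

```r
res <- run_pipeline(list(preset = "amazonia", out_dir = "out", seed = 1))
```

or, on real data, with `captures = "captures.csv", sites = "sites.csv"`
instead of `preset`.

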