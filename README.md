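# snowcross

Multi-scale analysis of where large mammals prefer to cross a highway,
from winter snow-track surveys.

## Who this is for

Road ecologists and quantitative wildlife biologists who have (or want
to prototype against) paired track surveys — crossing attempts recorded
along a highway, and tracks along off-road transects — plus landscape
predictors measured in buffers at several spatial scales, and who need
to answer: *how severe is the barrier effect, which landscape features
at which scale predict preferred crossing sites, and where would a
crossing structure serve the whole community?*

## What it computes

**Barrier effect.** Counts are standardized by elapsed 12 h periods
since snowfall (`count / ceiling(hours/12)`), converted to crossings
per km, and combined into highway permeability

```
permeability = (highway crossings per km) / (transect crossings per km)
```

(1 = no barrier, 0 = absolute barrier), with track accumulation curves
whose flat stretches mark candidate barrier segments.

**Crossing-site preference.** Per-point track abundance is modeled on
standardized (mean 0, sd 1) predictors under four count families —
Poisson, negative binomial (variance `mu + mu^2/theta`), and their
zero-inflated mixtures (`P(0) = pi + (1-pi) f(0)`) — fitted by
quasi-Newton maximum likelihood with analytic gradients. Families are
compared by likelihood-ratio tests, the Vuong statistic
`V = sqrt(N) mean(m) / sd(m)` with `m_i = log(P1(y_i)/P2(y_i))`, and
AICc ranking. Predictor subsets are explored by a branching AICc beam
search (all models within ΔAICc ≤ 2 of an iteration's best become bases
for the next), filtered on predictor significance (p ≤ 0.15) and
estimate/SE magnitude (≤ 50), and averaged with Akaike weights
`w_i ∝ exp(-Δ_i/2)` over the ΔAICc ≤ 2 set — separately for six
spatial approaches (200 m / 500 m / 1 km / all scales / digitized /
combined; 45 candidate predictors in the combined pool).

**Community maps.** Averaged models predict abundance on a 30 m grid
(15 m crossing corridor, 1 km approach corridor); per-group abundance
deciles multiply into a community preference score
`(∏ deciles) / 10^(g-1) ∈ (0, 10]`, and highway segments scoring in the
top quartile of both the crossing and the approach surface are flagged
as mitigation priorities.

A seeded synthetic-landscape generator (smooth latent fields,
configurable cross-scale correlation, all four count families, known
permeability) makes every stage testable end to end.

## Worked example

```r
library(snowcross)

cfg <- landscape_config(n_highway_points = 300, n_transect_points = 200,
                        highway_length_km = 40, n_transects = 6, seed = 7)
tab <- standardize_predictors(generate_predictors(cfg))
truth <- simulation_truth("zip",
                          c(intercept = 0.6, water_500 = 0.5),
                          c(intercept = -0.4),
                          permeability_truth = 0.25)

tracks <- simulate_tracks(cfg, truth, seed = 7, intensity_per_km = 4)
permeability_table(tracks, highway_km = 40, transect_km = 6)
```

```
       group highway_rate transect_rate permeability                basis
1 carnivores        2.150          1.21        1.775           all tracks
2 carnivores        0.579          1.21        0.478 successful crossings
3       deer        1.885          1.28        1.476           all tracks
4       deer        0.498          1.28        0.390 successful crossings
5        elk        1.740          1.25        1.390           all tracks
6        elk        0.319          1.25        0.255 successful crossings
...
```

Every simulated approach leaves a track, so the *successful crossings*
rows are the estimator of the planted permeability (0.25): elk lands at
0.255 here, the others scatter around it with only 6 transect-km of
effort.

```r
counts <- simulate_counts(tab$data, truth, seed = 8)
hwy <- counts[counts$route == "highway", ]
choice <- compare_distributions(hwy)
choice$table
```

```
   family   logLik df   n pred_zero   vuong      aic     aicc
1 poisson -557.244  1 300        84      NA 1116.488 1116.501
2  negbin -463.268  2 300       152      NA  930.536  930.576
3     zip -469.653  2 300       157 5.49969  943.306  943.346
4    zinb -458.944  3 300       157 1.52495  923.888  923.969
```

`choice$pick` is `"zinb"` even though the counts were generated as ZIP:
the omitted `water_500` effect makes the *marginal* distribution
overdispersed, so the intercept-only comparison prefers a dispersion
parameter. This is exactly why the pipeline re-evaluates all four
families once predictors enter the models rather than trusting
intercept-only pre-selection.

```r
set <- filter_candidates(
  iterative_search(hwy, choice$pick, approach_pools(cfg)[["500m"]],
                   approach = "500m"))
average_models(set)
```

```
<averaged_model> family=zinb  members=2  criterion=AICc
                predictors delta weight
1 water_500+herbaceous_500 0.000  0.547
2                water_500 0.379  0.453
```

The search recovers the planted `water_500` effect in every retained
member; predictions from this object feed `predict_abundance()`,
`decile_scores()` and `community_score()` on a `build_grid()` corridor.

## Pipeline / CLI

The whole analysis runs as one reproducible pipeline with JSON
configuration (defaults match the reference survey design):

```sh
Rscript inst/cli/snowcross.R full-run \
    --config inst/extdata/fixture_config.json --out-dir out --seed 42
```

writing the permeability table, distribution-comparison and
approach-ranking reports, search traces (JSON lines), averaged-model
coefficients, per-cell abundance/decile/community tables, GeoJSON cell
maps, overlap segments, and a run manifest (seed, config hash,
version). The same stages are callable from R via `run_subcommand()`.

## Layout

- `R/synthetic_data.R` — seeded landscape/count/track generator
- `R/survey.R` — deduplication, effort standardization, permeability,
  accumulation curves
- `R/count_models.R` — ML fitting of P/NB/ZIP/ZINB, criteria,
  predicted zeros
- `R/selection.R` — LRT, Vuong, distribution choice, beam search,
  filtering, averaging, approach comparison
- `R/mapping.R` — corridor grids, abundance surfaces, deciles,
  community scores, overlap report
- `R/cli.R`, `inst/cli/snowcross.R` — pipeline orchestration
- `vignettes/crossing-site-analysis.Rmd` — methods and design notes
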