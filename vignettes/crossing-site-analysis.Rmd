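---
title: "Methods: multi-scale crossing-site analysis from snow-track surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale crossing-site analysis from snow-track surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A major highway can act as a movement barrier for large mammals: animals
approach it through the surrounding landscape, and only some of them
attempt and complete a crossing. Winter snow-track surveys give two
complementary views of this process — tracks at highway crossing sites,
and tracks along off-road transects roughly parallel to the road. From
these, `snowcross` answers three questions:

1. *How strong is the barrier?* (permeability and accumulation curves)
2. *Which landscape features predict preferred crossing sites, and at
   which spatial scale?* (multi-scale count regression and model search)
3. *Where should mitigation structures go for the whole community?*
   (composite preference maps)

# Survey statistics

Counts accumulate between snowfalls, so each record is standardized by
the number of elapsed 12 h periods, `count / ceiling(hours / 12)`. The
ceiling is deliberate: surveys begin at least 12 h after snowfall, so
the divisor is always at least one, and a survey 30 h after snowfall is
treated as three accumulation periods. Standardized counts are summed
per route and divided by kilometres surveyed, giving crossings per km.
Permeability is the ratio of the highway rate to the transect rate: 1
means the road is no barrier, 0 an absolute one. It is undefined (and
flagged, not silently zeroed) when no off-road movement was observed.

Repeat crossings of one individual are handled the way a field crew
would: within a species and route, records within 300 m of the last
*kept* record are flagged as possible repeats, scanning left to right
along the route. This greedy rule is a modelling decision, not a
theorem; the test suite bounds it against a brute-force clustering
oracle on pathological spacings. Both the full and the repeat-filtered
permeability tables are reported, because whether repeat tracks belong
in "all tracks" totals is genuinely ambiguous.

Track accumulation curves are monotone step functions of cumulative
(count-weighted) crossings along the route; flat stretches longer than
a configurable threshold (default 5 km) are reported as candidate
barrier segments.

# Count models

Per-point track counts are regressed on standardized predictors
(mean 0, sd 1 on the training rows; grid predictions reuse the training
statistics). Four error families are fitted by maximum likelihood with
a log link on the count mean:

* Poisson (`P`), variance = mean;
* negative binomial (`NB`) with dispersion `theta`, variance
  `mu + mu^2 / theta` — the parameterization of the common fitting
  software, stated explicitly because conventions differ;
* zero-inflated Poisson and negative binomial (`ZIP`, `ZINB`), mixtures
  with a logit-linked structural-zero probability `pi`:
  `P(0) = pi + (1 - pi) f(0)` and `P(y > 0) = (1 - pi) f(y)`.

All four are optimized jointly by BFGS with analytic gradients. Two
numerical choices matter:

* `theta` is estimated on the log scale, and the NB log-likelihood is
  written with `log1p(lambda / theta)` terms. The naive form
  `theta*log(theta) - (theta + y)*log(theta + lambda)` cancels
  catastrophically as `theta -> Inf` (the Poisson boundary), which lets
  the optimizer chase floating-point noise and report spuriously good
  fits on equidispersed data. The stable form makes the boundary flat;
  `theta` is additionally capped at `exp(30)`.
* Zero-inflated fits are initialized from the base-family fit plus a
  logit intercept derived from the observed excess-zero fraction, which
  makes the mixture likelihood's benign mode the one found in practice.

Standard errors come from the observed-information Hessian at the
optimum; Wald p-values are computed identically for count-part and
zero-part coefficients (the significance filter below needs both).
Non-convergence is reported honestly (`converged = FALSE`), and an
all-zero response under a zero-inflated family is flagged as a boundary
case rather than fitted to a diverging intercept.

# Distribution choice

Families are compared three ways on intercept-only fits: likelihood-
ratio tests for the nested pairs (P vs NB, ZIP vs ZINB; plain
chi-squared reference, without the boundary-corrected mixture for the
dispersion test — a documented, conventional simplification that makes
the test conservative), the Vuong statistic for the non-nested pairs
(base vs zero-inflated), and the information-criterion ranking. The
Vuong statistic is `V = sqrt(N) * mean(m) / sd(m)` with
`m_i = log(P1(y_i) / P2(y_i))`; `|V| > 1.96` indicates preference, and
a degenerate `sd(m) = 0` (identical predicted probabilities) yields an
explicitly flagged undefined result. The final pick is the family with
the lowest criterion value, with the tests reported as the
justification chain and exact ties resolved toward the simplest family.

`AIC = 2 df - 2 logLik` and `AICc = AIC + 2 df (df + 1) / (n - df - 1)`
are both computed; ranking uses AICc with `n` = number of survey points
(the choice of `n` for zero-inflated models is not settled usage; plain
observation count is used and recorded here).

# Model search, filtering, averaging

With 12 digitized and 33 scale-specific remote-sensed candidates, the
combined pool holds 45 predictors — 2^45 subsets, far beyond
enumeration. The search is a branching forward ("beam") procedure:
start from the intercept-only model; at each iteration extend every
base model with each absent predictor; keep *all* models within 2 AICc
of the iteration's best as bases for the next iteration; stop as soon
as the best AICc no longer strictly decreases (a tie counts as no
reduction). Duplicate predictor sets reached along different branches
are fitted once and cached. For zero-inflated families two zero-part
variants are searched — intercept-only, and mirroring the count
predictors — and pooled into one candidate list before ranking;
pooling after (rather than before) the search is a design choice made
here, since either order is defensible.

Candidates are then filtered: any model with a non-intercept
coefficient at Wald `p > 0.15` (a deliberately liberal, stepwise-style
cutoff aimed at uninformative local-maximum fits), and any model with
`|estimate| > 50` or `SE > 50` (separation / lack of fit), is removed
with a logged reason. Intercepts are exempt from the p-value rule,
otherwise intercept-only models could never survive. Surviving models
within 2 AICc of the best are averaged with Akaike weights
`w_i ∝ exp(-Δ_i / 2)`; predictions are weight-averaged predicted means,
and the averaged coefficient table is a *full* average (an absent
predictor contributes zero through that member).

Six spatial approaches are compared per species group and dataset:
each single scale (200 m, 500 m, 1 km), all scales, the digitized
variables, and everything combined. The best cell overall is reported,
and separately the best among the remote-sensed approaches, because
only remote-sensed predictors exist wall-to-wall and can feed
prediction grids.

# Prediction maps

A 30 m square grid (matching the land-cover product resolution) is laid
along the route: a 15 m corridor for crossing predictions and a 1 km
corridor for approach predictions. Cells belong to the corridor when
their centroid lies within the buffer of the polyline; the grid is
anchored at the corridor's bounding-box minimum corner, which makes the
construction deterministic and gives a straight 900 m route at default
settings exactly one 30-cell strip. Abundance surfaces from the
averaged models are binned into empirical deciles (ties share the
lowest containing bin; collapsed bins on zero-heavy surfaces are
flagged rather than jittered), and per-group deciles multiply into a
community score divided by `10^(g - 1)` — with four groups, the
familiar product-over-1000 — always in `(0, 10]`, 10 meaning every
group scores the top decile. Quantiles are computed separately per
prediction surface (highway vs approach), matching the two model sets.
Segments where crossing and approach scores are both in the top
quartile are the mitigation priorities; the quartile comparison is
strict (`>`), because with tie-heavy score maps a `>=` rule would flag
every bin sharing the threshold value.

# The synthetic landscape

Everything above is testable without field data because the generator
states a complete world:

* Eleven remote-sensed variables are smooth unit-variance random fields
  along the route (low-order Fourier series with 1/k amplitude decay),
  mixed with point-level noise. Scale variants share a latent field
  component with weight `cross_scale_correlation` (default 0.6), which
  reproduces the multicollinearity of nested buffers that makes scale
  selection a real problem. Transform slopes from the latent Gaussian
  to natural units (logistic for area proportions, exponential for road
  lengths and building counts) are fixed at 0.4, chosen from the
  attenuation formulas so the *delivered* columns still correlate near
  the configured latent value.
* Twelve digitized proportions are correlated noisy views of the same
  latent habitat, squashed through a softmax so they lie in [0, 1].
  How digitized micro-habitat maps covary with land-cover classes is an
  assumption of the generator, not an estimated quantity.
* Counts are drawn from any of the four families with known
  coefficients; tracks arrive as a Poisson process along routes, and a
  highway attempt's success flag is drawn with the configured
  permeability. Defaults follow the reference survey design: 463
  highway and 308 transect points, a 95 km highway, ten 1 km transects
  offset 10–900 m, scales 200/500/1000 m, and four groups (carnivores,
  deer, elk, moose) spanning all four families.

What a green test does **not** establish: the generator has no herding
behaviour (real elk tracks cluster far more than a Poisson process), no
GPS error, no observer effects, no temporal autocorrelation between
survey days, and its landscape is one-dimensional along the route. A
pipeline that recovers this stated world can still mis-rank models on
real data whose violations of these assumptions matter.

# Known limitations

* The dispersion LRT uses the plain chi-squared reference at a boundary
  null; p-values are conservative.
* AICc ranks relative fit only; no cross-validation of predictive
  ability is attempted.
* The beam search is a heuristic: on small pools it attains the
  exhaustive optimum in the vast majority of seeded replicates (and can
  never beat it), but no guarantee exists for 45-predictor pools.
* Planar local coordinates only; real-CRS geodesy is out of scope.
* Reversible-jump MCMC over model space would be a principled
  alternative to Akaike-weight averaging and is deliberately not
  implemented.
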