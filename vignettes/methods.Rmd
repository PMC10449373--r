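---
title: "Seasonal plankton association networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal plankton association networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lsanet` analyses microbial plankton communities sampled repeatedly
through a growing season across several nearby shallow lakes (the
motivating systems are alkaline soda pans sampled fortnightly across
spring, summer and autumn). This vignette explains the statistical
machinery, the choices behind it, and what the synthetic benchmark can
and cannot tell you about real data.

## Data model

A study is a set of per-lake OTU count tables (samples × OTUs) with
sample metadata: lake, integer sampling occasion `time_index` (1..T),
season label, and a `missing` flag for occasions when a lake was dry and
could not be sampled. Dry dates are represented as metadata rows
*without* count rows: filling them with zero counts would register as a
complete community die-off in every dissimilarity and association
statistic, which is an artefact of encoding, not biology.

All samples are rarefied (uniform subsampling without replacement, one
hypergeometric draw per sample, seeded per sample from a master seed) to
a common depth — by default the minimum observed read count — so read
shares, dissimilarities and detection calls are comparable across
samples. Core membership, abundance filters and read shares are computed
on the rarefied counts.

## Core microbiome

An OTU is *core* for a set of lakes when it has at least one
(post-rarefaction) read in every lake, pooled over the study period;
with five lakes this gives the usual "core5" set, with the four lakes of
one habitat type "core4". The definition is deliberately presence-based
at the whole-study level rather than prevalence-based per occasion: the
question it answers is whether a lineage is shared by all habitats at
all, not how often it is seen. Enlarging the lake set can only shrink
the core (an intersection), and per-sample core read shares plus
complement shares always sum to one — both properties are tested.

## Dissimilarity dynamics

Community change is measured with Bray–Curtis (BC) dissimilarity.
*Turnover* is BC between consecutive *present* occasions of one lake, so
a pair may span a desiccation gap — intentionally, because post-refill
turnover spikes are a real signal of drought-driven community
replacement. *Time distance decay* groups all within-lake pairwise BC
values by time lag. Lake and season effects on composition are tested
with PERMANOVA (sequential sums of squares, raw-observation
permutations; the `vegan::adonis2` engine), environmental association
with Mantel tests, predictor redundancy with a |r| > 0.7 Pearson screen,
and two-group comparisons (e.g. drying vs non-drying lakes) with a
two-sided permutation test on the difference of means — the latter
because no parametric family is assumed for turnover values. All
permutation p-values use the add-one rule and are never zero.

## Local similarity analysis

The association engine scores every OTU pair by *local similarity*
(LS): both series are percentile-Z normalised
(`z = qnorm(rank / (n + 1))`, ties averaged), and a dynamic program
finds the pair of aligned subintervals, offset by at most the delay
limit `D` (default one sampling interval), that maximises the running
sum of products (positive association) or negated products (negative
association), divided by the series length. Because each DP cell depends
only on its diagonal predecessor, the program decomposes into
independent one-dimensional passes per delay; an exhaustive
window-enumeration oracle pins the implementation exactly in the tests.
The reported delay is `start_x − start_y`; score ties resolve to the
smallest |delay| (a synchronous reading is preferred when the data
cannot distinguish), then to the positive sign, then to the earliest
window.

Missing occasions are linearly interpolated before normalisation
(terminal gaps take the nearest observed value), and the number of
interpolated points is carried into every edge record so downstream
users can discount gap-heavy edges. Series with fewer than six genuinely
observed points, or constant series, are excluded.

Significance is by permutation of one series' time order; the same
shuffle stream also yields the null for the *shifted Spearman rank
correlation* (SSCC) evaluated at the LS-optimal delay — the global
counterpart of the local score. Both p-value families (LS and SSCC) are
separately Benjamini–Hochberg corrected across all pairs, and an edge
requires `p < α` *and* `q < α` (default α = 0.01) in at least one
family. Edges whose global statistic passes are typed `SSCC`, the rest
`LS`; a global association subsumes a local one. Delay-0 edges form the
*synchronous* network, |delay| ≥ 1 edges the *time-shifted* network.
BH was chosen over Storey's q-value for its lack of tuning parameters at
the small family sizes typical here (hundreds of pairs); the FDR method
is configurable.

Two practical notes on power. First, with T = 14 occasions the
permutation p of a single pair is bounded below by 1/(n_perm+1), and the
BH q-value of k discoveries among m pairs is roughly p·m/k, so sparse
studies need n_perm of order 10^4 for q < 0.01 to be attainable at all —
the pipeline default (1000) suits dense seasonal networks, and the
recovery analyses use 9999–19999. Second, correlation networks are
transitive: several followers of one driver are themselves strongly
mutually correlated (at the product of couplings), so a "star" of
synchronous couplings is inferred as a clique. Genuine star topologies
arise in the time-shifted network, where follower–follower correlations
land at lag 0 or lag 2 and are excluded by the delay limit.

## Weighted topological importance and keystones

Node importance uses the weighted topological importance index: with
`D_i = Σ_j |w_ij|`, the one-step effect of j on its neighbour i is
`a_ij = |w_ij| / D_i` (each node divides its attention among neighbours
by interaction strength), m-step effects are the matrix power `A^m`
(walks, revisits allowed), `σ_m,j` sums the m-step effects of j on all
*other* nodes, and `WI^n_j` averages `σ_1..σ_n`; keystone calls use
n = 3. The index family has variants (path vs walk counting, diagonal
handling); the convention above is pinned exactly by a walk-enumeration
oracle in the tests, and two hand-derivable cases anchor intuition: a
single edge gives both endpoints WI³ = 2/3, a three-leaf star gives the
centre 2 and each leaf 4/9. Edge signs do not enter WI (absolute
weights); instead each keystone is classed *positive* or *negative* by
the sign of its summed signed incident weights, reflecting whether it is
rich in positive or negative associations. Keystones are nodes with
WI³ > 1, expanded to WI³ ≥ 1 when fewer than six qualify — the
expansion only matters at exactly 1.0 and is implemented literally.

Each OTU's *preferred season* is classified two ways, matching two
published conventions: the *relabund* rule (a season qualifies when its
mean relative abundance exceeds the study mean by more than the
population SD of the whole series) colours network nodes; the *zscore*
rule (the season with positive mean z-scored abundance) annotates
keystone heatmaps. Zero qualifying seasons give `"none"`; more than one
gives `"unspecified"` (explicit in the zscore convention; adopted for
relabund as well since a multi-season "preference" is no preference).

## The synthetic benchmark

`generate_study()` emulates the study design: 5 lakes × 14 fortnightly
occasions (spring 1–4, summer 5–10, autumn 11–14), a shared core plus
lake-specific non-core taxa, latent log-abundances with Gaussian
seasonal bumps (`baseline + amplitude·exp(−(t−peak)²/2w²) + noise`),
two drying lakes (occasions 11,13 and 7,8,10,11,13) whose first wet
occasion replaces a fraction φ of community mass with that lake's
non-core taxa, and multinomial read sampling at fixed depth. Planted
associations follow
`b_t = ρ(±a_{t−delay}) + sqrt(1−ρ²)·ε_t`
on the standardised latent scale; the driver series is standardised to
unit latent sd as well, so pair recoverability reflects ρ and read
sampling rather than an arbitrary driver amplitude. Default magnitudes
(log-baseline sd 0.7, amplitudes 1–2.5 giving up to ~12-fold seasonal
swings, latent noise sd 0.3) mirror the order of seasonal change
reported for real soda-pan phytoplankton, where dominant lineages move
over tenfold in relative abundance between seasons.

What the generator does *not* emulate: overdispersion beyond
multinomial sampling (a Dirichlet concentration hook exists but is off
by default), taxon-specific detection biases, and — importantly — it
*does* impose compositional closure. Closure matters for interpreting
recovery rates: the total latent mass fluctuates seasonally (log-sd
≈ 0.2 under the defaults), and dividing every OTU by it perturbs
observed rank correlations. Together with the rank fragility of smooth
seasonal series at T = 14 (long flat off-season stretches produce
near-tied ranks), the realised count-scale correlation of a pair planted
at ρ = 0.9 has mean ≈ 0.77 with a quarter of realisations below 0.7 —
even at infinite sequencing depth the mean is only ≈ 0.82. Since the
q < 0.01 edge criterion at T = 14 requires realised |ρ| ≳ 0.73,
planted-edge recall saturates near 0.5–0.7 under these study
conditions, with sign and delay-class essentially always correct for
recovered edges. Recall approaching 0.9 is reachable only for
iid (non-seasonal, non-compositional) couplings; passing or failing a
recall benchmark therefore says as much about the realism of the
benchmark's seasonality and closure as about the inference engine.

## Numerical and reproducibility choices

Every stochastic step takes an explicit integer seed; derived seeds are
small offsets of the master seed (per sample for rarefaction, per pair
for permutation streams, per stage in the pipeline), so adding or
removing one lake or OTU does not silently shift another's stream. Score
ties in the LS traceback and the keystone threshold are resolved by the
fixed rules above; degenerate inputs (constant series, all-zero samples,
empty networks, single-level factors) raise errors or warnings rather
than propagating NaNs. The pipeline writes deterministic TSV/GraphML
artifacts plus a JSON manifest, and rerunning a configuration with the
same seed reproduces every artifact byte for byte.

Problem sizes used by the test-suite simulations (40 OTUs × 14
occasions, depths 2000–5000, 200–2000 null replicates, 5–20 seeds per
recovery experiment) were chosen to make simulation-based checks
reproducible on a laptop in minutes while keeping binomial confidence
intervals tight enough for the calibration bounds they assert.

## Known limitations

- PERMANOVA and Mantel inherit `vegan`'s conventions (sequential SS,
  raw-row permutation); restricted permutation designs for repeated
  measures are not implemented, so within-lake temporal autocorrelation
  is not accounted for in those global tests.
- eLSA-style theoretical (asymptotic) p-values are not implemented;
  significance is permutation-only.
- The SSCC is evaluated at the LS-optimal delay (configurable in
  principle, fixed in this release); a pair whose LS delay is misled by
  noise is tested at that delay.
- The EC→salinity conversion implements the published regression as
  printed (`0.792·EC + 179`); the intercept is almost certainly a
  typographic slip (0.179 would be physically plausible for these
  waters), so the function warns and both coefficients are arguments.
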