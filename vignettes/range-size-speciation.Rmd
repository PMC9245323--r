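---
title: "Range size, speciation mode, and the rangediv pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range size, speciation mode, and the rangediv pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangediv)
```

## The scientific question

Whether large geographic ranges promote speciation is an old and unsettled
question. The expected answer depends on the mode of allopatric speciation:
where vicariant splitting dominates (large continental landmasses), bigger
ranges offer more room for barriers to bisect them, predicting a positive
range-size effect; where peripatric, dispersal-driven colonization dominates
(island archipelagos), dispersal ability rather than range size should drive
speciation, and island ranges are structurally small. Body size and position
(latitude, longitude, island versus continent) influence both range size and
dispersal, so any credible test must treat the whole variable system
jointly. `rangediv` implements that test battery for a single clade:
tip-level speciation rates, phylogenetic regressions with island
interactions, a structural path model, state-dependent diversification
models with character-independent nulls, a nonparametric tip-rate test, and
a joint spatial-phylogenetic mixed model.

## Models and estimators

### Tip rates

The DR statistic for tip $i$ inverts the equal-splits measure
$ES_i = \sum_{j} l_j (1/2)^{j-1}$, the weighted tip-to-root path length in
which each successive split toward the root halves an edge's weight
(pendant edge $j = 1$; a root edge is excluded, the conventional choice).
DR is a nonparametric proxy for recent speciation rate: it needs no rate
model, which is why it serves as the response everywhere a continuous rate
is regressed. Logs are natural logs throughout (recorded in the table
metadata); the log base only rescales coefficients.

### λ-PGLS

Regressions use generalized least squares with residual covariance
$\sigma^2 C(\lambda)$, where $C_{ij}$ is the shared root-to-tip path length
of tips $i, j$ and $\lambda \in [0, 1]$ multiplies the off-diagonals.
$\lambda$ is estimated by maximizing the profile likelihood (full ML, not
REML — the choice is recorded in every fit object since the two differ
slightly in small samples) with a bounded scalar search at tolerance
$10^{-6}$ plus explicit endpoint evaluation, because $\hat\lambda$ lands on
0 or 1 frequently; ties within $10^{-8}$ log-units break toward the
interior. Predictors are z-scored first so effect sizes are comparable;
the response is never standardized. Coefficient tests are two-sided t tests
on $n - p$ degrees of freedom, reported without multiple-testing
correction. The λ transform is restricted to ultrametric trees, where
preserving the diagonal is well defined.

The island/continent analysis follows a two-step logic: fit the full model
with setting-by-predictor interactions, then (when the interaction matters)
refit separately within island and continental species on pruned trees that
keep their branch lengths.

### Path model

The structural system ships as a directed acyclic graph: position
(absolute latitude/longitude, island flag) acts on body size, dispersal
(hand-wing index) and range size; body size acts on dispersal (that edge's
direction is configurable); body size and dispersal act on range size and
range shape; and everything acts on the speciation rate, which is a sink.
Each endogenous variable is regressed on its parents by λ-PGLS and an edge
is called positive/negative/undetermined by whether its 95% interval
excludes zero. This is a deliberate estimator choice: a joint Bayesian
multivariate system would estimate the same per-equation coefficients for
a DAG with independent equation errors, but per-equation ML keeps the
machinery light and the intervals analytic. The swap is recorded in every
fit object. A parametric bootstrap (default 200 draws when enabled) is
available where the t-based intervals are in doubt.

### State-dependent diversification

The BiSSE likelihood integrates, along every branch, the coupled ODEs for
the extinction probability $E_s(t)$ and the conditional likelihood
$D_s(t)$ of a lineage in state $s$, combining daughters at each node with
the state's speciation rate. HiSSE adds a hidden binary factor, giving
latent states 0A, 1A, 0B, 1B with tip ambiguity over the hidden component
and structural zeros for simultaneous observed-and-hidden transitions. The
integrator is a compiled adaptive Cash-Karp Runge-Kutta 4(5) with relative
tolerance $10^{-8}$ (absolute $10^{-10}$); branches of length zero are
collapsed to $10^{-9}$ inside the integration only. Correctness rests on a
factorization identity used throughout the tests: with state-independent
rates the joint likelihood is exactly (constant-rate birth-death
likelihood) x (Mk character likelihood), and both factors have closed
forms implemented independently of the ODE core.

At the root, states are weighted by their conditional likelihoods by
default (weighting by relative plausibility of each root state), with flat
weighting as an option, and no conditioning on survival unless requested —
both switches are recorded in fits, since the literature varies and the
choice shifts log-likelihoods.

The model battery holds 20 models. Sixteen are hidden-state models crossing
speciation structure (all four latent rates free, or hidden heterogeneity
only on observed state 1), extinction structure (single rate or four free),
and transition structure (all equal; observed-vs-hidden two-rate;
asymmetric observed flips plus one hidden rate; all eight free). Because no
canonical list of sixteen variants exists, this enumeration is this
package's own, chosen to span the transition-matrix constraints
systematically. The four nulls are character-independent: two CID-2 models
(speciation tied to a two-level hidden factor only; six free parameters,
deliberately matching the plain binary model) and two CID-4 models (eight
latent states, four-level hidden factor). Models are compared by AIC and
Akaike weights $w_i \propto \exp(-\Delta_i/2)$. Individual transition-rate
estimates are flagged unreliable below 800 tips; the analysis surface is
the weight table, not the rates. Free parameters are optimized in log
space by bounded quasi-Newton search with seeded multistart (default 5
starts); speciation and extinction rates are bounded in $[10^{-6}, 10^3]$
per unit tree depth, transition rates in $[10^{-6}, 10^2]$ — beyond ~100
expected flips per tree depth a binary character is statistically
indistinguishable from random while the ODEs become needlessly stiff.

The FiSSE-style test avoids likelihood models entirely: the statistic is
the difference in mean tip DR between states, and its null distribution
comes from neutral binary characters simulated on the same tree under a
symmetric Mk process whose rate is fitted to the observed pattern by 1-D
maximum likelihood (the original test calibrates by parsimony; ML is this
package's choice, recorded in the result object). The two-tailed p-value
uses the +1 small-sample correction and is therefore never exactly zero.

Threshold rules for binarizing range size: empirical median and quartiles,
a fixed cut, and a quartile-grouping mode that contrasts the outer
quartiles against the interquartile range. "Small" means strictly below
the threshold; ties sit in the upper state.

### Spatial-phylogenetic model

Speciation rate is modelled as
$y = X\beta + u_{phylo} + u_{spatial} + \varepsilon$ with
$u_{phylo} \sim N(0, \sigma^2_p C_{std})$ on the determinant-standardized
covariance ($\det C_{std} = 1$, asserted before every fit — this pins the
scale of $\sigma^2_p$ so variance components are comparable) and
$u_{spatial} \sim N(0, \sigma^2_s K)$ under a Matérn kernel
(smoothness fixed at 1.5 — a once-differentiable field — range $\rho$
estimated). Two deliberate simplifications relative to a full latent
Gaussian field treatment: the spatial field is evaluated at one
representative coordinate per species (range centroid or midpoint) rather
than integrated over an occurrence mesh, and inference is ML with Wald
intervals rather than posterior marginals. Both are recorded in the fit.
The total variance is profiled analytically and the optimizer works on the
three variance shares plus $\log\rho$; boundary models (no spatial term,
no phylogenetic term, neither) are always evaluated too and the best kept,
so the reported optimum never dips below a boundary. With the spatial
share at zero the model family coincides exactly with λ-PGLS on the
depth-1 tree — the reduction identity the tests exploit.

### Range geometry

All geometry is planar on equal-area-projected coordinates in km; the
package does no map projection (projection choice is upstream metadata).
Area is the shoelace sum over parts with holes subtracting; the perimeter
counts every ring; the shape index area/perimeter makes disjunct or
elongated ranges score low because splitting a range keeps area but adds
perimeter. Bounding-box midpoints (not area-weighted centroids, which are
computed but only exported) feed the regressions as position variables.
Island versus continental classification is any-overlap against a mask
polygon. Hand-wing index averages per-individual measurements before
taking 100 x Kipp's distance / wing length. Missing continuous traits are
imputed by the Brownian conditional mean given observed tips; body mass
can instead be gap-filled by genus means, mirroring the two distinct
procedures used for morphometric compilations.

## The synthetic-data generator

`generate_clade_dataset()` emulates a honeyeater-sized radiation: 192
species with a 68/192 island fraction by default, a pure-birth tree
rescaled to depth 1 (the fixed-root calibration), and log-normal range
sizes per setting (island location log(2e4), spread 1.2; continental
log(3e5), spread 1.6). Those location/spread choices reproduce the
qualitative facts the analyses lean on: right-skewed ranges spanning
roughly $10^2$ to $10^7$ km², island ranges systematically smaller, and
roughly 9 in 10 island species below $10^5$ km² while most continental
species sit above it. Trait covariances are induced by a linear structural
simulation following the hypothesized diagram (position and setting to
body size and dispersal, body size to dispersal, everything to range size
and shape), with phylogenetically correlated residuals (Pagel's λ 0.7 by
default) and user-settable coefficients — the field's theory fixes signs,
not magnitudes, so the defaults are moderate standardized effects near
0.2–0.3. The island flag is drawn i.i.d. by default, with an Mk-evolved
alternative; both regimes matter because a phylogenetically clustered flag
is exactly the situation in which naive tip-rate tests over-reject.

What the generator does *not* emulate: real range polygons (ranges are
scalar areas unless polygon fixtures are supplied), occurrence-record
sampling bias, trait measurement error, and any coupling of tip rates to
traits under the default pure-birth tree — rate-trait coupling requires
the state-dependent simulator. Passing tests on synthetic data therefore
demonstrate estimator correctness and calibration, not that any particular
empirical clade behaves this way.

## Numerical choices and degenerate inputs

- Tree depth is always rescaled to 1; all rates are per unit tree depth.
- The SSE simulator is an exact Gillespie event simulation stopping just
  before the first event after the target tip count (keeping pendant edges
  positive), with up to 100 restarts on extinction or monomorphism.
- Likelihood scaling: per-branch renormalization of $D$ with accumulated
  log-compensators, so 300-tip HiSSE likelihoods stay in range.
- PGLS solves by Cholesky whitening; rank-deficient designs and non-PSD
  covariances are rejected with explicit messages; data align to trees by
  tip label everywhere, never by row order.
- Duplicate spatial coordinates get a $10^{-6}$ diagonal jitter; constant
  columns refuse to standardize; constant inputs refuse to binarize.
- Problem sizes in the test suite (500 trees for the DR oracle, 100
  replicates at n = 200 for PGLS and the spatial model, 30 replicates at
  n = 300 for model selection with a 3-model subset, 200 replicates for
  FiSSE calibration) were chosen as the smallest runs that make the
  Monte-Carlo bands in those checks meaningful.

## Known limitations

- No Ornstein-Uhlenbeck or other residual structures in PGLS; λ only.
- No GeoSSE/MuSSE/QuaSSE generalizations; no ancestral-state
  reconstruction; the SSE surface is model comparison, not rate estimation
  (and transition rates are flagged unreliable below 800 tips).
- The path model assumes the supplied DAG; no structure search or
  d-separation testing.
- The spatial model's one-coordinate-per-species support understates
  within-range spatial averaging for wide-ranging species.
- Polygon handling assumes simple (non-self-intersecting) rings in a
  planar equal-area projection supplied upstream.
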