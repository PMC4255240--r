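---
title: "Laminar origins, SLN, and the estimation of cortical hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar origins, SLN, and the estimation of cortical hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The quantity being modeled

Retrograde tracer injected into a cortical area labels the neurons that
project to it. In each source area the labeled neurons divide between the
supragranular layers (layers 1–3, above the granular layer 4) and the
infragranular layers (5–6). The supragranular fraction

\[ \mathrm{SLN} = \frac{S}{S + I} \]

is a robust signature of a pathway's hierarchical direction: feedforward
(FF) pathways ascend the hierarchy from supragranular parent neurons
(SLN → 1), feedback (FB) pathways descend from infragranular ones
(SLN → 0). `lamhier` treats SLN as a graded measure of hierarchical
*distance* and estimates a continuous hierarchy from it.

Two conventions are fixed package-wide. SLN is stored as a fraction in
[0, 1]; files use percent, and the conversion happens only at the I/O
boundary (`read_connectivity` / `write_connectivity`), so a silent
100-fold error cannot propagate. Replicate injections of the same pathway
are pooled by summing supra- and infragranular counts and recomputing SLN
from the totals (`pool_injections`), which weights each injection by its
size; the mean of per-replicate SLN values is *not* used.

## The hierarchy model

For a projection from area $i$ to area $j$, the expected SLN is modeled as

\[ \mu_{ij} = \Phi(\beta_j - \beta_i), \]

with $\Phi$ the cumulative standard normal (probit link) and $\beta$ the
per-area hierarchical levels. Stacking one row per projection gives
$\mu = \Phi(X\beta)$ where $X$ is the incidence matrix of the cortical
graph: $-1$ at each edge's source column, $+1$ at its target column
(`build_incidence`). Every row of $X$ sums to zero, so one column is
deleted and the corresponding reference area (V1 by convention) is fixed
at level 0; the hierarchy is identified only up to affine transformation,
and reported levels are mapped to a conventional 1–10 scale
(`rescale_levels`), which rescales the standard errors by the same factor
and leaves predictions untouched (they are always computed from the
unscaled levels).

Labeled-neuron counts are overdispersed relative to a binomial, so the
supragranular count $k$ of $n$ labeled neurons follows a beta-binomial
with mean $\mu$ and dispersion $\varphi \in [0, 1)$, parameterized through
beta shape parameters $a = \mu(1-\varphi)/\varphi$,
$b = (1-\mu)(1-\varphi)/\varphi$. This parameterization is chosen because
it yields the variance of the estimated proportion

\[ \operatorname{Var}(k/n) = \tfrac{1}{n}\,\mu(1-\mu)\,(1 + (n-1)\varphi), \]

which the test suite verifies by Monte Carlo. At $\varphi = 0$ the
binomial limit is taken analytically (`betabin_logpmf`). A binomial GLM
(no dispersion) and a binary-response variant are deliberately not
offered: with the large counts typical of tracing data the former yields
unrealistically small standard errors and the latter discards almost all
the information.

### Numerical choices

* **Optimization.** The negative log likelihood is minimized over
  $(\beta, \operatorname{logit}\varphi)$ — the logit keeps $\varphi$
  inside (0, 1) — by Nelder–Mead (relative tolerance $10^{-8}$, restarts
  from the incumbent), followed by a BFGS polish that is kept only when it
  improves the objective. The polish matters: in the 10–40 dimensional
  problems typical here, Nelder–Mead alone can stall visibly short of the
  optimum (the test suite cross-checks the polished solution against an
  independent beta-binomial fitter, glmmTMB, to $10^{-3}$).
* **Standard errors** are square roots of the diagonal of the inverse
  Hessian of the negative log likelihood, computed by central finite
  differences on the natural $(\beta, \varphi)$ scale with a relative step
  of $10^{-4}$.
* **Degenerate inputs.** The graph must be connected on its undirected
  support: `fit_hierarchy_betabin` refuses a disconnected graph naming the
  stranded component, while the high-level `fit_hierarchy` drops areas
  unreachable from the reference with a warning. $\mu$ is clipped to
  $[10^{-9}, 1-10^{-9}]$ inside the likelihood to keep extreme level
  differences finite.
* **Probit of boundary SLN.** `probit_sln` clips its argument to
  $[\varepsilon, 1-\varepsilon]$, default $\varepsilon = 0.005$,
  before applying $\Phi^{-1}$; exact 0 and 1 occur in real tables and have
  infinite probits. The bound is configurable; results in the mid-range
  are insensitive to it.

### Fitting tables that publish SLN but not counts

The packaged SLN/distance table (`load_table2`) prints pooled SLN
percentages without the underlying counts. For beta-binomial fits on such
tables, `fit_hierarchy` synthesizes $k = \operatorname{round}(\mathrm{SLN}
\cdot n_{\mathrm{eff}})$, $n = n_{\mathrm{eff}}$ per edge (default
$n_{\mathrm{eff}} = 100$) and flags the result `approximate`. The choice
of $n_{\mathrm{eff}}$ trades off how strongly each edge constrains the
fit against the dispersion estimate absorbing the discreteness; because
every edge gets the same $n$, the relative weighting of edges — the main
thing the counts would add — is lost, and such fits should be read as
SLN-only approximations.

### The identity-link alternative and model comparison

With an identity link the model $Y = X\beta$ is solved by ordinary least
squares on raw SLN (`fit_hierarchy_linear`), the classical approach in
which SLN differences are read directly as hierarchical distances; its
predictions are clipped to [0, 1]. `compare_models` compares the two fits
by the Pearson correlation between observed and predicted SLN. The two
correlations share the observed variable, so no off-the-shelf independence
test applies; the default is a bootstrap over edges: the difference
$r_a - r_b$ is recomputed over resampled edge sets and the statistic is
the observed difference divided by its bootstrap standard deviation. The
method is recorded in the result, the resampling is seeded, and the output
is *not* comparable to any single published test statistic — the published
analysis does not state the test behind its comparison, so this package
makes its own choice and says so.

## Pairwise correlation analyses

If SLN differences measured hierarchical distance exactly, SLN values from
two injections plotted over their common source areas would fall on a line
of unit slope; if the SLN "ruler" merely stretches between injections, a
line of arbitrary slope. `common_source_pairs` extracts the paired values
(excluding the two injected areas themselves), `fit_line` fits the
unit-slope line (intercept = mean difference) and the major-axis line (the
first principal axis of the centered pairs, dually minimizing distance in
both coordinates), and `sln_correlation_matrix` assembles the pairwise
Pearson matrix on the raw or probit scale. Pairs supported by fewer than
`min_support = 3` common sources are reported missing — a correlation over
two points is a ±1 artifact, and the published matrices themselves contain
no such entries.

The two published correlation matrices ship as fixtures (`load_table3`,
`load_table4`) and are the reference for summary statistics
(`correlation_summary`, quartiles by linear interpolation at
$1 + (m-1)p$ — R's default type 7 — which reproduces the published
interquartile ranges exactly). Recomputing the matrices from the packaged
SLN table is only a broad-pattern diagnostic: the published inclusion
rules (which sources entered each pair, and at what pooling stage) are not
stated, and the test suite asserts pattern-level agreement only.

## Weight–distance rules

Projection weight is measured by FLN, the fraction of all labeled neurons
of an injection found in a given source area. Connection weights fall
roughly exponentially with white-matter distance, and the package analyses
weights on the log10 scale by default (identity available).

* `fractionate_fln` splits a pathway's FLN into laminar parts
  $\mathrm{SLN}\cdot\mathrm{FLN}$ and $(1-\mathrm{SLN})\cdot\mathrm{FLN}$;
  they sum to FLN exactly.
* `fit_distance_rule` regresses both laminar series on distance jointly
  for one direction (FF or FB), with one intercept shared between the two
  layer series and a slope per layer. Two nested-RSS F tests are reported:
  `f_stat` compares the shared intercept against separate intercepts (3 vs
  4 parameters), and `f_slope` compares a common slope against separate
  slopes within the shared-intercept family (2 vs 3 parameters) — the
  degrees of freedom of these two tests match the two F statistics
  published for this analysis. "Common intercept at the origin" is read as
  a shared intercept at distance 0; a zero-intercept variant sits behind
  `zero_intercept = TRUE` with no claim about which the published fits
  used. Zero fractions under the log transform are floored at half the
  smallest positive fraction, with a warning. If the constrained model
  fits perfectly (zero residuals), both F statistics are reported as
  carrying no evidence rather than as 0/0.
* `fit_fln_sln_parabola` fits the quadratic of log10 FLN on SLN with a
  pointwise standard-error band: near-lateral pathways (SLN ≈ 0.5) are
  short and heavy, pathways crossing many levels are long and weak, so the
  parabola opens downward with its vertex near mid-SLN.
* `incidence_by_distance` and `fln_balance_by_distance` count FF/FB
  pathways and compare their summed FLN percentages per half-open distance
  bin `[lo, hi)`; the balance summary is the median across target areas
  with the raw median absolute deviation (no consistency constant) as the
  error measure.

### FF/FB classification

Two conventions exist in this literature and the package implements both
(`classify_pathways`): the banded rule (FF: SLN ≥ 0.55; FB: SLN ≤ 0.45;
between: unclassified, and *excluded* from FF/FB counts rather than
assigned to the nearest band) and the simple 0.5 cut. The banded rule is
the default for incidence analyses. On the packaged table the two rules
give materially different FB:FF ratios (2.49 banded vs 2.23 at the 0.5
cut, both computed by `scripts/acceptance.R`), which is why the command
line reports both rather than adjudicating.

Exact area-name matching is deliberate: the combined label `TH/TF` used
for some projections matches neither `TH` nor `TF` of the 40-area
reference list, because no published rule says how to split such rows, and
exact matching reproduces the published pathway count. Downstream
operations take explicit area filters instead of guessing; the packaged
table also lists sources outside the 40-area list (e.g. TPt, PGa, CORE),
and whether any published analysis beyond the hierarchy fit excluded them
is not stated.

## Laminar depth profiles

Within the supragranular layers, FB parent neurons concentrate above FF
parent neurons. `fit_depth_split` formalizes the compartment boundary as a
regression stump: an exhaustive search over midpoints between adjacent
depth bins for the single split minimizing the summed squared deviation of
counts from the two segment means. Only depth is a split candidate and
only one split is fitted — the analysis this mirrors reports a single
compartment boundary per stream, and deeper trees are out of scope. Ties
break toward the smallest threshold for determinism; a constant profile
returns a no-split result. The stump agrees with an `rpart` stump on
non-degenerate profiles (cross-checked in the tests), and its threshold is
invariant to rescaling the counts.

## The synthetic-data generator

`simulate_tracing` inverts the fitted model: levels $\beta$ (given, or
uniform on a configurable span), edges realized independently per ordered
pair, $k \sim \mathrm{BetaBinomial}(n, \Phi(\beta_j - \beta_i), \varphi)$
per edge, and weights $w = A_{\mathrm{dir}} e^{-\lambda_{\mathrm{dir}} d}
\cdot \mathrm{lognormal}$ noise, normalized so FLN sums to one per target.
Defaults are matched to the packaged dataset where it measures them:

* `n_areas = 11` — the number of injected targets;
* `edge_density = 0.9` — the packaged table realizes 99 of the 110 ordered
  pairs among its 11 injected areas;
* `level_span = 2.5` probit units — spans the observed SLN range through Φ;
* `phi = 0.1` — dispersion of the order estimated from count-level tracing
  data;
* `counts_per_edge = 100` — the same effective count as the SLN-only
  fitting default;
* `box_mm = 40` — uniform area centers in a 40 mm cube give pairwise
  distances of roughly 4–46 mm, matching the packaged distance column
  (3.6–46.4 mm);
* `edr_lambda = 0.19` per mm — the canonical exponential-distance-rule
  decay for this species;
* `noise_sd_logfln = 1` — about one natural-log unit of weight scatter.

Direction-specific decay and amplitude knobs (`edr_lambda_ff/fb`,
`edr_amp_ff/fb`) let the two weight curves cross, reproducing the
counterstream distance rule (strong but fast-decaying FF, weak but
persistent FB) for demonstrations; `fb_bias` tilts edge realization toward
descending pathways to mimic the observed FB preponderance. Both are off
by default. One integer seed governs everything through deterministic
per-stage substreams; the same configuration always regenerates the
identical dataset, and the caller's RNG state is restored.
`generate_depth_profiles` draws Poisson counts around two Gaussian bumps
on the normalized 0–100 depth axis (FF center 30, FB center 70, sd 12) for
the stump analysis.

What the generator deliberately does **not** emulate: spatially extended
injection sites, per-neuron depth charts, double labeling, anterograde
(terminal-layer) patterns, and any correlation between an area's level and
its spatial position. Passing the recovery tests therefore shows that the
estimator inverts its own generative model at realistic scale — not that
real cortical data satisfy that model.

## Validation strategy and problem sizes

The published quantities that can be recomputed from shipped fixtures are
asserted exactly: the 339-pathway count, and every summary statistic of
the two published correlation matrices. The published model outputs that
*cannot* be recomputed (the fitted hierarchy values, the published F and z
statistics) depend on per-injection counts and FLN values published
elsewhere; the machinery behind them is validated on synthetic data
instead: likelihood normalization to $10^{-10}$ and the binomial limit to
$10^{-8}$ on parameter grids; the variance formula by $10^5$ Monte-Carlo
draws within three standard errors; level recovery on twenty 11-area
datasets at the defaults above (mean correlation with truth ≥ 0.95
required; observed ≈ 0.99) with 1.96-SE interval coverage required inside
90–99%; the least-squares fit against an explicit normal-equations solve
to $10^{-10}$; the distance-rule F statistic against a brute-force
nested-RSS computation to $10^{-9}$; and the depth stump against
exhaustive enumeration on randomized profiles. These sizes keep the whole
suite to a few minutes on one core while leaving the Monte-Carlo checks
comfortably powered.

## Known limitations

* The beta-binomial ML dispersion estimate is biased low at small edge
  counts (as ML variance components are); at the default study scale this
  shows up as interval coverage a little below nominal (the low 90s rather
  than 95%).
* Fits from SLN-only tables inherit the fixed effective count described
  above; their dispersion estimate absorbs both biological overdispersion
  and transcription rounding, and should not be compared to count-level
  fits.
* Wald intervals on a reference-anchored hierarchy are correlated across
  areas: mis-estimating the reference area's neighborhood shifts all
  levels together.
* The pairwise correlation matrices recomputed from the pooled SLN table
  do not reproduce the published matrices cell-for-cell (the published
  inclusion rules are unstated); the fixtures are authoritative, the
  recomputation is a diagnostic.
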