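---
title: "Models and methods for MET stability analysis with metstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for MET stability analysis with metstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The data and the model

metstab analyses balanced multi-environment trials: `g` genotypes grown in
`e` environments (location × year combinations), each laid out as a
randomized complete block design with `r` blocks. The plot-level model is

$$Y_{ger} = \mu + \alpha_g + \beta_e + \sum_n \lambda_n \gamma_{gn} \delta_{en}
          + b_{r(e)} + \varepsilon_{ger},$$

where $\mu$ is the grand mean, $\alpha_g$ and $\beta_e$ are centered
genotype and environment main effects, the multiplicative sum is the
genotype-by-environment interaction (GEI) written as a singular value
decomposition of the double-centered cell-means matrix, $b_{r(e)}$ is a
block effect nested in environment, and $\varepsilon$ is plot noise. All
yields are treated as g m⁻² and units are carried as documentation only.

Everything downstream consumes the `g × e` cell-means matrix
(`cell_means()`): replicates are averaged within each (genotype,
environment) cell, and the marginal means define $\mu$, $\alpha_g$,
$\beta_e$. The package requires a complete balanced table; missing plots are
a design failure the user must resolve explicitly, not something to impute
silently.

## Joint ANOVA and the AMMI decomposition

`met_anova()` partitions the plot-level sum of squares into ENV, REP(ENV),
GEN, GEN:ENV and Residuals. Environments are tested against the
replicate-within-environment stratum (blocks are the replication unit for
environment contrasts); genotypes and the interaction against the pooled
residual. `ss_proportions()` reports the shares of the three-way
ENV + GEN + GEN:ENV total, the conventional summary of how much of the
treatment variation each source carries. When the residual mean square is
zero to machine precision (identical replicates, a situation that arises
with noise-free synthetic data), F is reported as `+Inf` with p = 0 rather
than failing.

`fit_ammi()` decomposes the double-centered means by SVD. The bookkeeping
identities it guarantees (and the tests pin):

* plot-level axis sum of squares $r\lambda_k^2$, summing exactly to the
  GEN:ENV stratum;
* Gollob degrees of freedom $g + e - 1 - 2k$ per axis, summing to
  $(g-1)(e-1)$;
* axis F-tests against the pooled residual mean square at $\alpha = 0.05$.
  The Gollob test is liberal but matches the one-line-per-axis ANOVA layout
  breeders expect; no multiplicity adjustment is applied across axes.
  Cross-validation-based axis selection is out of scope.

Three numerical conventions are worth stating. First, the default score
scaling is symmetric ($\lambda^{0.5}$ on both genotype and environment
scores), configurable through `score_scaling`; nothing downstream depends on
the choice because WAAS uses axis-share weights and the geometry tests are
scaling-invariant. Second, axis signs are fixed by making the
largest-magnitude environment loading positive (first index on ties), so
plots and tables are reproducible across SVD implementations; all statistics
are invariant to sign flips, and the test suite verifies this. Third, a
`ge_matrix` can be fitted directly (means-only mode, `r = 1`): the
decomposition is produced without F-tests, which is what makes hand-sized
worked examples checkable.

## GGE biplots

`fit_gge()` centers columns by environment means (optionally scaling by the
environment standard deviation; centering-only is the default, the most
common GGE form) and keeps the first two axes. Singular value partitioning
(SVP) is configurable: symmetric for the which–won–where view, genotype-
focused for mean-vs-stability — the standard practice for each view. The
genotype·environment inner products are identical under every SVP mode, so
sector winners and rankings do not depend on it.

`which_won_where()` builds the convex hull of the genotype points. The
classical construction draws rays from the origin perpendicular to hull
edges; equivalently (and this is how it is computed and tested), each
environment belongs to the hull vertex maximizing its inner product, which
is also the genotype the rank-2 model predicts to win that environment.
Environments exactly on a boundary go to the lower-indexed sector —
a deterministic tie rule that can only matter on constructed data.
Collinear or coincident genotype points have no polygon and raise a
degenerate-geometry error.

`mean_vs_stability()` projects genotypes onto the average environment axis
(AEA, the direction of the mean environment point). The projection is the
modeled mean performance; the signed perpendicular component is the
instability; the "ideal" genotype sits on the AEA at the largest observed
projection, and genotypes are ranked by Euclidean distance to it. If the
mean environment point is at the origin the AEA is undefined and an error is
raised (this happens only when environment scores cancel exactly).

## The stability panel

`stability_table()` assembles, per genotype: mean yield; WAAS
($\sum_k |s_{ik}| EP_k / \sum_k EP_k$ over the Gollob-significant axes by
default, where $EP_k$ is the axis share of GEI); Wricke ecovalence
$W_i = \sum_e \hat{ge}_{ie}^2$; Shukla's stability variance (the unbiased
linear transform of $W_i$ — their ranks always coincide, which the tests
assert); Eberhart–Russell joint regression slope $b_i$ and deviation mean
square $S^2_{d,i}$ (the mean slope is exactly 1 by construction);
Annicchiarico's reliability index (mean percent-of-environment-mean minus
$z_{0.75} \approx 0.674$ times its standard deviation — the paper-typical
75% one-sided confidence, configurable via `conf_z`); Lin & Binns
superiority $P_i$; environmental variance, CV and the geometric adaptability
index; Tai's $\alpha_i$ and $\lambda_i$; and Huehn's S1/S2/S3/S6 with
Thennarasu's N1.

Conventions adopted where the literature (or the source material of such
analyses) is silent or ambiguous:

* **Favorable/unfavorable environments** split at the grand mean
  (`classify_environments()`, ties unfavorable), applied identically to the
  Annicchiarico and Lin–Binns sub-variants. Empty subsets yield `NA` columns
  with a warning rather than an error, so one degenerate split does not kill
  the rest of the table.
* **Huehn correction**: S3 and S6 are computed on ranks of
  genotype-effect-corrected values $x_{ie} - \bar x_{i.} + \bar x_{..}$
  (per Huehn's original definitions), S1/S2 and N1 on raw within-environment
  ranks.
* **Tai's statistics** use the replicate-within-environment mean square to
  debias the environmental-effect sum of squares and the pooled residual to
  scale the deviation term; they require `r ≥ 2` and are `NA` otherwise.
  $\alpha_i$ is exactly collinear with $b_i - 1$, so its ranks duplicate the
  regression view — it is reported for completeness.
* **Mean variance component / GE variance component** (Plaisted–Peterson and
  Plaisted statistics) are affine functions of ecovalence; their ranks are
  `Ecoval_R` by identity, so they are not materialized as columns.
* **Rank directions** (`rank_table()`): rank 1 = most desirable. Stability
  indices rank ascending; mean yield, GAI and the Annicchiarico reliability
  index rank descending (a larger reliability index is better — ranking it
  ascending would invert its meaning); the regression slope ranks by
  $|b_i - 1|$ and Tai's alpha by $|\alpha_i|$. Ties get average ranks.
* **GAI** requires strictly positive cell means and errors otherwise — a
  geometric mean of nonpositive yields is meaningless.

The GY × WAAS quadrant classification splits at the mean yield and mean
WAAS; points exactly on a boundary go to the lower-yield / higher-WAAS side,
so fully degenerate inputs land in quadrant I deterministically.

## Rank-profile clustering

`cluster_rank_profiles()` computes squared Euclidean distances between the
genotypes' `_R` rank vectors and agglomerates by Ward's minimum-variance
criterion — the classical form, i.e. `hclust`'s `"ward.D"` linkage applied
to squared distances; `"ward.D2"` on unsquared distances is available by
flag. Merge heights are guaranteed nondecreasing. The number of clusters is
user-supplied (default 8, a typical subcluster count for a few dozen
genotypes); automatic selection by index voting is out of scope. Tie-breaks
in the agglomeration are delegated to `hclust` and are deterministic for a
fixed input order. Dendrograms export to Newick via ape.

## Correlations

`spearman_matrix()` reports Spearman rank correlations with p-values from
the t approximation on $n - 2$ degrees of freedom and conventional
significance stars, without multiplicity adjustment. Pooled scope
concatenates environments at plot level, which deliberately mixes between-
and within-environment variation (the naive pooled analysis); per-
environment and genotype-mean modes expose the partitioned views, since
published overall coefficients may be computed at either level.

## The synthetic generator

`simulate_met()` is generative use of the model above. Main effects are
drawn from normal distributions, centered, and then **exactly rescaled** so
the true-effect sums of squares hit the configured ENV/GEN/GEI partition —
a draw-then-rescale construction, deliberately non-distributional, chosen so
recovery tests can be tight. The GEI is built from `gei_rank` orthonormal,
column-centered axis pairs with singular values set from the axis weights;
axis signs are randomized (both sides flipped, leaving the interaction
unchanged) so downstream code must be sign-invariant. Blocks are drawn per
(environment, replicate) and centered within environment so they do not leak
into the ENV stratum. A single integer seed drives everything; identical
seeds give bit-identical datasets.

Defaults are the package's reference study conditions: `g = 34, e = 8,
r = 3`; fractions `(0.7129, 0.1477, 0.1394)`; four GEI axes at
`(0.889, 0.079, 0.022, 0.010)`; grand mean 700 g m⁻²; total true-effect SS
scaled to a per-plot mean square of 55,000 (g m⁻²)², giving field-realistic
environment means of roughly 500–900 g m⁻²; plot noise SD 22 and block SD
3.2 g m⁻², back-solved from residual and block mean squares typical of such
trials. For smaller designs the GEI rank adapts to `min(4, g−1, e−1)` with
the weight profile renormalized.

`simulate_traits()` adds secondary traits by a Gaussian copula: yield is
mapped to normal scores, each trait's latent variable mixes that score with
independent noise at the Pearson loading $2\sin(\pi\rho_s/6)$ that yields
the target Spearman $\rho_s$ under bivariate normality, and the trait is a
linear (rank-preserving) transform of the latent variable. Defaults target
panicle length 0.825, panicles per plant 0.904, thousand-grain weight 0.491
and sterility −0.6 (a plausibly strong negative association; only its sign
is dictated by the biology).

What the generator emulates: the variance partition, low-rank GEI, block
structure, homoscedastic plot noise, and monotone trait–yield association.
What it does not: crossover-specific interaction patterns, spatial field
trends, heteroscedasticity across environments, non-Gaussian yield tails,
and trait–trait dependence beyond what routing through yield induces.
Passing tests therefore demonstrate correctness of the estimators and
geometry on data satisfying the model's assumptions — not robustness to
messy field data. One tail artifact is worth knowing: with Gaussian effects
at the default scale an occasional plot value (rarely, a cell mean) can be
negative; analysis functions only require balance, but `read_met_table()` /
`validate_met()` enforce non-negative yields for real data, and GAI errors
on nonpositive cell means.

## Problem sizes and determinism in the test suite

The suite exercises hand-sized worked examples (a fully hand-computed 3×3
matrix), brute-force oracles (power-iteration singular values on 5×5
matrices, point-in-triangle convex hulls and rank-2 argmax winners on 200
random 6×4 matrices), and Monte-Carlo recovery at the reference design
(20 seeds of 34×8×3, asserting the environment share within ±2 points, the
first-axis GEI share within ±3 points, and trait correlations within ±0.05
of their targets). All stochastic tests run under fixed seeds. Data-
dependent outcomes of real published trials — which genotype is "ideal",
exact top-eight orders, dendrogram memberships — are qualitative
expectations that depend on raw data not shipped here; the pipeline tests
assert their structural properties (permutation rankings, winners on the
hull, requested cluster counts) instead.

## Known limitations

Unbalanced or incomplete-block designs are rejected, not repaired. The
Gollob F-test is anti-conservative; treat axis significance as a screening
device. The BLUP-based WAASB variant and robust AMMI are not implemented;
WAAS here is the fixed-effect version computed from the AMMI scores. The
biplots are strictly 2-D.
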