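---
title: "Models and methods behind nutridimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nutridimorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nutridimorph` analyses sex-specific responses to dietary
protein-to-carbohydrate (P:C) composition on two fronts: a
differential-expression engine for small designed bulk RNA-seq experiments
(2 sexes × 2 diets × a few replicate libraries of pooled whole animals),
and a nutritional-geometry toolkit for fitness landscapes over nutrient
intake. This vignette records the models, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not
establish.

## The count model

Counts for gene $g$ in library $i$ are modelled as negative binomial,
$y_{gi} \sim \mathrm{NB}(\mu_{gi}, \phi_g)$ with
$\mathrm{Var}(y) = \mu + \phi\mu^2$, and a log-linear mean

$$\log \mu_{gi} = x_i^\top \beta_g + \log(N_i f_i),$$

where $N_i$ is the library size (column sum) and $f_i$ the TMM
normalization factor. Factors follow the trimmed-mean-of-M-values recipe:
the reference library is the one whose 75th-percentile count fraction is
closest to the mean; per library, M and A values are computed on genes
nonzero in both that library and the reference; the most extreme 30% of M
(two-sided) and 5% of A are trimmed by rank; the factor is
$2^{\bar M_w}$ with inverse delta-method variances as weights; and factors
are rescaled to geometric mean 1. Filtering keeps genes with CPM above 1
in at least 3 libraries (the smallest cell size); both thresholds are
arguments.

Low-level fitting is one IRLS per gene (C++/Armadillo) with step-halving
and convergence declared at a relative deviance change below $10^{-8}$
(at most 50 iterations). Linear predictors are clamped to $\pm 40$; genes
whose fitted mean collapses to the boundary (for instance a diet cell
that is all zero) are flagged and excluded from fold-change reporting and
classification totals.

## Dispersion estimation

Dispersions are profiled out before testing using the Cox–Reid adjusted
profile likelihood $\mathrm{APL}_g(\phi) = \ell_g(\hat\beta_g(\phi); \phi)
- \tfrac12 \log\det(X^\top W X)$. The common value maximizes
$\sum_g \mathrm{APL}_g$; tagwise values maximize

$$\mathrm{APL}_g(\phi) + \frac{d_0}{d_{\mathrm{res}}}\,
\overline{\mathrm{APL}}(\phi)$$

on a log-spaced grid around the common value (31 points spanning a
64-fold range either side, with local quadratic interpolation), where
$d_0$ is the shrinkage prior df (default 10) and $d_{\mathrm{res}}$ the
residual df. Estimates are clamped to lie between the gene's raw APL
maximizer and the common value, so the shrinkage direction is guaranteed;
$d_0 = \infty$ returns the common value for every gene. A fixed, moderate
$d_0$ keeps single-gene tests honest at typical effect sizes but leaves
the extreme tail of null p-values slightly heavy compared with an
estimated-prior scheme: genes whose raw dispersion is underestimated by
chance retain some of that underestimate. The realized-FDR guard in the
test suite measures exactly this (see below).

## Term tests and classification

The experiment crosses sex (F/M) and diet (C/P, carbohydrate- vs
protein-rich). Each model term is tested with a nested likelihood-ratio
test at one degree of freedom, with dispersions held fixed across both
fits:

* sex `S`: `~ sex + diet` vs `~ diet`;
* diet `D`: `~ sex + diet` vs `~ sex`;
* interaction `D×S`: `~ sex * diet` vs `~ sex + diet`.

Defining the main-effect tests through model spaces rather than single
columns makes every LR statistic invariant to factor coding (treatment vs
sum contrasts), which the suite verifies numerically. Reported log2 fold
changes use treatment coding with reference female / carbohydrate-rich, so
`logFC_D` is the carbohydrate→protein shift and positive values mean
higher expression on protein-rich food. q-values are BH within term.

At a working FDR $\alpha$ (default 0.05, with 0.1 the conventional
alternative for the sex-limited table), each shared gene falls in one of
the $2^3$ significance cells and one of three headline categories:
concordant (`D` significant, `D×S` not), opposing (`D×S` only), and
sex-biased (both). Detection is raw count ≥ 1 in at least one library
(CPM-based detection is an option); genes detected in only one sex are
analysed within that sex with a diet-only model. For those sex-limited
fits the offsets (library sizes and TMM factors) come from the sex's
*complete* count matrix: a small gene set cannot normalize itself — if
all its members shift together between diets, that shift is signal, not
sequencing depth.

Per-sex fold changes for shared genes refit `~ diet` within each sex,
re-estimating normalization and dispersions inside the subset (a config
switch reuses the full-data estimates instead; the choice matters little
in simulation but subset re-estimation respects the different
compositions of male and female libraries).

## Concordance and overlap

Cross-sex concordance is the Pearson correlation (Spearman optional)
between male and female carbohydrate→protein log2 fold changes within a
gene set, using all genes assigned to the set rather than only per-sex
significant ones. The non-metabolic baseline set is built by taking a
parent term's genes and removing every gene annotated to an excluded term
*or any of its hierarchy descendants*. The bootstrap contrast resamples
genes with replacement independently within target and baseline, reports
95% percentile intervals, and a two-sided empirical p for the difference,
floored at $1/B$; zero-variance resamples are redrawn and counted.

Overlap tests are hypergeometric upper tails over an explicit,
caller-supplied universe (sets are never silently intersected into it),
with expected overlap $n_a n_b / N$ and percent excess
$100(k/\mathrm{exp} - 1)$; a helper intersects two expressed-gene lists to
form the universe for cross-study comparisons, since overlap should only
be judged among genes both studies could have detected. The sample odds
ratio uses the Haldane 0.5 correction only when a zero cell occurs.
Correspondence between two classifications is the Pearson Χ² on their
R×C table (no continuity correction), via `chisq.test`.

## Fitness landscapes

Male and female fitness are measured in different units (egg counts;
proportion of offspring sired), so each sex is Z-standardized across
treatments before surface fitting, and a Gaussian working likelihood is
used on the standardized scale. Following standard selection-gradient
practice, the linear gradients β come from an OLS model with only linear
intake terms, and the nonlinear gradients from a model adding $P^2$,
$C^2$ and $PC$; under the $w = \alpha + \beta^\top z + \tfrac12 z^\top
\gamma z$ convention, $\gamma$'s diagonal is twice the fitted squared-term
coefficients. Output headers state the convention since the factor of two
is a common source of cross-study confusion. Surface prediction and the
analytic stationary point $-\gamma^{-1}\beta$ use the full model's own
coefficients (the linear-only β is a different estimand whenever curvature
is present).

The sex-difference test compares one shared quadratic surface (single
coefficient vector, single variance) against sex-specific surfaces
(separate coefficients and variances), with
$\mathrm{PB} = 2(\ell_{\mathrm{sex}} - \ell_{\mathrm{shared}}) \ge 0$.
Because the published analyses name a parametric-bootstrap statistic
without defining its construction, this likelihood-ratio form is our
interpretation, and both the statistic and the null-generation procedure
are ordinary functions a user can swap. The null distribution simulates
$B$ datasets from the fitted shared model with Gaussian residuals at its
MLE variance and *re-standardizes each replicate within sex* before
refitting; this step is essential — the per-sex z-transform imposes an
exact mean-0/SD-1 constraint per sex which is part of the observed
statistic's sampling distribution, and omitting it inflates the type-I
error from ~0.05 to ~0.13 in our simulations.
$p = (1 + \#\{\mathrm{PB}^* \ge \mathrm{PB}\})/(B + 1)$.

## The synthetic-data generator

The generator is the package's study-design stand-in, not a tuning knob.
Counts come from a gamma–Poisson mixture with log-normal library sizes
(mean 18M reads, CV 0.15, matching typical depths for this design) and
per-sample compositional renormalization, so TMM has real work to do.
Defaults plant 600 concordant, 50 opposing and 120 sex-biased genes among
9000 — the magnitudes of the motivating study's shared-response table —
plus 400 male-limited and 80 female-limited genes (scaled-down echoes of
the observed 1879/165 split), with planted log2 fold changes of 1.5,
sex effects of 2, and dispersion 0.1 (constant by default; a gamma
distribution across genes is available). Sex-limited genes have mean
exactly zero in the silent sex. Thirty percent of sex-limited genes carry
a diet response, oriented as observed: female-limited genes rise on
protein-rich food, male-limited genes on carbohydrate-rich.

Landscapes place observations along the eight standard P:C rails (4:1 …
1:32) with log-normal total intake, and default gradients put the female
optimum on the 2:1 rail and the male optimum on 1:4 with curvature
$\gamma = -2I$ and residual SD 0.5 on the fitness scale. The default of
60 flies per sex per rail (960 rows) follows the experimental design the
package emulates; one published figure caption says 120 per rail instead,
and the gradient-recovery checks use 120 per sex total as the
acceptance-scale problem size.

What these simulations do *not* emulate: per-gene abundance-dependent
dispersion trends, GC/length biases, correlated genes, batch effects,
unbalanced designs, or the pooling of 12 flies per library. Passing tests
demonstrate internal statistical correctness (calibration, recovery,
invariances) under the generative model, not robustness to every artefact
of real libraries.

## Calibration results the suite actually measures

* Diet-term p-values on pure-null data pass a KS uniformity check
  (distance < 0.05 at 2000 genes).
* Realized FDR for the diet term — null-truth discoveries over all
  discoveries on mixed datasets with planted effects — averages ≤ 0.075
  over 20 seeds at nominal 0.05. On *all-null* data the extreme tail is
  slightly heavy (see the dispersion section): across 20 null seeds a
  handful contain one or two false discoveries, a behaviour shared by the
  standard implementations of this methodology at fixed shrinkage priors.
* Planted concordant and opposing categories are recovered with
  sensitivity above 0.9, and their cross-sex fold-change correlations have
  the expected sign structure (strongly positive and strongly negative).
  Sex-biased genes (a response in one sex only, log2FC 1.5 at φ = 0.1 and
  3 replicates) are intrinsically hard: the interaction contrast's
  standard error is bounded below by $\sqrt{4\phi/3}$ nats, so its
  detection probability after FDR control tops out near 0.3 regardless of
  sequencing depth, and most detected sex-biased genes carry only one
  significant term. The classification logic is exercised by the tests;
  the power ceiling is a property of the design, not the implementation.
* Full-model CIs for selection gradients cover the generative values in
  ≥ 90% of 200 replicates at 120 observations per sex; noiseless inputs
  are recovered to numerical precision.
* The PB test's type-I error sits inside the 95% binomial band around
  0.05 (300 simulations, B = 199), with power ~1 for the 2:1-vs-1:4
  optima scenario.

## Known limitations

Quasi-likelihood F-tests, robust/outlier-aware dispersion handling,
abundance-dependent dispersion trends and exact tests are out of scope;
the LRT's finite-sample tail behaviour at 12 libraries is the price of a
fully first-principles engine. Term hierarchies are plain parent→child
edge lists, not a full ontology DAG parser. Thin-plate-spline landscape
visualisation is deliberately replaced by quadratic-surface grids: the
fitted model *is* the quadratic, and plotting a different smoother than
one fits invites over-reading.
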