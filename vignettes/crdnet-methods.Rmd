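---
title: "Methods: component-resolved IgE networks and differential interaction classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: component-resolved IgE networks and differential interaction classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multiplex component-resolved diagnostics (CRD) measure serum specific IgE
against on the order of a hundred purified allergen proteins at once, on
the semi-quantitative ISU scale of the ISAC microarray. In childhood
asthma, the open question is not whether sensitisation matters but which
*structure* in the sIgE profile carries the clinical signal: individual
component levels, co-sensitisation patterns, or the way pairs of
components co-vary differently in children with and without asthma.
`crdnet` implements a complete analysis chain for that question:

1. **Filtering** — dichotomise at 0.30 ISU (strictly greater; the
   manufacturer cut-off itself is negative), keep *active* components
   (positive in at least 5% of children, inclusive, denominator = all
   children supplied) and *sensitised* participants (at least one active
   positive).
2. **Component clusters** — average-linkage hierarchical clustering on
   the `1 - dCor` dissimilarity between components, cut at 0.40, with
   DIANA and PAM as robustness comparators (plain Rand index agreement).
3. **Sensitisation clusters** — Ward clustering (Lance–Williams D2
   update) of participants on Jaccard distances between binary profiles,
   the number of clusters chosen by the Calinski–Harabasz criterion, and
   cluster–outcome associations (chi-squared, odds ratios with Wald
   intervals, Kruskal–Wallis for continuous outcomes).
4. **JDINAC** — a logistic regression of asthma on per-pair log ratios of
   class-conditional bivariate kernel densities with an L1 constraint,
   estimated by multiple data splitting with prediction averaging; pairs
   repeatedly selected across splits form the *differential network*.
5. **Baseline and harness** — class-weighted L1 logistic regression on
   the individual components, and a repeated stratified cross-validation
   harness producing AUC, accuracy, sensitivity, specificity, precision
   and F1 from averaged out-of-fold probabilities.

# The JDINAC model

Let $X_{n \times p}$ hold log-transformed sIgE values ($\log(x+1)$;
applied before all modelling) and $Y_l \in \{0, 1\}$ asthma status. With
$f^1_{ij}$ and $f^0_{ij}$ the class-conditional joint densities of
components $(G_i, G_j)$,

$$\operatorname{logit} P(Y = 1) = \alpha_0 + \sum_{i<j} \beta_{ij}
\ln \frac{f^1_{ij}(G_i, G_j)}{f^0_{ij}(G_i, G_j)},
\qquad \sum_{i<j} |\beta_{ij}| \le c .$$

The densities are unknown; each of $T$ repetitions draws a stratified
half-split, estimates all pair densities on one half (bivariate Gaussian
product-kernel KDE), computes the log-ratio features on the other half
and fits a class-weighted L1-penalised logistic regression there, then
swaps the halves. A pair's **differential weight** is the number of the
$2T$ fitted models in which $\hat\beta_{ij} \ne 0$; pairs at or above a
25% inclusion fraction form the differential network, with edge
direction the sign of the mean nonzero coefficient (positive = risk).

Why pairs? A dependency difference with identical marginals is invisible
to any model of individual component levels: that is exactly the
`interaction_only` regime of the synthetic generator, and the package's
acceptance tests verify that JDINAC detects it while the penalised
logistic baseline stays at chance.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.30 ISU | positivity cut, strict inequality |
| `min_prevalence` | 0.05 | active-component rule, inclusive |
| `cut_height` | 0.40 | flat cut on the `1 - dCor` scale |
| `T` | 25 | split-swap repetitions (50 fitted models, matching a 50-repetition protocol) |
| `bandwidth_rule` | "scott" | per class, per dimension, on the density half only ($h = \hat\sigma\, m^{-1/6}$; Silverman's multivariate rule coincides in 2-D, a fixed bandwidth is available) |
| `floor` | 1e-10 | density floor before logs; far outside both supports the feature is exactly 0 |
| `penalty` | "1se" | largest lambda within one SE of the minimum inner-CV deviance (5 stratified folds) |
| class weights | inverse frequency | normalised to mean 1, used in both models |
| `min_fraction` | 0.25 | network inclusion threshold |
| `folds`, `repetitions` | 10, 50 | baseline evaluation protocol |

# Evaluation protocols: two drivers, used for different things

The split-swap machinery produces averaged *out-of-half* probabilities:
each participant is predicted by the models whose regression half did
not contain them. These are the right diagnostic for the fit itself and
the source of the differential weights. They are **not** a good estimate
of out-of-sample discrimination: all participants sharing a half receive
correlated predictions (they share each model's intercept and spurious
selections), so under weak signal the AUC of these averages has very
heavy tails — we observed values from 0.18 to 0.76 on null data where a
properly cross-validated AUC sits tightly around 0.5.

The package therefore also provides `jdinac_spec()`, which nests the
entire JDINAC estimator inside the stratified repeated cross-validation
harness: densities, penalties and coefficients are estimated on training
folds only and held-out folds are scored by full prediction averaging.
All reported AUCs in the tests, the analysis scripts and the acceptance
script use this outer-CV driver (5 folds, `T = 10` inside each training
fold — prediction averaging stabilises quickly, and the outer folds
multiply cost); the differential network always comes from the native
driver at full `T`, and the pipeline summary records the native
split-swap AUC labelled as such. Every `performance_report` names its
protocol.
Classification metrics threshold the averaged probabilities at 0.5.

# The synthetic cohort generator

No cohort data are distributable, so every claim is exercised on
synthetic cohorts whose structure mirrors what the analysis assumes:

- **Gaussian copula**: a latent matrix with unit-variance margins, a
  shared "atopy" factor (`background_r`), planted component blocks
  (within-block latent correlation), and optional per-component loading
  overrides. The copula is the simplest structure with controllable
  block dependence, and the downstream distance-correlation and KDE
  stages need only monotone-transformable dependence.
- **Zero-inflated ISU margins**: `ISU = max(exp(mu + sigma z) - shift, 0)`
  — with `shift = 1` the log1 transform recovers the latent Gaussian on
  the positive part, and truncation itself produces the heavy spike at
  zero that real ISAC data show; an extra per-component structural-zero
  probability is available. Marginal parameters are set per component
  from target positivity rates via
  `mu = log(1.3) - sigma * qnorm(1 - q)`.
- **Signal regimes**: `null` (outcome independent), `marginal`
  (logistic in selected components' log1 values, intercept solved for
  the requested prevalence), and `interaction_only` (classes drawn
  first; identical marginals, class-specific latent correlation for the
  configured pairs — precisely the signal JDINAC claims to detect and a
  marginal model cannot). Infeasible (non-PSD) class correlation
  matrices are rejected with an error naming the class; nothing is
  repaired silently.

`emulate_paper_shape()` is the canned study-shaped configuration:
461 participants, 112 components of which seven blocks of sizes
(4, 3, 4, 6, 8, 4, 4) carry allergen-family names (house dust mite,
peanut, lipocalins, grasses, PR-10, trees, profilins), 11 active
singletons and 68 rare components; outcome prevalence 0.34 so that
asthma prevalence among sensitised children is about a third. Its free
parameters were calibrated once, against the target geometry — about 44
active components, roughly 46% of children sensitised, blocks
recoverable at the 0.40 cut — giving atopy factor `r0 = 0.74`,
within-block latent `r = 0.90`, `sigma = 1.5`, per-block positivity
0.069–0.167 and singleton positivity 0.069–0.108.

One calibration subtlety is worth recording. Restricting the analysis to
sensitised participants conditions on "at least one positive", which
truncates the shared atopy factor and *inflates* every between-component
correlation in the retained subset. Planted differential pairs must
therefore stay moderately loaded on the shared factor (loading$^2$ =
0.60 here, with class correlations 0.95 vs 0.20): detaching them from
the factor changes who gets selected and can push between-block
correlations past the 0.40 cut. This is a real phenomenon, not an
artifact — any cohort filtered on sensitisation has the same selection
effect.

What the generator does **not** emulate: assay noise floors and plate
effects, semi-quantitative ISU banding, longitudinal trajectories, and
any particular real marginal shape (the log-normal is a modelling
convenience, config-exposed). Passing tests therefore show that the
chain detects the structures it claims to detect under a faithful
dependence model — not that the specific clinical numbers of any real
cohort would be reproduced.

# Numerical and design choices

- **Distance correlation** is computed from double-centred absolute
  -distance matrices; all p(p−1)/2 pair statistics come from one
  crossproduct of the stacked centred matrices. A constant component has
  zero distance variance; its dCor is defined as 0 (the statistic is
  0/0) with a warning. By default dCor runs on log1 values for
  consistency with the modelling stages — heavy right tails otherwise
  dominate the pairwise distances; `log1 = FALSE` restores raw-scale
  behaviour. Scaled connectivity always uses all pairs; the
  `edge_min_dcor = 0.3` threshold only prunes the exported graph.
- **Cluster counts**: the component partition comes from the 0.40 cut,
  never from k-selection; DIANA and PAM are given the agglomerative
  cluster count so the Rand comparison is like-for-like. Exact-tie
  merges follow `stats::hclust` order (lowest index first).
- **Ward on Jaccard** is formally heuristic (Jaccard is not Euclidean);
  the Ward.D2 Lance–Williams update on the given distances is standard
  practice for binary sensitisation profiles and is used deliberately.
  The Calinski–Harabasz index is computed on the 0/1 coordinates (it
  needs centroids); k = 1 is undefined and excluded from the trace.
- **Odds ratios** use cluster-vs-rest as the default contrast
  (config-switchable to a named reference cluster), Wald intervals on
  the log scale, and the Haldane–Anscombe 0.5 correction (flagged) for
  zero cells. Chi-squared tests drop the Yates correction and fall back
  to a Monte-Carlo p-value when any expected count is below 5. Raw
  p-values are reported without multiplicity adjustment, matching the
  descriptive use of these tables.
- **KDE degeneracies**: a class-half in which a component is constant
  (all zeros is common for rare components) would give a zero bandwidth;
  such dimensions fall back to a small fixed bandwidth (1e-3 before the
  $m^{-1/6}$ factor) so densities stay evaluable, and the density floor
  keeps every feature finite. Precision with zero predicted positives is
  defined as 0 with a warning; F is F1.
- **Determinism**: every stochastic stage derives per-repetition seeds
  from a single master seed (`seed * 7919 + i * 104729 mod 2^31-19`
  style sub-streams, kept within 32-bit range), so pipelines, fits and
  the evaluation harness are bitwise reproducible.

# Problem sizes used in the test suite

The acceptance-style tests run the full conditions of interest per seed
(e.g. n = 400, p = 10, T = 20 for planted-interaction recovery; n = 300,
p = 8, T = 20 for null calibration; 461 × 112 study-shaped cohorts for
clustering), with 20 Monte-Carlo seeds for the clustering and archetype
checks and 10 seeds for the JDINAC simulations; the end-to-end
determinism check runs the full pipeline at a reduced protocol
(T = 3, 2 × 5-fold CV), since determinism does not depend on the
repetition count. These sizes are the package's chosen trade-off between
Monte-Carlo resolution and a test suite that stays pleasant to run.

# Known limitations

- Differential weights count selections; they are not effect sizes, and
  no confidence statement attaches to an edge. Higher-order (three-way
  and beyond) interactions are out of scope.
- The native split-swap AUC is reported only as a diagnostic; see the
  protocol discussion above.
- Ward-on-Jaccard and CH-on-binary-coordinates are pragmatic choices;
  other binary-data clusterings (e.g. model-based) may partition
  differently.
- The odds-ratio reference group of the original tables is not
  recoverable from the outputs we mirror; both available contrasts are
  exposed and the default is documented rather than asserted as
  faithful.
- With missing input cells the package refuses to guess: ingestion
  either errors or, under an explicit flag, maps missing to 0 (the ISAC
  convention for below-detection) and says so.
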