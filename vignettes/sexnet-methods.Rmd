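---
title: "Methods: neural attribution of sex-biased expression and downstream screens"
author: "sexnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural attribution of sex-biased expression and downstream screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexnet)
```

# The scientific problem

Many cancers, gastric cancer prominently among them, show a strong male
bias in incidence together with sex differences in prognosis. Part of that
bias is trivially explained by sex-chromosome biology (Y-linked genes,
XIST, genes escaping X inactivation), but hormone signaling — in
particular androgen receptor (AR) activity — is a candidate driver that
ordinary differential expression between the sexes tends to bury under the
sex-chromosome signal. `sexnet` implements a discovery chain that attacks
this question in three movements:

1. **Which genes encode sex in the transcriptome?** A classifier is
   trained to predict a sample's sex from its expression profile, and
   *feature attribution* on that classifier ranks genes by how much they
   contribute to the prediction. Intersecting top-ranked genes across
   independent cohorts yields a consensus that is robust to cohort-level
   noise, and gene-set enrichment on the attribution ranking names the
   processes involved.
2. **Which hormone-linked markers carry prognosis?** Genes co-expressed
   with the AR-like marker are screened by differential expression, a
   penalized Cox model selects a sparse prognostic signature, and patients
   are stratified by quantile cutpoints on the selected markers.
3. **What does the miRNA in that signature repress?** A microRNA target
   screen intersects three lines of evidence — predicted seed sites in
   3'-UTRs, down-regulation after miRNA over-expression, and inverse
   correlation in patient data — and a promoter scan looks for androgen
   response element (ARE) half-sites upstream of the miRNA's transcription
   start sites.

Every stage is exercised end to end on a synthetic cohort generator that
plants exactly the structures the chain is supposed to find.

# The sex classifier

## Model

The classifier is a densely connected feed-forward network: with input
$x \in \mathbb{R}^d$ (a z-scaled expression profile) and hidden layers
$h_1, \dots, h_{L-1}$, layer $k$ receives the concatenation
$[x, h_1, \dots, h_{k-1}]$ and the output unit sees
$[x, h_1, \dots, h_{L-1}]$, mapping to
$P(\text{male}) = \sigma(w^\top[\cdot] + b)$. The default depth is
`total_layers = 11` (ten hidden layers plus the output unit). Dense
connectivity gives every layer, and therefore the attribution method, a
direct path to the raw inputs.

Sex is encoded female = 0, male = 1 throughout; a positive attribution
therefore pushes the prediction toward male.

## Training choices

The topology is fixed by design, but widths, activation and optimizer are
free parameters; the defaults are `hidden_width = 64`, ReLU activations,
binary cross-entropy loss, Adam with learning rate $10^{-3}$ and batch
size 32, trained for 200 epochs. A stratified random 10% of samples is
held out; after every epoch the model is scored on that validation set
(accuracy by default, AUC by flag) and the parameters of the best epoch —
not the last — are returned, with ties resolved toward the earliest epoch.
Forward, backward and input-gradient passes are implemented analytically
in the package; a finite-difference contract test keeps the input gradient
honest to within $10^{-4}$ relative error, which the attribution method
depends on.

At the simulation scale used for the package's end-to-end checks
(2000 genes, 300 samples per cohort) the width is reduced to 16 units so
that five cohorts train in about five minutes on one CPU; accuracy on the
planted signal is insensitive to width in this range.

## Preprocessing

Counts matrices are normalized to counts-per-million and
$\log_2(\text{cpm} + 1)$ transformed (pseudocount 1, recorded in the
output); log-intensity matrices are taken as-is. Genes are then z-scaled
across samples. Zero-variance genes cannot be scaled and are dropped and
recorded, not imputed. Two scaling disciplines exist: fitting the scaling
on the training split and applying it to validation (`zscale_genes` +
`zscale_apply`, the leakage-safe default for model assessment), or scaling
the full matrix first, which is what the pipeline uses when attributing
*all* samples of a cohort after training — at that point the model is
fixed and the quantity of interest is descriptive, not a generalization
estimate.

# Integrated-gradient attribution

For input $x$, baseline $x'$ and model output $F$, the attribution of
gene $i$ is

$$\mathrm{IG}_i(x) = (x_i - x'_i) \cdot \frac{1}{m} \sum_{k=0}^{m-1}
\left. \frac{\partial F}{\partial x_i} \right|_{x' + \frac{k + 1/2}{m}(x - x')}$$

a midpoint-rule approximation of the path integral with `m = 128` steps
by default. The midpoint rule was chosen over the left-endpoint sum
because its residual falls as $1/m^2$ rather than $1/m$, which is what
keeps the completeness bound below at practical step counts; both rules
give the exact closed form on a linear scorer. The method satisfies
*completeness*:
attributions sum to $F(x) - F(x')$ up to the Riemann residual, which the
package records per sample (`completeness_error`) and which shrinks as
$m$ grows; the test suite checks the $10^{-3}$ bound at $m = 256$ and the
closed form $\mathrm{IG}_i = w_i (x_i - x'_i)$ on a linear scorer, exact
for any $m$.

The baseline is the all-zeros vector in z-scaled space, i.e. the
population-mean expression profile — the natural "typical sample"
reference; it is configurable. Per-gene attribution scores are the mean
attribution over the male group (the convention under which positive
scores push toward male); female-group and male-minus-female variants are
available for exploration. Per-cohort top-100 score sets are intersected
and genes appearing in at least 4 of 5 cohorts form the consensus;
boundary ties in `top_k` resolve lexicographically so runs are
deterministic.

# Preranked enrichment

The enrichment score of a gene set $S$ in a descending ranking is the
signed maximal deviation of the weighted Kolmogorov–Smirnov running sum:
stepping down the list, members of $S$ add $|s|^p / N_R$ (with
$N_R = \sum_{S}|s|^p$, weight $p = 1$ by default) and non-members
subtract $1/(N - |S|)$. The null distribution is obtained by drawing
random same-size gene sets from the ranking (gene-label permutation, the
only null available to preranked input; 1000 draws by default). The
normalized score divides ES by the mean $|ES|$ of the same-sign null
draws; the nominal p-value uses +1 smoothing over same-sign draws, so
$p \in [1/(n_{perm}+1), 1]$; Benjamini–Hochberg adjusts across sets. A
brute-force running-sum oracle, exhaustive subset enumeration on tiny
universes, and the independent `fgsea` implementation all appear as
cross-checks in the test suite.

# Differential expression and correlation

Two-group screening uses a per-gene Welch $t$-test on the log2 scale with
BH adjustment; the log fold change is the difference of group means.
This is a deliberate, documented divergence from moderated linear-model
statistics: empirical-Bayes variance shrinkage is out of scope, and at
the sample sizes simulated here (50+ per group) moderation changes little.
The screening filter keeps genes with $p < 0.05$ and $|\log_2 FC| > 0.5$
(both strict). The fold-change threshold is read on the log2 scale by
default because the linear reading is near-vacuous — a gene repressed to
62% of control ($2^{-0.7}$) would still pass a linear "ratio > 0.5"
filter; the literal linear reading remains available by flag, and a test
documents its behavior. Correlation testing is the Pearson test with the
two-sided $t$ approximation $t = r\sqrt{(n-2)/(1-r^2)}$.

# Survival analysis

Markers are dichotomized at quantile cutpoints — median, upper quartile,
upper or lower tertile — with "high" meaning strictly above the cutoff and
ties assigned low (the cutpoint conventions are stated; the tie policy is
a package decision). Kaplan–Meier curves, log-rank tests and Cox
proportional-hazards models are computed by the `survival` package with
the Efron correction for ties; monotone-likelihood fits (perfect
separation) are flagged `converged = FALSE` rather than silently reported.
Hazard ratios carry 95% Wald intervals $\exp(\beta \pm 1.96\,SE)$.

LASSO-Cox feature selection runs the L1-penalized partial-likelihood path
(`glmnet`) with tenfold cross-validation on the held-out partial-likelihood
deviance; the selected signature is the nonzero set at the
deviance-minimizing $\lambda$ (the one-standard-error rule is available by
flag). The $\lambda = 0$ endpoint reproduces the unpenalized fit to
$10^{-4}$ (the path tolerance is tightened to `thresh = 1e-12` for this);
large $\lambda$ yields the empty model.

The two-marker stratification crosses a median split on the AR-like
marker with an upper-quartile split on the miRNA-like marker into four
groups, and merges the three non-"both-high" groups into one for the
binary contrast.

# Sequence screens

For a mature miRNA (default: miR-125b-5p, shipped as a miRBase-sourced
constant), the canonical site patterns are compiled from seed positions
2–8: `7mer-m8` (reverse complement of 2–8), `8mer` (7mer-m8 plus the
position-1 adenine), `6mer` (reverse complement of 2–7) and `7mer-A1`
(6mer plus the adenine). UTR scanning reports all occurrences; where
sites overlap, only the most specific type is kept
(8mer > 7mer-m8 > 7mer-A1 > 6mer), mirroring standard target-prediction
convention. The three-evidence integration intersects predicted-site
genes, transfection-down genes and patient-inverse genes (Pearson
$r < -0.3$ by default) and reports all seven Venn regions.

The promoter scan searches the 2-kb region upstream of a TSS for the ARE
half-site `AGAACA` on both strands (a reverse-strand site is a forward
occurrence of `TGTTCT`). Coordinates are upstream offsets with $-1$ the
base immediately 5' of the TSS, each site reported as $-a/-b$ with
$|a| < |b|$; the smaller-magnitude-first order fixes a convention the
figure-style notation leaves ambiguous. Strandedness of the supplied
sequence is the caller's responsibility. Both scanners are validated
against naive every-offset oracles on random sequences.

# The synthetic cohort generator

The generator is the package's definition of the study conditions, not a
tuning knob. One cohort draws a gene-by-sample Gaussian log2-intensity
surface (gene means uniform on 4–10, noise SD 1) and plants:

- **Y-linked genes** (10): expressed in males, at the floor value in every
  female;
- **XIST-like genes** (10): the mirror image, silent in males;
- **XCI-escape genes** (10): shifted up by `sex_effect_size` (default
  1 log2 unit, a realistic escape-gene magnitude) in females;
- a **hormone module**: an AR-like gene and a miRNA-like gene drawn with
  population correlation 0.5 (the planted analogue of the observed
  AR–miR co-expression), plus two host-lncRNA genes correlated 0.6 with
  the miRNA, placed on the appropriate chromosomes in the annotation;
- optional **negative-binomial counts mode** (dispersion size 10 around
  the log2 surface) feeding the CPM normalizer.

Defaults are 300 samples and 2000 genes per cohort with a 2:1
male:female ratio — the disease's incidence ratio; the sex ratio of the
original training cohorts is not stated anywhere, so this is a modeling
choice made once. The floor for absent expression is 1.0 (the noise
floor), not exact zero, so scaling stays well-defined. Gene-level
properties (means, chromosome assignments, planted identities) are drawn
once from the master seed and shared across cohorts; per-cohort noise and
labels use child seeds derived by the fixed rule
`(seed + 104729 i) mod (2^31 - 1)`, so one integer reproduces an entire
multi-cohort simulation bit for bit.

Survival is exponential with hazard
$\lambda_0 \exp(\beta^\top x)$ (default $\lambda_0 = 0.02$ events/month,
planted $\beta = \log 1.45$ on the standardized AR-like and miRNA-like
markers, inside the hazard-ratio range the stratified analyses are meant
to detect). Censoring is independent exponential, its rate calibrated by
bisection against fixed uniform draws until the realized censoring
fraction is within two points of the target (default 30%), which keeps
the simulation deterministic per seed.

UTR generation writes the requested seed sites into random ACGT
backgrounds at non-overlapping positions and rejection-samples until a
rescan reports exactly the planted sites — no spurious seed matches
anywhere, none in decoys. Promoter generation does the same for ARE
half-sites on random strands.

**What the generator does not emulate:** microarray probe effects, batch
effects and platform normalization; realistic expression covariance
between background genes; copy-number or mutation structure; and any
relationship between the expression surface and the sequence fixtures
beyond the planted correlations. Passing tests therefore demonstrate that
the chain recovers planted structure of realistic magnitude under clean
noise — not that it would survive confounded real cohorts.

# Numerical choices and degenerate inputs

- Gradient checks: analytic vs central finite differences, $10^{-4}$
  relative tolerance.
- Completeness: midpoint Riemann rule, residual logged per sample;
  $\le 10^{-3}$ at $m = 256$ on the tested nets.
- Ranking ties: descending score, then lexicographic gene id — total
  order, deterministic consensus.
- ES ties: the first position attaining the maximal $|deviation|$ defines
  ES; with continuous scores exact ties have measure zero.
- Zero-variance genes are dropped before scaling; all-zero count columns
  are an error naming the sample; constant vectors are errors for
  dichotomization and correlation.
- Cox: Efron ties, convergence at relative log-likelihood change
  $< 10^{-9}$ or 100 iterations; separation flagged, not silenced.
- All stage seeds derive from one master seed; two runs of the same
  config and seed produce byte-identical artifacts, checked by MD5 in the
  run manifest.

# Problem sizes used in the shipped checks

The full-scale end-to-end check trains five 11-layer nets (width 16) for
200 epochs on 2000-gene, 300-sample cohorts and attributes the male
group at $m = 128$; this completes in roughly five to six minutes on one
CPU and recovers 100% of the planted sex genes in the $\ge 4/5$ consensus
at the shipped seed. Unit tests use reduced nets (3–4 layers, widths
4–16) and the demonstration pipeline configuration (`demo_config()`: two
80-sample cohorts, 300 genes) so the whole suite stays inside a routine
CI budget. Statistical checks (type-I rates, CI coverage, LASSO recovery
rates, permutation calibration) use replicate counts chosen so that their
acceptance bands are several Monte-Carlo standard errors wide.

# Known limitations

- The Welch test replaces moderated statistics; very small groups
  (< 10 per arm) would benefit from moderation the package does not do.
- The permutation null is gene-label permutation only; phenotype
  permutation is undefined for preranked input and out of scope.
- Seed-site scanning is pattern matching: no context scores, conservation
  or free-energy terms; site counts are upper bounds on functional sites.
- The promoter scan matches the literal half-site; it is not a PWM and
  will not find degenerate AREs.
- The classifier is a fixed dense topology; no hyperparameter search is
  performed, by design.
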