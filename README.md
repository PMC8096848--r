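# sexnet

Sex-disparity gene discovery by neural attribution in cancer
transcriptomics.

Male-biased cancers such as gastric cancer pose a recurring analysis
problem: which genes carry the sex signal in the transcriptome, and which
hormone-linked markers among them matter for prognosis? `sexnet`
implements a complete discovery chain for this question, usable on real
gene-by-sample expression matrices with sex labels and optional survival,
and fully testable without any external data through a built-in synthetic
cohort generator.

The chain, end to end:

1. **Sex classifier.** A densely connected feed-forward network (default
   11 layers: each hidden layer sees the concatenation of the raw input
   and all earlier layers) is trained to predict sex
   (female = 0, male = 1) from z-scaled expression, 200 epochs with a 10%
   validation split; the best-validation epoch is kept.
2. **Integrated-gradient attribution.** Per-gene attribution scores are
   the male-group mean of
   IG_i(x) = (x_i − x'_i) · (1/m) Σ_k ∂F/∂x_i at x' + (k/m)(x − x'),
   computed from the network's analytic input gradients against the
   population-mean baseline. Attributions satisfy completeness:
   Σ_i IG_i ≈ F(x) − F(x').
3. **Cross-cohort consensus.** Per-cohort top-100 attribution sets are
   intersected; genes in ≥ 4 of 5 cohorts form the consensus.
4. **Preranked GSEA.** The attribution ranking is tested against gene-set
   collections with the weighted Kolmogorov–Smirnov running-sum score and
   a gene-label permutation null (NES, +1-smoothed p, BH q).
5. **Survival screens.** AR-associated differential expression (Welch t,
   p < 0.05 and |log2FC| > 0.5), LASSO-Cox signature selection with
   tenfold cross-validation, quantile-cutpoint stratification
   (median / upper-quartile), Kaplan–Meier, log-rank and Cox models with
   Efron ties and Wald intervals.
6. **Target screens.** miRNA seed-site scanning of 3'-UTRs (8mer,
   7mer-m8, 7mer-A1, 6mer with most-specific-wins overlap resolution),
   three-evidence target integration (predicted ∩ transfection-down ∩
   patient-inverse), and AGAACA androgen-response-element half-site
   scanning of 2-kb promoters on both strands.

The synthetic generator plants exactly these structures — Y-linked,
XIST-like and X-inactivation-escape genes, a correlated AR/miRNA hormone
module, proportional-hazards survival effects, and UTR/promoter sequences
with known site plans — so every stage's recovery is checkable.

## Worked example

The bundled demonstration configuration simulates two 80-sample cohorts
of 300 genes (15 planted sex genes, planted hormone module and survival
effects), runs the full chain in a few seconds, and writes per-stage
artifacts plus a manifest:

```r
library(sexnet)
res <- run_pipeline(demo_config(seed = 7), output_dir = "demo_run")
cat(readLines("demo_run/summary.txt"), sep = "\n")
```

```
cohorts: 2 x 80 samples, 300 genes
consensus (>= 2/2 cohorts): 11 genes
planted sex genes recovered in consensus: 10 / 15
DE genes past filter: 16
LASSO-Cox selected: ARlike, MIRlike, XCIesc03, gene00108, HOSTlnc2, gene00014, Ygene05, Ygene02, gene00147, gene00209, gene00160
merged-stratification log-rank p: 0.0001589
final miRNA targets: 4
ARE half-sites found: 4
```

Reading the output: 10 of the 15 planted sex-informative genes reach the
two-cohort consensus even at this deliberately small scale (at the full
simulated study scale recovery is complete — see below); both planted
prognostic markers (`ARlike`, `MIRlike`) are selected by LASSO-Cox; the
merged both-high-vs-rest stratification separates survival
(log-rank p ≈ 2e-4, reflecting the planted hazard ratios of 1.45); all
four planted miRNA targets survive the three-evidence intersection with
no decoys; and the four planted ARE half-sites are found in the two
synthetic promoters.

Individual stages are ordinary functions on plain containers
(`expression_matrix`, data frames), e.g.:

```r
ms <- compile_seed_patterns(MIR125B_5P)
scan_utr("GGGTCTCAGGGTTTT", ms)        # one 7mer-m8 site at 5-11
scan_promoter_halfsites("...AGAACA...")  # ARE half-sites, -a/-b offsets
```

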