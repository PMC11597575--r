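---
title: "Methods: cold-stress differential expression, gene-set enrichment and qPCR quantification"
author: "coldtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cold-stress differential expression, gene-set enrichment and qPCR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldtx)
```

# Scope

`coldtx` analyses low-temperature transcriptome experiments of the classic
design: a control condition (22&nbsp;°C) and one or more cold treatments
(0, 4, 10&nbsp;°C), each with a small number of biological replicates
(three by default). It covers four stages — pairwise negative-binomial
differential expression, top-N induced-gene selection with exclusive Venn
partitioning, Gene Ontology term enrichment by logistic regression on a
signed significance score, and 2^−ΔCt qPCR quantification — plus a seeded
simulator that generates data with known ground truth so every stage can be
tested for calibration and parameter recovery.

# The count model and the exact test

Counts for gene $g$ in sample $j$ are modelled as negative binomial with
mean $\mu_{gj}$ and dispersion $\phi$:

$$\mathrm{Var}(y_{gj}) = \mu_{gj} + \phi\,\mu_{gj}^2 .$$

Throughout the package $\phi$ is the squared biological coefficient of
variation ($\phi = 0$ is Poisson); this is stated explicitly to avoid the
common $\phi$ versus $1/\phi$ ("size") confusion.

**Normalization.** Between-sample scaling uses the trimmed mean of
M-values: against a reference sample (the one whose upper-quartile CPM is
closest to the mean), genes with a zero in either sample are dropped, the
most extreme 30% of log-ratios and 5% of average log-abundances are
trimmed, and the factor is the precision-weighted mean of the surviving
log-ratios. Factors are rescaled to geometric mean 1, so they only
redistribute depth. One unit test cross-checks the factors against an
independent implementation of the same estimator.

**Dispersion.** A single dispersion common to all genes is estimated by
conditional maximum likelihood on counts scaled to a common pseudo-library
(the geometric mean of effective library sizes). Conditioning each group's
replicate vector on its sum removes the per-gene mean from the likelihood,
which is what makes the estimator usable with two small groups. The 1-D
maximization is a golden-section search on $\log_{10}\phi$ over
$[10^{-6}, 10]$; the endpoints are compared explicitly, so degenerate
inputs (bit-identical replicates) return exactly the lower bound rather
than a point a search-tolerance away from it. Tagwise and trended
dispersion are deliberately out of scope: the package implements the
classical common-dispersion pairwise path, which is verifiable against a
closed-form oracle (below).

**Exact test.** For a contrast, each gene's counts are scaled to the
pseudo-library and summed per group. Under the null, the rounded treatment
sum given the rounded total follows the conditional distribution of two NB
group sums with a common per-sample mean (estimated from the total) and the
estimated $\phi$. The two-sided p doubles the smaller tail, includes the
observed point in both tails, and is capped at 1. Two properties anchor
correctness:

* at $\phi = 0$ the conditional distribution is exactly binomial, so p
  must agree with a direct binomial-tail computation — the suite asserts
  agreement to $10^{-8}$ and observes $\sim 10^{-15}$;
* on null simulations the rejection rate at $\alpha = 0.05$ is nominal
  (measured 0.042–0.043 at 5,000 genes; the slight conservatism is the
  usual cost of tail-doubling on a discrete support).

Reported per gene: $\mathrm{logFC} = \log_2\frac{S_T + 0.5}{S_C + 0.5}
\cdot \frac{n_C}{n_T}$ (pseudo-counts of 0.5 avoid infinities at zero),
logCPM as the log2 mean of $(y + 0.5)/(\text{eff.\ lib} + 1)\times 10^6$,
and the Benjamini–Hochberg FDR of the exact-test p-values. DEGs are counted
at strict FDR < 0.01.

# Ranking and Venn partitioning

Top induced genes per contrast are those with FDR < 0.01 (strict),
logCPM > 4 (strict) and positive logFC, ranked by logFC descending. The
thresholds deliberately mirror the published analysis this package
re-implements; the tie rule (smaller FDR first, then lexicographic gene id)
is our own choice, made so the ranking is a total order and reruns are
byte-identical — published analyses of this kind typically leave the tie
rule unstated.

`venn_partition()` is exact set algebra: for every non-empty subset of the
compared conditions, the exclusive region contains genes in all of those
sets and none of the others. Regions are disjoint, their counts sum to the
union, and both properties are asserted on random fixtures. The package
ships the published shared-gene lists for the Arabidopsis cold-stress
comparison as a plain-text fixture; padding each per-temperature set to 50
with per-temperature placeholders and partitioning reproduces the reported
region counts 31 / 9 / 8 / 2 exactly.

# Gene-set enrichment by logistic regression

Instead of a hypergeometric test on a DEG cut-off, enrichment is a
regression over the *whole measured universe*. Each gene gets a signed
significance score

$$x_g = \mathrm{sign}(\mathrm{logFC}_g)\cdot(-\log_{10}\mathrm{FDR}_g),$$

zero when logFC is zero or FDR is 1, and floored at FDR $=10^{-300}$ so an
underflowed FDR yields a large finite score. For each term, membership
$y_g \in \{0,1\}$ is regressed on $x_g$ with the binomial family and logit
link:

$$\mathrm{logit}\,P(y_g = 1) = \beta_0 + \beta_1 x_g .$$

The fit is iteratively reweighted least squares with closed-form 2×2
Newton solves, at most 100 iterations and a relative deviance tolerance of
$10^{-10}$ (an absolute $10^{-10}$ is below float resolution for a
deviance of order $10^3$–$10^4$, so the relative form is used). The
enrichment p-value is the two-sided Wald test on $\beta_1$ (a
likelihood-ratio variant is available via `p_type = "lrt"`), and the
reported score is $\mathrm{sign}(\beta_1)\cdot(-\log_{10} p)$ — positive
for induced gene sets, negative for repressed ones, suitable directly as a
heatmap colour value. `p_enrich` is floored at $10^{-300}$ so the identity
$|score| = -\log_{10} p$ holds even when the Wald p underflows.

**Separation.** A term whose membership is perfectly predicted by the sign
of $x$ has no finite maximum-likelihood estimate. Separation is detected by
non-convergence, $|\beta_1| > 30$, a degenerate information matrix, or
weight collapse (all fitted probabilities saturated); the term is then
refitted with Firth's Jeffreys-prior penalty — a damped penalized-IRLS with
hat-leverage-adjusted working responses — and flagged
`fit_method = "firth"`. Firth estimates are finite by construction and the
Wald p is taken from the penalized information matrix.

**Verification.** On small fixtures the IRLS coefficients match a
brute-force likelihood maximizer (coarse grid plus two rounds of
derivative-free/quasi-Newton polish, written independently of the IRLS
path) to $10^{-6}$, and match `glm()` to $10^{-8}$; negating every score
negates every slope and score while leaving p unchanged.

**A calibration caveat that matters.** With a realistic DE landscape the
score vector is mostly exact zeros (genes at FDR 1) plus a heavy tail of
large $|x|$. The slope's Fisher information is then carried by the few
large-score genes that land inside a term — effectively a handful of
observations however large the term — and the Wald (and likelihood-ratio)
null distribution is visibly non-normal: across 2,000 random-membership
terms on a 10,000-gene simulated landscape we measure a null rejection
rate of ~0.08 at $\alpha = 0.05$ and a Kolmogorov–Smirnov distance from
uniform of ~0.09–0.12, for term sizes small and large alike. In the
balanced moderate regime (50/50 membership at $n = 1000$) the same test is
calibrated almost exactly (0.05). The enrichment *ranking* is unaffected —
planted terms are recovered essentially perfectly (see below) — but the
absolute p-values from this model family should be read as scores, not as
calibrated tail probabilities, when the score distribution is heavy-tailed.
This is a property of the regression-on-signed-score method itself, not of
this implementation; users needing calibrated term-level p-values under
such landscapes should prefer permutation nulls, which are out of scope
here.

No multiple-testing correction is applied across terms for ranking; a BH
column is emitted for information only, matching how signed
$-\log_{10} p$ heatmaps are conventionally reported.

# qPCR quantification

Relative expression uses the 2^−ΔCt method: per replicate,
$\Delta C_t = C_t(\text{target}) - C_t(\text{reference})$ with the
reference gene (*AtUBQ5*-style housekeeping control) measured in the same
condition and replicate, and relative expression $2^{-\Delta C_t}$. Means
and SDs are taken over biological replicates; in addition to the raw
values, each mean is expressed as a fold change over the control-condition
mean, since cold-stress figures conventionally plot values relative to
22&nbsp;°C. The transformation is exactly invariant to a global Ct shift —
asserted to machine precision. Significance across temperatures uses
classical one-way ANOVA followed by Tukey's HSD (studentized range); the
significance level is p < 0.05. Zero within-group variance is flagged as a
degenerate result with NA p-values rather than being reported as
significant. Amplification-efficiency correction and ΔΔCt calibration are
intentionally not implemented.

# The synthetic-data generator

The simulator emulates the study design the analysis assumes, and its
defaults are fixed once as that design:

| parameter | default | rationale |
|---|---|---|
| conditions | 22C, 0C, 4C, 10C | control plus three cold treatments |
| replicates | 3 | standard for this design |
| library size | 5×10⁶ mean, CV 0.1, log-normal | conventional bulk depth; CV exercises normalization |
| baseline log2 abundance | uniform on [0, 12] | ~4 decades of expression |
| dispersion φ | 0.1 | conventional biological variability for inbred plant material |
| DE fraction | 0.1 per treatment | sizeable but minority response |
| planted log2FC | N(0, 2²) | signed effects; top inductions reach the 8–13 log2FC range seen in strong cold responses |

Counts are drawn NB with mean $s_j \cdot 2^{b_g + \beta_{gc}}$, where
$s_j$ scales each sample's expected total to its library size, $b_g$ is the
baseline and $\beta_{gc}$ the planted effect (zero in the control; exactly
zero iff the gene is non-DE, so the truth table is unambiguous). Planted
gene sets are drawn independently per treatment by default; an optional
nested mode draws each treatment's DE set as a subset of the previous
one, mimicking graded cold responses. GO terms are simulated by weighted
sampling: a planted "up" term draws members with weight
$\propto \exp(\text{strength}\cdot \bar\beta_g)$, where $\bar\beta_g$ is
the gene's mean planted effect across treatments; unplanted terms draw
uniformly (their membership–effect correlation averages to zero, asserted
over 100 seeds). Ct tables place a condition-independent reference gene
next to targets shifted by per-condition ΔCt effects, with Gaussian noise
on the Ct scale.

All randomness flows through one `set.seed()` per generator call, and the
caller's RNG stream is preserved, so identical configs are bit-identical
and independent of call order.

**What the simulator does not emulate:** read-level noise and mapping
ambiguity, isoforms, batch effects, gene–gene count correlation, tagwise
dispersion variation, and GO-hierarchy structure (terms are flat sets).
Passing recovery tests on these simulations therefore demonstrates
correctness of the statistics under the stated model, not robustness to
those real-data complications.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run, among smaller fixtures:
null calibration on 10,000 genes × 2,000 random terms; planted-term
recovery with 20 planted terms among 500 over 10 seeds (median 20/20
recovered in the top 5% by score); type-I error on 5,000 null genes;
IRLS-vs-brute-force agreement on 100 fixtures of n ≤ 50; and a full
pipeline determinism check (two runs, byte-identical outputs). These sizes
were chosen as the smallest at which the binomial/Monte-Carlo noise of each
property is comfortably below its assertion band.

# Known limitations

* Common dispersion only; genes with atypical variability get slightly
  anti-conservative or conservative p-values relative to tagwise methods.
* Asymptotic enrichment p-values are miscalibrated under heavy-tailed
  score distributions (see above); ranking remains reliable.
* The exact test's tail-doubling is mildly conservative on discrete
  supports at low counts.
* Annotation is taken as given — no ancestor propagation up the GO graph.
* No multi-factor designs; every contrast is one treatment against the
  control.
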