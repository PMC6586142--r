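---
title: "Gene-signature biomarker scoring and evaluation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-signature biomarker scoring and evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscore)
```

## The problem

In facioscapulohumeral muscular dystrophy (FSHD), two transcriptomic
programs compete as candidate biomarkers: activation of DUX4 target genes,
and repression of PAX7 target genes. Both can be summarized into a single
number per sample from a gene-level expression matrix, and the two kinds of
summary behave very differently — activation signatures are driven by rare,
strong expression bursts (especially in single cells), while repression
signatures are a weak but pervasive shift affecting every diseased sample.
`sigscore` implements both score forms and the complete statistical stack
needed to compare them fairly on the same samples.

The package is deliberately agnostic about which genes are in a signature:
gene sets are supplied as GMT files (with a `__up`/`__down` naming
convention pairing the two halves of a repression signature), so any curated
program can be evaluated.

## The two score forms

**Two-set t-score (repression biomarker).** For one sample with
log-expression values, let $U$ be the values of the signature's up-regulated
genes and $D$ those of its down-regulated genes. The score is the Welch
two-sample t-statistic

$$ t \;=\; \frac{\bar U - \bar D}
     {\sqrt{s_U^2/n_U + s_D^2/n_D}} $$

with unbiased variances. When the up-targets are repressed the numerator
falls, so diseased samples trend negative. Because the statistic is computed
*within* a sample, it is invariant to adding a constant to that sample's
log-expression (a library-size shift), which is what makes it usable on
single cells without careful per-cell normalization.

Whether the original analyses used Welch or pooled variances is not
documented; we default to Welch because the two sets differ in size and
there is no reason to assume equal spread, and expose
`pooled = TRUE` for sensitivity analysis. Degenerate inputs follow an
explicit contract: fewer than two genes present in either set is an error;
zero variance in both sets with equal means returns 0 with a warning; zero
variance with unequal means is an error rather than an infinite score.

**Mean expression (activation biomarker).** The arithmetic mean of the
sample's log-expression over the signature's up-regulated genes present in
the matrix. Genes absent from the matrix are dropped (with a coverage
warning), never imputed; an average of several activation biomarkers is the
plain arithmetic mean of their per-sample values, which is meaningful
because all are means of log expression on one common normalized scale.

## Normalization

Input matrices are expected as genes × samples tables. Raw counts are
transformed as $\log_2(x + 1)$ — base and pseudocount are the dominant
RNA-seq convention and are configurable — and quantile normalized. Quantile
normalization uses the per-rank mean of the column-sorted values as the
reference distribution, with ties within a column receiving the mean of the
reference values across the tied rank span; this is the Bolstad convention
and the implementation delegates to `limma::normalizeQuantiles(ties = TRUE)`
behind the `quantile_normalize()` surface. The procedure is idempotent and
preserves within-column rank order; both properties are tested.

Normalization is applied jointly across all samples of a matrix (cases and
controls together), mirroring how whole public datasets are normalized
before biomarker evaluation.

## Group comparison, ROC and DeLong's test

Case/control score differences are tested with a two-tailed Wilcoxon
rank-sum test (`stats::wilcox.test` behind `wilcoxon_rank_sum()`), using the
exact null distribution when $n_x n_y \le 400$ and the data are tie-free,
and the tie- and continuity-corrected normal approximation otherwise.

ROC curves and AUCs are computed from the Mann–Whitney U-statistic with 0.5
credit for ties. Orientation matters for repression-type scores, which are
*lower* in cases: `direction = "auto"` (the default) orients each biomarker
by its group-mean ordering so an informative biomarker scores above 0.5,
and the resolved direction is recorded in every result rather than silently
applied.

Correlated AUCs measured on the same samples are compared with DeLong's
test, implemented from the structural components (placements): for each
case the fraction of controls it beats (ties 0.5), and for each control the
fraction of cases it loses to. Placements are computed with midranks in
$O(N \log N)$. The variance of an AUC difference combines the 2×2
covariance matrices of the paired placement vectors,
$\mathrm{var} = (S^{X}_{11} + S^{X}_{22} - 2S^{X}_{12})/m +
(S^{Y}_{11} + S^{Y}_{22} - 2S^{Y}_{12})/n$, and
$z = (\hat A_1 - \hat A_2)/\sqrt{\mathrm{var}}$ is referred to a standard
normal. A degenerate zero variance (notably a biomarker compared with
itself) is reported as $z = 0$, $p = 1$. The test suite validates the AUC
against brute-force pairwise enumeration, the placements against their
U-statistic identity, the paired p-values against a paired bootstrap, the
single-AUC variance against the empirical variance over thousands of
simulated datasets, and the whole stack against the independent pROC
implementation.

## Severity models and stratification

Associations between biomarkers and numeric severity covariates
(histopathology scores, inflammation, MRI read-outs) are ordinary least
squares fits of `covariate ~ biomarker`, reported with the standard
per-coefficient estimate, SE, t and two-sided Pr(>|t|). Multivariate models
fit several biomarkers as separate covariates jointly to test independent
association. P-values are reported unadjusted — the convention of the
analyses this package supports — and the number of tests performed is
recorded alongside. Missing severity values are excluded pairwise per fit,
with complete-case counts reported; fits with too few complete cases are
skipped with a warning, never silently. Binary severity measures are
treated as 0/1 numeric responses in these linear fits (a deliberate
simplification matching the linear-model treatment of MRI status reads).

The stratification workflow derives its cut points from the data: the
activation threshold can be chosen as the smallest value above which every
sample shows active disease (`minimal_activation_threshold()`, ties broken
toward the smaller threshold), and the repression threshold is the mean
repression score of the high-activation samples. "Above" and "below" are
strict inequalities; samples exactly at a threshold fall in the
complementary group. The activity ratio compares mean activity between the
high- and low-repression strata of the high-activation samples; a zero
denominator is flagged rather than returned as infinity.

## Single-cell positivity

A cell is called signature-positive when at least $k$ of the signature's
up-regulated genes exceed a detection threshold; the default threshold 0
("detected" means any nonzero expression) matches the count-based notion of
a detectable target program, and $k = 1$ versus $k = 5$ distinguishes "any
detectable expression" from "broad program expression". Positivity-defined
subsets feed `subset_roc_comparison()`, which re-runs the ROC/DeLong
machinery on only the positive (or only the negative) cells — the analysis
that asks whether a repression biomarker still discriminates disease in
cells where the activation program is invisible. In the single-cell
pipeline, positivity and scoring are computed on $\log_2(\text{count}+1)$
values *without* quantile normalization, so that "detected ⇔ count > 0"
remains exact; quantile normalization of zero-inflated columns would map
some zeros to small positive reference values.

## The synthetic data generators

Both generators are first-class, tested code: they define the conditions
under which every downstream claim is validated.

**Bulk (`simulate_bulk`).** Defaults are the bulk study conditions: 34
cases and 9 controls; a repression signature of 311 up / 290 down genes and
three activation signatures of 114, 165 and 212 genes, disjoint by
construction so the planted doses stay identifiable; 5000 genes in total,
chosen so the 1082 signature genes stay a minority of the transcriptome —
quantile normalization assumes most genes are unchanged between samples,
and a generator in which half the genes carry planted effects would have
its signal partly normalized away. Gene baselines are
$N(5, 2^2)$ on the log2 scale with $N(0, 1)$ per-gene-per-sample noise.
Cases carry the repression program scaled by a per-sample dose
$\sim U(0.5, 1.5)$ (disease-severity heterogeneity), and an activation
program with the same dose structure. Severity is generated from the true
doses: $\text{activity} = a + b\,\text{dose}_{rep} + c\,\text{dose}_{act} +
\varepsilon$, so coefficient-recovery tests have a known ground truth.

Effect sizes are calibrated analytically. With per-gene noise SD $\sigma$, a
planted shift of $\pm\delta$ moves the per-sample t-score by
$2\delta/(\sigma\sqrt{1/n_{up}+1/n_{down}})$ of its own across-sample
spread — the gene-baseline variance cancels because baselines are fixed
across samples — so under the binormal model the population AUC is
$\Phi(d/\sqrt 2)$ and `repression_effect_for_auc()` inverts this exactly.
The default targets an AUC of 0.93, a typical performance level for these
biomarkers on well-powered bulk biopsy cohorts. The per-sample dose
heterogeneity slightly inflates the case-score spread, so realized AUCs sit
a little below the nominal target (about 0.89 at a nominal 0.9); the
planted-recovery test band accounts for this.

**Single cell (`simulate_single_cell`).** Defaults are the single-cell
study conditions: 5133 case and 1914 control cells over 1500 genes. Counts
are Poisson draws from a latent log-normal level (gene baseline
$N(1.5, 1)$ plus $N(0,1)$ cell noise), thinned by Bernoulli dropout
(default rate 0.3). Every case cell carries a weak repression shift; the
default is calibrated numerically — the Poisson observation and dropout
attenuate a latent log2 shift, and the calibration integrates the
attenuation and the observed-scale SD over the latent distribution —
targeting a population AUC of 0.651 on $\log_2(\text{count}+1)$ scores.
The calibration is approximate through the count layer; realized population
AUCs come out near 0.63, which is the regime the qualitative claims need
(clearly informative, far below bulk performance).

Activation is all-or-nothing: activation-signature genes sit at a very low
latent baseline (default $2^{-15}$ relative scale, i.e. silent), and a
burst adds a joint shift lifting them to roughly two expected counts per
gene. A fraction of case cells (default 19.7%) burst; control cells burst
spuriously at a leak fraction (default 7.8%). These two defaults are the
detectable-fraction conditions the single-cell analyses report. Because a
burst shifts all activation genes jointly, bursting cells typically detect
many signature genes; real cells show a more graded pattern in which most
detectable cells express only one to four target genes — the generator does
not attempt to reproduce that gradation, so positivity fractions at high
$k$ are close to the burst fraction rather than much smaller, and passing
tests say nothing about graded low-$k$/high-$k$ differences in real data.

Other limitations shared by both generators: genes are independent given
the planted programs (no co-expression structure), there are no batch or
library-size artifacts, and signature gene sets are exactly known rather
than noisy curations. Tests passing under these conditions validate the
statistical machinery and the qualitative design of the analyses, not the
numerical values any particular real dataset would produce.

Reproducibility: every generator output is a pure function of its
`sim_config`, including the seed. Sub-seeds are derived per component
(gene baselines, doses/bursts, noise, counts/dropout, severity), so
changing, say, the severity noise level leaves the expression matrix
byte-identical — a property the test suite asserts.

## Numerical and design choices

- AUC ties get 0.5 credit everywhere (curve, placements, variance), so the
  curve's trapezoidal area and the U-statistic agree to machine precision.
- The Wilcoxon exact/approximate branch boundary ($n_x n_y \le 400$,
  tie-free) balances enumeration cost against approximation error; the two
  branches agree to within 0.01 in p at the boundary.
- OLS uses QR factorization; rank deficiency is an error naming the
  collinear columns rather than a silently dropped coefficient.
- `read_expression_table` validates hard: duplicate gene IDs, ragged rows
  and non-numeric cells are errors naming the offending location, because
  silent coercion corrupts downstream scores.
- File outputs (Results.csv, expression tables) are written at full
  precision (17 significant digits) so that reruns are byte-identical and
  round trips are exact.
- The command-line interface preserves the scoring-app input contract (a
  log-normalized table plus a single-column list of case column numbers)
  so it can be dropped into existing workflows; plots are emitted as
  plot-ready CSV summaries (group medians, quartiles, 1.5·IQR whisker
  bounds) with rendered images optional.

## Problem sizes used in validation

The statistical validation suite uses: 1000-instance fuzz checks for the
AUC and t-score oracles; 20 paired datasets of 30+30 samples against a
B = 2000 bootstrap; 5000 simulated datasets of 50+50 for variance
calibration; 1000 null replicates of 200+200 for Wilcoxon type-I error;
500 random designs for the OLS oracle; 100 seeds of a 40+10 bulk cohort
for planted-AUC recovery; and 100 replicates of 2000+800 cells for the
single-cell qualitative reproduction. These sizes were chosen as the
smallest at which the respective stochastic tolerances are comfortably
stable.
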