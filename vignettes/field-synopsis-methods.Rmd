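---
title: "Methods: meta-analysis and evidence grading for a genetic field synopsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis and evidence grading for a genetic field synopsis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesynopsis)
```

## The problem

A *field synopsis* compiles every candidate-gene case-control association
study of one disease, re-analyses each variant by meta-analysis, and
grades how credible the cumulative evidence is.  The unit of input is one
study's genotype counts for cases and controls of one variant; the unit
of output is a pooled odds ratio per variant x genetic model x subgroup,
with heterogeneity, publication-bias and sensitivity diagnostics and a
Venice-criteria grade.  `genesynopsis` implements that statistical core.
Literature search, screening and manual data extraction — human
processes — are out of scope, as is any web database front end.

## Genetic models

For a variant with effect allele A and other allele a, per-study genotype
counts `(n_AA, n_Aa, n_aa)` collapse to a 2x2 case/control x
exposed/unexposed table:

* **additive (allele) model** — A vs a allele counts: exposed
  `2 n_AA + n_Aa`, unexposed `2 n_aa + n_Aa` (the table counts alleles,
  so totals are twice the subject totals);
* **dominant** — carriers vs non-carriers, `(AA + Aa)` vs `aa`;
* **recessive** — `AA` vs `(Aa + aa)`;
* **carrier** — present vs null, for deletion-type variants (GSTM1-like)
  recorded as present/null.

The dominant and recessive contrasts follow the universal convention for
a high-risk allele A.  Orientation is fixed once per contrast by the
declared effect allele and never re-derived from the minor-allele
frequency, which can flip between populations and silently reverse the
direction of effect.  Genotype-scheme and carrier-scheme records of the
same gene are never pooled together: the contrasts count different
things.

## Per-study effects

The study-level effect is the log cross-product odds ratio with Woolf
standard error `sqrt(1/a + 1/b + 1/c + 1/d)`.  Zero cells get the
Haldane–Anscombe correction — 0.5 added to *all four* cells, flagged in
the result — the default in mainstream meta-analysis software.  A table
with an entire zero row or column carries no information about the odds
ratio and raises a degenerate-table error; the pipeline drops such
studies with a logged reason rather than aborting the variant.

Hardy–Weinberg equilibrium in controls is tested with the asymptotic
1-df Pearson chi-square against expected proportions `(p², 2pq, q²)`,
with `p` the observed control effect-allele frequency, no continuity
correction, and alpha 0.05.  Exact tests are deliberately not offered:
at typical control-arm sizes the asymptotic test's calibration is
adequate (verified by simulation in the test suite) and the field's
convention is the chi-square.  Monomorphic controls satisfy HWE
trivially and are flagged degenerate.  HWE violation does **not**
exclude a study from the primary analysis; it drives a sensitivity
re-analysis (below), since deviation may denote genotyping error or
selection bias.

## Pooling and heterogeneity

Fixed-effect pooling is the inverse-variance average with weights
`w_i = 1/se_i²`.  Heterogeneity is quantified by Cochran's
`Q = sum(w_i (theta_i - theta_F)²)` (chi-square, `k - 1` df, giving the
heterogeneity p-value `Ph`), by `I² = max(0, (Q - df)/Q) x 100`
(mild < 25%, moderate 25–50% inclusive, large > 50%), and by the
DerSimonian–Laird moment estimator
`tau² = max(0, (Q - df) / (sum(w) - sum(w²)/sum(w)))`.

The primary reported estimate is always the DerSimonian–Laird
random-effects pool: weights `1/(se_i² + tau²)`, 95% CI
`exp(log_or ± 1.96 se)`, two-sided normal p.  REML or Paule–Mandel
estimators are not offered — the package reproduces the classic
field-synopsis toolchain, and with `tau² = 0` the random-effects result
collapses exactly to the fixed-effect one, which is retained as a
diagnostic column.

**Eligibility.** A meta-analysis (or subgroup analysis) requires at
least three *independent sources*, counted as distinct publications:
two cohorts inside one publication count once toward eligibility but
both contribute effects.  This stabilises `I²` and makes leave-one-out
analysis meaningful.

## Publication bias and sensitivity

*Egger's test* regresses the standardized effect `theta_i/se_i` on the
precision `1/se_i` (the classic formulation) and t-tests the intercept
with `k - 2` df.  *Begg's test* rank-correlates the standardized
deviates `(theta_i - theta_F)/sqrt(v_i - v_F)` with the variances,
using tie-corrected Kendall tau and its normal approximation; the
radicand is floored at 1e-12 to avoid negative values from rounding.
Both tests have low power at small k and are flagged `low_power` below
10 studies (a reporting convention, not a refusal).  Funnel-plot data
are exposed as plain coordinates; no rendering decision is made in the
statistical layer.

Two sensitivity analyses accompany every pooled result: leave-one-out
re-pooling (robust = no single omission flips significance at 0.05;
omission sets below three studies are computed but flagged) and
re-pooling after excluding HWE-violating studies.

## Venice grading

Each nominally significant result is graded A/B/C on three axes:

* **amount of evidence** — total copies of the tested allele among cases
  and controls combined: A above 1,000, B from 100 to 1,000 inclusive,
  C below 100, with a caution attached for rare variants (frequency
  < 1%), for which an A is effectively unobtainable;
* **replication** — `I²` of the reported model: A < 25%, B 25–50%
  inclusive, C > 50%;
* **protection from bias** — automated rules only: OR magnitude
  `max(OR, 1/OR)` below 1.15 gives C unless a manual
  prospective-replication flag exempts it; Egger p < 0.05 (or a hard
  manual flag) gives C; Egger p in [0.05, 0.10) or a soft flag gives B;
  otherwise A.  Genotyping error, population stratification and
  phenotype misclassification are judgment calls that cannot be
  automated; they enter only through the manual flags.

The composite label is **strong** iff all three letters are A, **weak**
iff any letter is C, **moderate** otherwise; the mapping is monotone in
each letter.  The amount letter depends on genotype-level totals that
published synopsis tables often do not print, and published amount
letters are known to be judgment-laden; the package therefore treats
amount and bias letters as reproducible only from its own rules, while
the replication letter and the composite mapping are checked 31/31
against the bundled published table.

## The bundled synopsis fixture

`synopsis_fixture()` returns a transcription of the 31 variant x model
rows of a published hepatocellular-carcinoma field synopsis (pooled OR,
95% CI, printed P, Ph/I², grade string, evidence label; allelic-contrast
columns for rows graded on a dominant or recessive model).  Printed P
values are stored as character to preserve displayed precision ("0"
means below 0.0005 at three printed decimals).  It anchors three
self-consistency checks: the composite rule reproduces all 31 labels
(1 strong / 14 moderate / 16 weak), the replication rule reproduces all
31 middle letters from the printed model-specific I², and each printed
OR/CI/P triplet is Wald-consistent — the p-value implied by
`se = (log hi - log lo)/(2 x 1.96)` falls within the printed P's
rounding band once the OR and CI's own rounding is propagated; rows
whose rounding box yields a single printed representation must match
exactly.  Interval propagation is what makes this check honest: a CI
bound printed as 1.00 can shift the implied p by more than the printed
precision.

## What the simulator emulates

`simulate_dataset()` generates the data-generating process the analysis
assumes: control genotypes multinomial at Hardy–Weinberg proportions
for control effect-allele frequency `p0`; case genotypes from the same
proportions tilted by the multiplicative per-allele odds model
`P(g) ∝ HWE(g) exp(theta_i g)` with `g` the number of effect alleles —
chosen because under it the population *allelic* odds ratio equals
`exp(theta_i)` exactly, making parameter recovery a sharp oracle rather
than an approximation; study-level `theta_i ~ Normal(theta, tau²)`; and
publication bias as significance-threshold censoring (a study whose
additive-contrast p is at least `censor_alpha` is suppressed with
probability `censor_prob`) — the simplest mechanism that induces funnel
asymmetry and gives the Egger/Begg tests something detectable.

Each study draws from its own deterministically derived substream, so
changing `k` never reshuffles earlier studies and a fixed seed yields a
byte-identical CSV.  Defaults are chosen to resemble the candidate-gene
literature: per-arm sizes of a few hundred subjects, common variants
(`p0` around 0.3), and ethnicity labels drawn from a mixture dominated
by Asian cohorts, as in the hepatocellular-carcinoma literature the
fixture comes from.

The simulator does *not* emulate linkage disequilibrium between
variants, covariate confounding, genotyping error, or population
stratification.  Passing tests therefore demonstrate the statistical
engine's correctness under its own assumptions, not robustness of the
method to the messiness of real literature data.

## Verification problem sizes and numerical choices

The test suite verifies, at fixed seeds:

* worked small instances of every pooling, heterogeneity and bias
  statistic against hand arithmetic and closed forms, and against an
  independent implementation (metafor, DL method) on random instances;
* parameter recovery on one homogeneous meta-analysis of k = 200
  studies (2,000 subjects per arm, theta = 0.3) and on 500
  heterogeneous replicates (k = 20, tau² = 0.05), requiring empirical
  95% CI coverage in [90%, 98%] and mean estimated tau² within 20% of
  truth — sizes at which the DerSimonian–Laird estimator's small-k bias
  is negligible relative to Monte-Carlo error;
* type-I calibration of the HWE test (2,000 replicates, 1,000 controls
  at p0 = 0.5) and the Egger test (500 unbiased funnels of 15 studies)
  within 99% binomial bands of the nominal 5%.

Numerical conventions worth naming: the 95% CI uses the literal 1.96
normal quantile (matching how published CIs are computed); p-values are
stored at full precision and *displayed* to three decimals with "0"
meaning below 0.0005; `I²` truncates at zero; Begg's variance floor is
1e-12; ties in Kendall's tau use the standard tie-corrected variance.
Displayed boundary conventions (amount "100 to 1,000" inclusive B,
`I²` in [25, 50] inclusive B) were fixed by checking them against all
31 printed middle letters of the bundled table.

## Known limitations

* Amount and bias letters automate only the codifiable rules; published
  grades mixing in expert judgment will not always be reproduced.
* No multiple-testing correction is applied across variants (nominal
  p-values, matching field practice); an adjusted column can be derived
  by the caller.
* The presentation rule for null variants (at least six independent
  datasets) is a reporting filter, not a statistical one; all computed
  results remain available in the report object.
* Fixed- and random-effects pooling assume within-study normality of
  the log OR; for very sparse tables (rare variants, small studies) the
  Woolf variance is itself noisy, and no exact or Mantel-Haenszel
  pooling is offered.
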