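# genesynopsis

Statistical machinery for a **field synopsis** of candidate-gene
case-control association studies: given per-study genotype counts for
one disease, it pools each variant's effect under additive, dominant,
recessive or carrier genetic models, quantifies heterogeneity and
publication bias, runs the standard sensitivity analyses, and grades the
cumulative epidemiological evidence on the Venice criteria.  It is aimed
at genetic epidemiologists compiling or auditing disease synopses, and
ships a seeded simulator of multi-study genotype data so every stage is
testable without any external dataset.

## The model

For study *i*, the 2x2 contrast (e.g. A-vs-a allele counts under the
additive model) yields the log odds ratio
*θ̂ᵢ* = log(a·d/(b·c)) with Woolf variance
*vᵢ* = 1/a + 1/b + 1/c + 1/d (all cells +0.5 when any cell is zero).
Heterogeneity across *k* studies is measured by Cochran's
*Q* = Σ wᵢ(θ̂ᵢ − θ̂_F)², wᵢ = 1/vᵢ, by
*I²* = max(0, (Q − df)/Q)·100, and by the DerSimonian–Laird moment
estimator *τ²* = max(0, (Q − df)/(Σw − Σw²/Σw)).  The primary estimate
is the random-effects pool with weights 1/(vᵢ + τ²), 95% CI
exp(θ̂ ± 1.96·se), two-sided normal *p*.  Egger's regression
(θ̂ᵢ/seᵢ on 1/seᵢ) and Begg's tie-corrected rank correlation test
funnel asymmetry; leave-one-out and Hardy–Weinberg-exclusion
re-analyses probe robustness.  Nominally significant pools are graded
A/B/C on amount of evidence (tested-allele copies: >1000 / 100–1000 /
<100), replication (*I²*: <25% / 25–50% / >50%) and protection from
bias (OR magnitude < 1.15 or Egger p < 0.05 ⇒ C), combined into
**strong** (AAA), **weak** (any C) or **moderate** (otherwise).

## Worked example

```r
library(genesynopsis)

cfg <- sim_config(k = 8, n_cases = c(150, 1500), n_controls = c(150, 1500),
                  p0 = 0.3, theta = 0.25, tau2 = 0.02, seed = 42)
studies <- simulate_dataset(cfg)

m <- meta_analyze(studies, "rs0000001", model = "additive")
m
#> GENE1 rs0000001 (additive model, all): 8 studies, 8 sources
#>   random-effects OR 1.32 (95% CI 1.20-1.45), p = 0
#>   Q = 11.85 (df 7, p = 0.106), I2 = 40.9% (moderate), tau2 = 0.0074

eg <- egger_test(m$effects)
venice_grade(m, bias = eg)
#> Venice grade ABA -> moderate
#>   amount=A (5973 tested-allele copies); replication=B (I2 = 40.9%);
#>   bias=A (OR magnitude 1.32, Egger p 0.852)

leave_one_out(studies, "rs0000001")
#> leave-one-out over 8 studies: baseline OR 1.32 (p = 0), robust
```

The simulated truth was a per-allele OR of e^0.25 ≈ 1.28 with moderate
between-study variance; the pool recovers 1.32 (CI 1.20–1.45), the
printed "p = 0" means p < 0.0005 at three displayed decimals, and the
I² of 40.9% lands the replication grade B, so the composite evidence is
*moderate*.  `run_synopsis()` applies the same analysis to every variant
x model x ethnicity subgroup of a study table, enforcing the
three-independent-source eligibility rule and presenting non-significant
variants only when six or more independent datasets contribute;
`write_synopsis()` renders the report as CSV or markdown.  A thin
command-line wrapper with `simulate` / `analyze` / `grade` / `selfcheck`
subcommands lives at `inst/scripts/synopsis-cli.R`.

The package also bundles `synopsis_fixture()`, a machine-readable
transcription of a published 31-variant hepatocellular-carcinoma
synopsis (pooled ORs, CIs, printed P, Ph/I², grade strings, evidence
labels) used by the self-consistency test suite.

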