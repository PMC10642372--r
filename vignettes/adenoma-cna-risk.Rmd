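---
title: "Molecular risk of metachronous colorectal cancer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular risk of metachronous colorectal cancer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adenomaRisk)
```

## The scientific question

Patients who have a colorectal adenoma removed are stratified for
surveillance by the adenoma's morphology: an *advanced* adenoma (size
≥ 10 mm, high-grade dysplasia, or ≥ 25% villous component) marks the
patient as high risk for a later, metachronous colorectal cancer
(me-CRC). Chromosomal instability offers an alternative, molecular
stratification: seven recurrent arm-level copy-number changes — gains of
8q, 13q and 20q, losses of 8p, 15q, 17p and 18q, the *cancer-associated
events* (CAEs) — accompany the adenoma-to-carcinoma transition, and an
adenoma carrying two or more of them can be called molecular high-risk.
`adenomaRisk` implements the machinery needed to compare the two
classifications within a surveillance cohort using a nested case–control
design, together with a synthetic-cohort generator so that every stage is
testable without access to registry data.

## Copy-number classification

The classification chain is deliberately simple and fully deterministic:

1. **Bin calling.** Each fixed-width genomic bin carries a log2 ratio
   relative to the diploid state. A bin is called a gain at or above
   `gain_threshold` (default +0.10), a loss at or below `loss_threshold`
   (default −0.10), normal in between. Mixture-model callers used on real
   sequencing data estimate these boundaries from the sample; here fixed,
   config-exposed thresholds are preferred because they are transparent,
   idempotent, and adequate at the noise levels the generator produces.
   With Gaussian bin noise of sd 0.05 the neutral band of ±0.10 sits two
   standard deviations from the neutral mean, so about
   `2 * pnorm(-2)` ≈ 4.6% of neutral bins are miscalled — an error rate
   that arm-level aggregation absorbs completely (the tests verify
   essentially perfect arm recovery at that noise level).
2. **Arm events.** Bins are assigned to the chromosome arm containing
   their midpoint, using a cytoBand-dialect arm map (an hg38 autosome map
   is packaged; the short arms of the acrocentric chromosomes 13–15, 21
   and 22 are excluded as uncallable). An arm is a gain (loss) when at
   least `min_fraction` (default 0.5) of its covered bins are called gain
   (loss); if both directions clear the bar the larger fraction wins, and
   an exact tie is neutral. The fraction rule is this package's
   convention — field practice varies and nothing sharper is forced by
   the data; it is config-exposed.
3. **Risk flags.** `cae_count` counts the direction-specific CAEs
   (0–7); `high_cae` is `cae_count >= 2`. Burden flags `high_cna`,
   `high_gain`, `high_loss` use ≥ 3 alterations counted at *arm*
   resolution, so a whole-chromosome change contributes two events (p and
   q). Counting per arm is a declared choice: per-segment counting would
   make the burden depend on segmentation granularity, which the
   arm-level analysis otherwise never uses.

## The nested case–control design

Cases (subjects who develop me-CRC) are matched to `M = 2` controls on
sex and baseline age within ±5 years (closed interval, ages compared as
stored), with controls drawn from the case's *risk set*: their follow-up
must last at least until the case's event time. Two control-eligibility
policies are provided. The default, `never_cases`, excludes anyone who
ever develops the event — mirroring a design in which controls were drawn
from subjects who never developed cancer. `risk_set` is the textbook
incidence-density rule in which a later case may serve as a control while
still event-free. Cases are processed in ascending order of event time
(ties broken by id): earlier cases face the largest risk sets, so this
order maximises feasibility and makes the output invariant to input row
order. Controls are sampled uniformly (seeded) from the sorted eligible
list, by default without replacement across sets; cases with fewer than
`M` eligible controls are dropped (or kept 1:smaller, by policy) and
always listed in the match report. An audit function re-checks every
emitted set against the eligibility rules.

## Conditional likelihood inference

For matched sets the per-set intercepts are eliminated by conditioning on
set membership, giving

$$\ell(\beta) = \sum_s \left[ x_{case}^\top\beta -
  \log \sum_{j \in s} \exp(x_j^\top\beta) \right]$$

implemented with exact analytic gradient and hessian (the within-set
log-sum-exp is stabilised by subtracting the set maximum). Newton–Raphson
starts at zero with step halving (up to 20 halvings), converging when the
largest absolute gradient component drops below `tol = 1e-8`
(`max_iter = 50`). Sets in which no covariate varies carry no information
and are only counted in diagnostics. Complete separation is declared when
a coefficient exceeds 10 in absolute value — on the odds-ratio scale that
is beyond e^10 ≈ 22,000, far outside anything a matched epidemiological
analysis can support — and reported as an error naming the covariate;
under separation the conditional-likelihood gradient shrinks
monotonically toward zero, so a gradient-based trigger alone would
silently "converge" onto a divergent coefficient. Inference is Wald:
OR = exp(β̂), 95% limits exp(β̂ ± 1.96·se), p from z = β̂/se.
Profile-likelihood intervals are out of scope.

The 1-df conditional score test evaluates U(0)²/I(0) for a single
covariate; for a binary exposure this equals the Cochran–Mantel–Haenszel
statistic without continuity correction, which the tests verify against
`stats::mantelhaen.test`. Model discrimination is summarised by a
matched concordance: over all within-set (case, control) pairs, the
fraction in which the case has the higher linear predictor, ties counting
one half. Restricting pairs to within-set comparisons is a declared
convention — it respects the matching, but its absolute value is not
comparable to a concordance computed over all unmatched pairs.

Design matrices are built from explicit term lists: numeric covariates
(age enters in years, untransformed, so its OR is per year), indicators
with a stated reference level, products of previously defined columns for
interactions, and a combined 4-level categorical over two binary flags
(morphology × molecular class) with a selectable reference cell — the
latter reproduces subgroup contrasts within a single fit instead of
refitting per pair.

## Survival components

`km_estimate` is the product-limit estimator over distinct event times;
at tied times events are handled before censorings (the standard
convention: a subject censored at *t* is still at risk at *t*).
`logrank_test` compares k groups via the summed hypergeometric
observed-minus-expected vector and its summed covariance matrix, with
k − 1 degrees of freedom; single-subject risk sets contribute zero
variance. `stratified_window_or` assigns each matched set to the
time window (lo, hi] containing its case's event time — default windows
(0,1], (1,2], (2,3], (3,∞) years — and fits the conditional model per
window; windows with no informative sets (common in the first year, where
few sets fall) are flagged rather than fitted. Pooling all windows
reproduces the full-data fit, which the tests check. Kaplan–Meier
comparisons in the pipeline run on cohort subgroups defined by the
baseline classification, with time measured from baseline; an optional
truncation (e.g. at 5 years) restricts attention to early events.

## Design arithmetic

The power module reproduces a matched study's planning arithmetic.
`expected_prevalence` mixes class-conditional prevalences by class
weights. `shift_to_target_or` moves a (case, control) prevalence pair
along a mean-preserving line until the odds ratio hits the target, by
root-finding on the case prevalence (the log odds ratio is strictly
monotone along the line; the result satisfies both constraints to
1e-10). The default constraint preserves the arithmetic mean; a
1:M-weighted variant is available because "maintaining the average
proportion" is ambiguous in a design with twice as many controls, and
explicit planned proportions may be supplied to bypass the shift
entirely. `analytic_power` is the two-proportion normal approximation;
the default uses the pooled-variance standard error in both roles, which
reproduces the conventional ≥ 90% figure for a 32% vs 13% comparison with
69 cases and 137 controls, while the unpooled-alternative variant gives
about 88.5% for the same design — both are exposed because published
power statements rarely say which was used. `simulate_power` validates
the approximation with the design's own test: each replicate draws
independent Bernoulli exposures for 1:M sets and applies the conditional
score test. `prevalence_sample_size` is the standard p(1−p)/SE²
formula; its outputs are reported in the design report but deliberately
not asserted against any rounded published target, since rounding
conventions in such calculations are rarely recoverable.

## The synthetic cohort: what it does and does not emulate

The generator's defaults are the study conditions, chosen once:

- morphology: advanced with probability 0.505;
- molecular high risk (≥ 2 CAEs): probability 0.318 given advanced,
  0.103 given non-advanced;
- CAE multiplicity: high-risk subjects carry 2 + Binomial(5, 0.2) CAEs,
  low-risk subjects one CAE with probability 0.35, else none; a
  background alteration rate of 0.04 per remaining arm (constrained to
  the non-CAE direction on CAE arms so the planted high/low label is
  never disturbed) produces realistic burden variation for the ≥ 3
  CNA/gain/loss classes;
- age: truncated normal, mean 69, sd 10, minimum 40 (cohort entry rule);
  sex: 44% male;
- events: exponential with rate 0.003/year times exp(Σ log-OR ×
  covariate); default planted effects are rate ratios 2.9 for advanced
  morphology and 2.3 for ≥ 3 losses. Because me-CRC is rare, these
  hazard-scale rate ratios are interchangeable in practice with the odds
  ratios the matched analysis estimates (the rare-event OR ≈ HR
  approximation), which parameter-recovery tests confirm within
  simulation error;
- censoring: uniform administrative censoring on (5.5, 20.5) years —
  a 20.5-year horizon with a 15-year staggered accrual period. The real
  entry/exit process behind a median follow-up of about 13 years is not
  recoverable from summary statistics; this two-parameter approximation
  reproduces the median (the generator tests check it lands within 1.5
  years) and the broad IQR shape, and is documented as an approximation
  rather than an estimate.

Bin-level profiles encode an arm gain as a segment mean of +log2(3/2)
≈ +0.58 (one extra copy) and a loss as −1 (one of two copies lost),
plus i.i.d. Gaussian noise. Real FFPE low-coverage sequencing data differ
in ways the generator deliberately ignores: GC/mappability waves,
tumour-cell fraction diluting segment means, focal and sub-arm events,
and correlated noise. Passing round-trip tests therefore demonstrates the
correctness of the classification logic, not robustness to those
artifacts; the threshold caller is not claimed to replace a
mixture-model caller on real data.

## Numerical and testing choices

Percentages in report tables are rounded to one decimal, half away from
zero, matching clinical-table convention. All randomness flows from one
root seed, split deterministically per pipeline stage; identical config
and seed reproduce every output table byte for byte. Test problem sizes
are chosen to make sampling error negligible relative to the tolerance
being asserted: prevalence convergence at n = 20,000 with 4·SE bands,
parameter recovery on 2,000 matched sets with coverage over 200
replicates, type-I error checks at 1,000 null replicates with acceptance
region (0.03, 0.07), and oracle equivalences (likelihood enumeration,
CMH, product-limit, log-rank) at 1e-9 to 1e-12 on small fixed instances.
Cross-checks against the `survival` package are used only in tests; the
package's own estimators are the implementation everywhere.

## Known limitations

- The threshold caller assumes profiles centred on a diploid baseline;
  no purity/ploidy correction is attempted.
- Burden counts are arm-resolution; sub-arm and focal alterations are
  invisible to every risk definition implemented here.
- The matched concordance uses within-set pairs only and is not
  comparable across matching designs.
- Exact conditional inference and bias-reduced (Firth-type) estimation
  are not implemented; sparse strata (e.g. one-year windows with a
  handful of sets) either separate — reported as such — or carry very
  wide Wald intervals, which is a faithful property of the design, not a
  defect of the fitter.
- The cohort generator simulates one adenoma per subject and no
  competing mortality; follow-up ends at event or administrative
  censoring.
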