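# adenomaRisk

Tools for asking whether the DNA copy-number profile of a colorectal
adenoma removed at baseline predicts the patient's risk of a later,
*metachronous* colorectal cancer (me-CRC) — and for comparing that
molecular risk classification with the conventional morphologic one
(advanced vs non-advanced adenoma). The package is aimed at
biostatisticians and cancer-epidemiology researchers who want a tested,
reproducible implementation of the full nested case–control workflow:
cohort simulation, arm-level copy-number classification, incidence-density
matching, matched conditional-likelihood inference, survival analysis, and
matched-design power arithmetic.

## What it computes

**Molecular risk classification.** Binned log2-ratio copy-number profiles
are thresholded into loss/normal/gain calls, aggregated to chromosome-arm
events, and scored against the seven direction-specific
*cancer-associated events* (CAEs): gains of 8q, 13q, 20q and losses of 8p,
15q, 17p, 18q. An adenoma with ≥ 2 CAEs is molecular high-risk; three
further burden-based definitions (≥ 3 CNAs, ≥ 3 gains, ≥ 3 losses) are
computed alongside.

**Nested case–control inference.** Each me-CRC case is matched to M
controls by incidence-density (risk-set) sampling — same sex, baseline age
within ±5 years, follow-up at least as long as the case's time to event.
Odds ratios come from conditional logistic regression implemented from the
matched conditional likelihood

    l(β) = Σ_s [ x_case·β − log Σ_{j∈s} exp(x_j·β) ]

maximised by Newton–Raphson with step halving, with Wald 95% intervals, a
1-df conditional score test (equal to the Cochran–Mantel–Haenszel
statistic for binary exposures), matched concordance, subgroup and
interaction encodings, and a time-window-stratified analysis. Kaplan–Meier
curves and the k-group log-rank test are implemented from the
product-limit definition.

**Design arithmetic.** Weighted null prevalences, shifting a prevalence
pair to a target odds ratio under a mean-preserving constraint, analytic
power for comparing exposure prevalences between n₁ cases and n₂ controls
(pooled or unpooled variance), simulated power of the matched score test,
and prevalence-estimation sample sizes.

**Synthetic cohort.** Because the motivating registry data cannot be
redistributed, the package ships a first-class generator producing
cohorts with the same statistical structure: ~50.5% advanced adenomas,
molecular high risk in ~31.8% of advanced and ~10.3% of non-advanced
adenomas, exponential event times with covariate rate ratios (advanced
≈ 2.9, ≥ 3 losses ≈ 2.3), and staggered-entry administrative censoring
giving a median follow-up near 13 years, plus bin-level profiles
consistent with each subject's simulated arm events.

## Worked example

```r
library(adenomaRisk)

coh <- generate_cohort(cohort_params(2000, seed = 5))
coh
#> <cohort> 2000 subjects: 51.6% advanced, 21.1% molecular high-risk,
#>          186 events, median follow-up 12.0 y

crosstab_morphology_molecular(coh)
#> Molecular (high_cae) x morphologic classification, n = 2000
#>      advanced   non_advanced Total
#> High 338 (32.8) 84 (8.7)     422 (21.1)
#> Low  694 (67.2) 884 (91.3)   1578 (78.9)

ms <- match_cases(coh, M = 2, seed = 5)
ms
#> <matched_sets> 186/186 cases matched 1:2 (0 dropped, 0 short);
#>                558 subjects in sets

md <- matched_data(ms, coh)
md$advanced <- md$morphology == "advanced"
spec <- design_spec(term_numeric("age_at_baseline"),
                    term_indicator("advanced"),
                    term_indicator("high_loss"))
fit_clogit(md, spec)
#> Conditional logistic fit: 186 sets (186 informative), loglik -165.111
#>        covariate         OR (95% CI)        p
#>  age_at_baseline 0.974 (0.889-1.067) 5.73e-01
#>         advanced 4.066 (2.617-6.317) 4.36e-10
#>        high_loss 3.026 (1.823-5.022) 1.85e-05
```

The crosstab percentages are the within-morphology prevalence of the ≥ 2
CAE class (32.8% of advanced, 8.7% of non-advanced adenomas here — close
to the generator's 31.8%/10.3% targets). The matched fit recovers the
planted rate ratios: an advanced adenoma at baseline roughly quadruples,
and ≥ 3 copy-number losses roughly triples, the within-set odds of me-CRC
in this simulation (the generator planted 2.9 and 2.3; a single 186-set
cohort estimates them with wide intervals).

The design arithmetic behind a 69-case/137-control study:

```r
design_report(planned_p_case = 0.32, planned_p_ctrl = 0.13)
#> Matched case-control design report
#>   null prevalence: cohort 13.6%, cases 16.6%, controls 13.1%
#>   shifted to OR 3: cases 0.214, controls 0.083
#>   design 69 cases / 137 controls at alpha 0.05
#>   analytic power: 90.3% (pooled), 88.5% (unpooled)
```

An end-to-end run (simulate → classify → match → fit → survival → design),
writing every report table plus a manifest:

```r
run_study(read_study_config(system.file("config", "demo.yaml",
                                        package = "adenomaRisk")),
          outdir = "study_out")
```

or from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "adenomarisk.R",
                                      package = "adenomaRisk"))') \
    run-all --config inst/config/demo.yaml --outdir study_out
```

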