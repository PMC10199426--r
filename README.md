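# neutrality

Clinical studies of rare diseases often measure disease severity with ad hoc
endpoint sets rather than a validated disease-specific disease-severity scale
(DSS). `neutrality` quantifies that mismatch and what it costs. Treating the
indicator set of a DSS as a surrogate for the disease phenotype, each study's
endpoints are classified against the scale over the *observation universe* —
every indicator seen in any study of that disease — into four cells:

|                      | in the scale | outside the scale |
|----------------------|--------------|-------------------|
| **used by the study**| overlap *a*  | redundant *b*     |
| **not used**         | missing *c*  | irrelevant *d*    |

From these cells:

- sensitivity `Se = a / (a + c)` — the share of scale indicators the study measured;
- specificity `Sp = d / (b + d)` — the share of out-of-scale indicators it avoided;
- **Neutrality** `N = Se + Sp`, with `N = 2` a perfect match and `N > 1.50`
  an acceptable one.

The mismatch is then propagated into misclassification risk. For a prevalence
*p* of severe disease, with `Se` and `Sp` treated as independent of *p*:

    PPV = Se·p / (Se·p + (1−Sp)(1−p))        FP rate = 1 − PPV
    NPV = Sp(1−p) / (Sp(1−p) + (1−Se)p)      FN rate = 1 − NPV

both analytically and by seeded Monte Carlo simulation over trial-sized
cohorts (default 30 subjects, 1000 replicates, prevalence grid 20/50/80%).
For diseases with several scales, study endpoints can be scored against the
first published scale and against a composite (the deduplicated union of the
later scales), with the mean-Neutrality delta measuring whether the growing
body of knowledge converged with what trials actually measure.

The package is aimed at methodologists and trialists selecting endpoints:
score a curated endpoint corpus, find the diseases and studies where severity
measurement is weakest, and see the false-positive/false-negative consequences
of an endpoint set before using it as an inclusion criterion.

## Worked example

```r
library(neutrality)

scale <- severity_scale("achalasia demo", "demo severity score", 2000,
                        c("Dysphagia", "Regurgitation", "Chest pain", "Weight loss"))
studies <- list(
  study_endpoints("achalasia demo", "trial A",
                  c("dysphagia", "regurgitation", "chest-pain", "weight loss"),
                  sample_size = 45),
  study_endpoints("achalasia demo", "trial B",
                  c("Dysphagia", "Quality of life", "Hospital stay"),
                  sample_size = 30),
  study_endpoints("achalasia demo", "trial C",
                  c("Quality of life", "Mortality"))
)
ds <- disease_dataset(list(scale), studies)
(scores <- score_studies(ds))
#>   study_id     a     b     c     d sensitivity specificity neutrality acceptable
#> 1 trial A      4     0     0     3        1          1          2     TRUE
#> 2 trial B      1     2     3     1        0.25       0.333      0.583 FALSE
#> 3 trial C      0     2     4     1        0          0.333      0.333 FALSE
```

Labels are normalized before matching, so `"chest-pain"` and `"Chest pain"`
are one indicator. Trial A used every scale indicator and nothing else
(`b = c = 0`), hence `N = 2`; trial C measured no scale indicator at all
(`a = 0`, so `Se = 0`). The universe here has 7 indicators: the 4 scale items
plus quality of life, hospital stay and mortality, observed only as endpoints
of other studies.

```r
summarize_cohort(scores)[, c("n_studies", "mean_neutrality", "most_study_id",
                             "least_study_id", "n_acceptable")]
#>   n_studies mean_neutrality most_study_id least_study_id n_acceptable
#> 1         3           0.972 trial A       trial C                   1

extremes_report(scores, prevalence = c(0.2, 0.5, 0.8),
                simulate = TRUE, replicates = 1000, seed = 17)
#>   which study_id prevalence fp_rate fn_rate sim_fp_p50 sim_fn_p50
#> 1 most  trial A         0.2       0   0              0      0
#> ...
#> 4 least trial C         0.2       1   0.429          1      0.429
#> 5 least trial C         0.5       1   0.75           1      0.75
#> 6 least trial C         0.8       1   0.923          1      0.926
```

Because trial C's sensitivity is zero, every positive severity classification
it could make is a false positive (`fp_rate = 1` at every prevalence), and its
false-negative risk climbs with prevalence — the analytic rates and the
1000-replicate simulated medians agree.

Other entry points: `build_composite()` and `compare_scales()` for
first-vs-composite analyses, `synthetic_spec()` / `generate_dataset()` for
datasets with controlled target Se/Sp, `reference_tables()` for the curated
summary tables of a published systematic review of rare-disease severity
scales, `load_datasets()` / `run_pipeline()` for CSV-in, CSV-out batch runs,
and `inst/cli/neutral.R` for a shell interface.

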