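---
title: "Scoring endpoint-to-phenotype match and its misclassification cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring endpoint-to-phenotype match and its misclassification cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrality)
```

## The model

A disease phenotype can be idealized as the complete set of observable
indicators of the disease. That set is not empirically attainable, so a
validated disease-specific disease-severity scale (DSS) stands in for it.
Given one disease, the package works with three collections of normalized
indicator labels:

* the **reference set** — the indicators of the DSS (or of a composite of
  DSSs) under analysis;
* each **study's endpoint set**;
* the **observation universe** — everything observed for the disease: the
  union of all studies' endpoints, the reference set, and any scales
  explicitly folded in.

For one study, the universe splits into overlap ($a$), redundant ($b$),
missing ($c$) and irrelevant ($d$) cells, with $a + c$ the reference size and
$b + d$ its complement within the universe. Sensitivity $Se = a/(a+c)$ and
specificity $Sp = d/(b+d)$ are the two directions of match, and their sum $N$
(the Neutrality score) ranges over $[0, 2]$: $N = 2$ means the study measured
every phenotype indicator and nothing else; the acceptability rule is the
strict inequality $N > 1.50$, so a score of exactly 1.50 is *not* acceptable.

Treating the study's endpoint choice as a diagnostic test for "severe
disease", $Se$ and $Sp$ propagate into predictive values at a prevalence $p$:

$$PPV = \frac{Se\,p}{Se\,p + (1-Sp)(1-p)},\qquad
  NPV = \frac{Sp(1-p)}{Sp(1-p) + (1-Se)p},$$

with false-positive rate $1-PPV$ and false-negative rate $1-NPV$. Sensitivity
and specificity are treated as statistically independent and fixed — no
uncertainty is placed on the classification cells themselves. Two consequences
are worth internalizing: for $0 < Se, Sp < 1$ the false-negative rate rises
strictly and the false-positive rate falls strictly as prevalence grows; and a
study with $Se = 0$ (no overlap with the scale) has $PPV = 0$, i.e. *every*
positive classification it makes is false, at every prevalence.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| acceptability threshold | 1.50 | strict cut-off on $N$ |
| prevalence grid | 0.20, 0.50, 0.80 | prevalence of severe disease in the assessed population |
| cohort size | 30 subjects | used when a study reports no sample size |
| replicates | 1000 | Monte Carlo cohorts per (study, prevalence) |

Prevalence must lie strictly inside $(0,1)$: at 0 or 1 one of the predictive
values degenerates to 0/0. When a denominator is zero at an interior
prevalence (e.g. $Se = 0$ with $Sp = 1$: nobody classifies positive), the
estimate is reported as `NA` rather than given a convention.

## The Monte Carlo estimand

Each replicate draws a cohort: subjects are severe with probability $p$,
severe subjects classify positive with probability $Se$, non-severe with
probability $1-Sp$. The per-replicate summaries are the *conditional*
proportions $FP/(FP+TP)$ among positives and $FN/(FN+TN)$ among negatives —
the empirical $1-PPV$ and $1-NPV$ — because the analytic quantities being
mirrored are the predictive values. Replicates with no positives (or no
negatives) are dropped from the respective list and counted in the result;
imputing 0 or 1 for them would bias the medians at extreme prevalences, and
the dropped counts keep the accounting auditable. Summaries are the median
with 5th/95th percentiles using the linear-interpolation percentile
(`quantile(type = 7)`), stated so that results reproduce bit for bit at a
fixed seed. One master seed drives everything; per-(study, prevalence)
substreams are derived by hashing the keys with the master seed, so adding a
study or a prevalence level never perturbs the other draws.

## Label matching

Matching is exact on a normalized key: trim, case-fold, replace punctuation
with spaces, collapse whitespace, then apply an optional user-supplied synonym
map (variant → canonical, chains resolved at construction, cycles rejected).
Normalization is idempotent, so re-ingesting normalized output is a no-op.
There is deliberately no fuzzy matching: a silent fuzzy merge would corrupt
the integer cells irreversibly, and a wrong count is worse than a visible
mismatch the synonym map can fix. Endpoints within one study are a set, not a
multiset — mentioning an indicator twice does not count it twice.

## Composites and the scoring universe

For a disease with several DSSs, scales are ordered by publication year (ties
by name) and the composite is the deduplicated union of all scales *after* the
first, recording `duplicates_excluded = sum of member sizes − union size`.
When a study is scored against the first scale, the composite's indicators are
folded into the observation universe (they are observed information, and
ignoring them would inflate specificity); the fold is applied in that
direction only, which is how the comparison is defined. A symmetric fold of
the first scale into the composite-side universe exists behind
`fold_in`/`include_first_in_composite` flags but is off by default. The
universe is the full dataset as loaded — "another study of the same disease"
means any study in the collection, with no time windowing.

Degenerate tables refuse to score rather than invent a value: an empty
reference ($a+c=0$) and an empty universe complement ($b+d=0$) are both
errors, because a specificity computed from no outside information would be
fabricated.

## The synthetic generator

`synthetic_spec()`/`generate_dataset()` emulate a per-disease collection of
scales and studies with controlled structure: scale sizes, the number of
indicators each later scale shares with the union of the earlier ones (so a
composite over the generated scales excludes exactly the requested
duplicates), and per-study target sensitivity/specificity. Targets are
realized on the integer lattice — $a = \mathrm{round}(Se \cdot R)$ overlap
indicators out of a reference of size $R$, $b = \mathrm{round}((1-Sp)E)$
redundant picks from an out-of-scale pool of size $E$ — so rescoring a
generated study recovers the realized targets with zero error, which is what
makes the generator usable as a round-trip oracle. Off-lattice targets snap to
the nearest feasible value (recorded in the manifest); `strict = TRUE` errors
instead.

Because the universe is built from studies, the generator emits one auxiliary
"endpoint registry" study carrying the whole out-of-scale pool. This mirrors
a property of real curated collections — every irrelevant indicator was, by
definition, an endpoint of some study of the disease — and guarantees each
target study sees $b + d = E$ exactly. The registry row is flagged
`is_registry` in the manifest and should be excluded from cohort summaries of
the target studies. Indicator labels are opaque disease-prefixed tokens,
keeping label normalization out of the generator's correctness path.

What the generator does *not* emulate: realistic endpoint vocabulary and
synonymy, correlation between indicators, publication-year dynamics of
studies, or uncertainty in the extraction of endpoints from papers. Tests
passing on synthetic data therefore validate the arithmetic and the
contracts, not the fidelity of any curation pipeline.

## Reference tables and their verbatim defects

`reference_tables()` ships transcriptions of the per-disease summary tables of
a published systematic review of rare-disease severity scales (scale sizes,
composite bookkeeping, per-disease mean/most/least Neutrality, first-vs-
composite means and the implied deltas). The transcription is verbatim,
including rows that are internally inconsistent in print: one disease's
composite bookkeeping is smaller than its first scale (twice), and one
disease's printed mean components do not add to its printed mean Neutrality.
Such rows carry a non-empty `flag` column and are excluded from identity
checks rather than silently corrected — the package records what was printed,
and asserts only what is arithmetically coherent.

## Numerical and design choices

* All scores are carried at full double precision; rounding (2 decimals for
  the per-disease summary style, 3 for the first-vs-composite style) is
  presentation-only.
* Cohort means are unweighted across studies; weighting by sample size has no
  support in the summary-table format being mirrored.
* Extreme-study ties on $N$ break by higher specificity, then lexically
  smaller study id, so reports are deterministic.
* Identity checks against printed tables use half-print-unit slack per rounded
  component (0.0015 for three 3-decimal roundings, 0.015 at 2 decimals);
  first-vs-composite deltas are checked at 0.0005.
* Test problem sizes: property suites run on randomized cases of ≤ 40
  indicators and ≤ 6 studies; the simulation-vs-closed-form check uses
  200 replicates of 10,000-subject cohorts over a 12-point $(Se, Sp, p)$ grid;
  the generator round-trip covers 200 random feasible specifications. These
  sizes make every check exact or tight while keeping the suite fast.

## Limitations

The DSS is itself an imperfect surrogate for the phenotype, so absolute
Neutrality values are best read comparatively. Indicators are treated as
exchangeable and equally weighted; no clinical importance weighting is
applied. $Se$ and $Sp$ enter the misclassification model as fixed quantities —
no sampling uncertainty is attached to the classification cells. And exact
label matching is only as good as the curation and synonym map feeding it.
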