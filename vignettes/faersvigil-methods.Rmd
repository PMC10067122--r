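---
title: "Disproportionality screening of checkpoint-inhibitor arrhythmias: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of checkpoint-inhibitor arrhythmias: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersvigil)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect voluntary
reports of suspected drug reactions. They have no exposure denominator, so
incidence is not estimable; what is estimable is *disproportionality* — does a
drug-event pair appear more often than the overall reporting pattern would
predict? `faersvigil` implements that screen for arrhythmic events under
immune checkpoint inhibitors (ICIs): parsing and deduplicating the quarterly
multi-table FAERS extracts, selecting cases where an ICI is the primary
suspect and an arrhythmia preferred term (PT) is reported, classifying the
exposure into regimens (agent, class, named combination), computing
ROR / PRR / IC signal statistics with a composite criterion, and summarising
the cohort (demographics, time to onset, case fatality).

## Case selection and ingestion

FAERS ships each case possibly several times as revisions (`caseid` shared
across `primaryid` versions). We retain, per case, the version with the
highest FDA receipt date, ties broken by the highest `primaryid` — the
standard deterministic FAERS practice. Drug names are free text; we
canonicalise them by case-insensitive *containment* of a dictionary variant
(brand or generic) in the verbatim name, because FAERS names carry dose and
formulation suffixes that defeat exact matching. A case enters the arrhythmia
cohort iff it has (a) an ICI with role code `PS` (primary suspect) and (b) at
least one of the 24 arrhythmia PTs, matched case-insensitively as exact
strings — no MedDRA hierarchy or SMQ expansion is used, the PT list is a flat
bundled resource that users can replace.

Regimens are classified from the set of distinct ICI substances carrying a
*suspect* role (`PS` or `SS`) in the case: one substance is monotherapy of
that agent (class anti-PD-1, anti-PD-L1 or anti-CTLA-4); two or more are a
combination, matched against the four named pairs, otherwise
"other combination". The selection rule requires the ICI to be `PS`, but a
combination partner is frequently coded `SS`, which is why classification
widens the role set; this is a deliberate choice where the underlying
reporting practice is ambiguous.

Ages are converted to years from the FAERS unit code (decades ×10, months
/12, weeks /52, days /365.25); unmappable units become missing and are
counted, as are out-of-range values (outside 0–120). Time to onset (TTO) is
the whole-day interval from the *earliest full* (`YYYYMMDD`) ICI therapy
start date to the event date. Partial dates (year or year-month) are
excluded rather than imputed — imputation would fabricate onset times in the
exact quantity the analysis studies — and negative intervals are treated as
incorrect records, excluded and counted.

## The signal statistics

All three statistics are computed from the 2×2 table of a drug selector
against an event selector over the full database: `a` (target drug, target
event), `b`, `c`, `d`. Two counting units are available. The *record* unit
counts drug-event pairs — one case with two qualifying PTs contributes 2 to
`a` — and is the default for disproportionality, matching the convention in
which a screen's N exceeds the unique-case count. Cohort analyses are always
case-level.

* **ROR** $= ad/bc$, with the Wald interval
  $\exp(\ln \mathrm{ROR} \pm z\sqrt{1/a+1/b+1/c+1/d})$. When any cell is 0,
  0.5 is added to all four cells (Haldane–Anscombe) and the output is
  flagged; this keeps estimates finite and is transparent.
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$, screened jointly with the Pearson
  chi-square, Yates-corrected by default (the convention in PRR-based
  pharmacovigilance screening; the uncorrected statistic is available).
* **IC** $= \log_2 \frac{a + 0.5}{E + 0.5}$ with $E = (a+b)(a+c)/N$, the
  shrinkage-regularised observed/expected measure from the Bayesian
  confidence propagation framework. Credible bounds (IC025, IC975) are the
  quantiles of the $\mathrm{Gamma}(a+0.5,\, E+0.5)$ posterior of the Poisson
  intensity, evaluated exactly with `qgamma`. A closed-form polynomial
  approximation is also provided (`method = "approx"`), but it is accurate
  only at large counts: at $a = 10$ it misses the exact quantile by more
  than 0.3 log2-units, so the exact quantiles are the default and the
  Monte-Carlo posterior serves as the independent test oracle.

The composite criterion flags a pair as a potential signal when at least one
of: lower 95% ROR bound > 1, PRR > 1 with $\chi^2 > 4$, or IC025 > 0 — and
the pair has at least 3 reports. The prose definitions of such criteria bind
the minimum-case rule to the ROR and PRR clauses; we apply it to the IC
clause as well for consistency (configurable off), which is the conservative
reading.

Comparative RORs (class vs class, combination vs monotherapy) restrict the
database to the union of two disjoint groups and cross group membership
against event occurrence, case-level. The signal spectrum evaluates every
(regimen, PT) pair with at least one co-report; cells below the minimum case
count keep their statistics but carry no flags.

## The synthetic generator

Because the full FAERS corpus cannot be bundled, validation runs on a
synthetic generator that emits the same `$`-delimited multi-table dialect
the parser accepts, with known ground truth. Each case draws one primary
drug (or fixed combination) from configured marginal probabilities; each PT
is then included independently with probability
$\min(1, \text{background} \times \text{multiplier}(\text{drug}, \text{PT}))$.
This matches the independence structure the disproportionality model assumes
— there is deliberately no PT–PT dependence beyond the shared drug, and no
reporter-level biases (stimulated reporting, secular trends), so passing
tests demonstrate correctness of the machinery and its operating
characteristics under the model, not robustness to those real-data
pathologies. TTO is log-normal with a smaller log-mean for fatal cases
(medians 30 vs 33 days, $\sigma = 1.5$ — right-skewed with roughly the
observed IQR spread), realised as event date = start date + draw. Death
probabilities are per-drug with a 12% default; demographics use a truncated
normal age (mean 68, sd 11) and continent probabilities matching the
reported reporting-region mix. A configurable fraction of cases is emitted
with a superseded earlier version (to exercise deduplication) and of therapy
dates as year-month only (to exercise the partial-date policy). The same
configuration and seed produce byte-identical files.

`table1_fixture()` is different: a deterministic 1945-case cohort whose
margins — 507 fatal / 1438 non-fatal, and within each arm the printed sex,
age-band, year, continent, indication, outcome, TTO-band and regimen counts
— reproduce a published characteristics table exactly. Only margins are
published, so characteristics are assigned independently in deterministic
blocks within each arm; any statistic of a single characteristic crossed
with fatality is exact, joint distributions across characteristics are not
meaningful. One internal inconsistency in the published table (non-fatal
lung-cancer count exceeding total minus fatal by 3) is resolved in favour of
the totals and fatal counts.

## Cohort analyses

Percentages are `round(100 n / N, 2)`. Quantiles use linear interpolation
between order statistics (R type 7), which is what produces fractional IQR
bounds such as 73.75. Outcome is reported as one exclusive level per case by
severity precedence (death > life-threatening > disability > hospitalisation
> intervention > congenital anomaly > other > non-serious), so outcome counts
sum to the cohort size. Fatal vs non-fatal contrasts use chi-square tests
for categorical characteristics (unknown levels excluded from the test,
shown in summaries) and two-sided Wilcoxon rank-sum tests for age and TTO,
treated as non-normal; the omnibus TTO test across regimens is
Kruskal–Wallis over regimens with at least 5 known TTO values. Case-fatality
tables divide deaths by reports within a stratum; with event-group strata a
case contributes to *every* group in which it has a qualifying PT, so group
totals may exceed the cohort size — the published group-level death counts
are not derivable from single-PT tallies, and this attribution rule is the
package's own reconstruction.

## Operating characteristics and problem sizes

The test suite validates the screen's operating characteristics at sizes
chosen to give stable Monte-Carlo estimates in seconds-to-minutes:

* *Oracle agreement*: 1000 random tables with cells up to $10^5$; ROR/PRR/
  chi-square agree with independent implementations (log-space arithmetic, a
  weighted binomial GLM, `chisq.test`) to 10 significant digits (the
  iterative GLM to its own convergence tolerance); IC025 within 0.15
  log2-units of a 20,000-draw Monte-Carlo posterior whenever $a \ge 5$.
* *Null calibration*: 200 synthetic databases of 3000 reports, four target
  drugs × six PTs with all multipliers 1 and expected co-report count 6 per
  cell; the per-cell ROR false-flag rate stays below 7.5% (nominal one-sided
  2.5% plus discreteness; observed ≈ 3%).
* *Planted recovery*: 200 databases of 8000 reports with multiplier 3 on one
  pair and expected co-report count 24; the composite criterion fires in
  ≥ 95% of replicates. These conditions sit inside the "multiplier ≥ 2,
  expected count ≥ 20" regime: a Wald power calculation at exactly
  multiplier 2 and count 20 gives only ≈ 80% per-statistic power, so that
  boundary is not a regime where near-certain detection is attainable.
* *Comparative recovery*: 200 replicates of two 4000-case groups with 2:1
  planted reporting odds; the Wald interval covers the true odds ratio in
  ≈ 95% of replicates and the median estimate is ≈ 2.

## Numerical and degenerate-input choices

Cell counts are coerced to doubles before products (integer overflow begins
at cells ≈ $5 \times 10^4$). PRR is 0 when $a = 0$ and a flagged `Inf` when
$c = 0$ with $a > 0$; an empty background ($c + d = 0$) is an error
instructing the caller to supply full-database denominators. Empty cohorts
summarise without division by zero. Malformed lines in quarterly files are
counted and skipped; satellite rows whose `primaryid` is absent from DEMO
are dropped as orphans and counted. All randomness in the generator flows
from the single configured seed; simulation studies derive per-replicate
seeds as documented offsets from a base seed.

## Limitations

The screen is descriptive: a flagged pair is a reporting association, not
causality, and the absence of exposure denominators means no incidence or
mortality rate can be derived. Duplicate detection is by case version only;
probabilistic linkage of distinct `caseid`s re-reporting the same patient is
out of scope, as are MedDRA hierarchy traversal and EBGM-style
empirical-Bayes shrinkage scores.
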