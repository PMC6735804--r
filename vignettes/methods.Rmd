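---
title: "Estimating the human and economic costs of not breastfeeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the human and economic costs of not breastfeeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfcost)
```

## The model

`bfcost` estimates, for a one-year cohort of newborns and their mothers in
each country, what not breastfeeding according to the WHO/UNICEF
recommendations (exclusive breastfeeding below 6 months, continued
breastfeeding to age two) costs in avoidable disease, treatment spending and
foregone future earnings. The counterfactual throughout is universal
recommended breastfeeding at current disease rates; nothing is projected for
countries without data (see *Aggregation* below).

The estimator is a deterministic attribution cascade in three stages.

### 1. Attributable burden

For each disease pathway the share of observed burden attributable to
sub-optimal breastfeeding is a multi-category Levin population attributable
fraction,

$$\mathrm{PAF} \;=\; \frac{\sum_c p_c\,RR_c - 1}{\sum_c p_c\,RR_c},$$

where $p_c$ is the prevalence of exposure category $c$ and $RR_c$ its
relative risk, with the recommended practice as the reference ($RR=1$).
Attributable cases and deaths are observed incidence and deaths multiplied
by the PAF.

* **Diarrhoea and pneumonia (0–23 months).** Exposure is categorised
  separately for the 0–5 month band (exclusive / predominant / partial /
  none) and the 6–23 month band (any / none). The two band PAFs are pooled
  with weights equal to each band's share of the pathway's cases (for cases)
  and deaths (for deaths); the shares are inputs with a neutral default of
  one half and can be overridden per call.
* **Childhood obesity.** A two-category PAF (never vs ever breastfed) applied
  to incident cases; mortality is not estimated for this pathway.
* **Breast cancer, ovarian cancer, type II diabetes in women.** A
  two-category PAF whose exposed share is $1 - $ the population's attainment
  of recommended lifetime breastfeeding, applied to incidence; the mortality
  effect is assumed equal in magnitude, so the same fraction is applied to
  deaths. The upstream prose describing this computation is arithmetically
  ambiguous ("multiplied by ... and then multiplied by"); we fix the Levin
  PAF because it is the standard, bounded choice, and keep the raw product
  $I \times (RR-1) \times \text{shortfall}$ available as a `literal` audit
  mode of `maternal_pathway_burden()`. The two coincide to first order when
  $RR$ is near 1 and diverge (the literal product is unbounded) otherwise.

### 2. Health-system and household costs

Attributable diarrhoea and pneumonia cases flow through a care-seeking
cascade: fraction taken to a facility, split into inpatient vs outpatient
care, distributed over four facility levels (health centre, primary,
secondary, tertiary hospital), and costed at level-specific unit costs per
outpatient visit and inpatient bed day. The cascade conserves cases, and
cost is linear in both cases and unit costs. WHO-CHOICE-style unit costs are
published for an earlier base year and are inflated by a country-specific
cumulative CPI multiplier; this is the only place CPI enters. Visits per
outpatient episode default to 1 and bed days per inpatient episode to 3 —
the sources leave both unstated — and every shipped and generated dataset
states its own values explicitly.

Attributable diabetes cases are multiplied by the share of cases diagnosed
and the annual health expenditure per diagnosed case.

Formula affordability is reported descriptively (it is a household transfer,
not added to the loss total): containers of formula needed from birth to age
two times the price of a 900-g container, divided by 24 months of mean
earnings. The denominator period is our choice — the source says only
"divided by the nominal wage" — and using the same 24-month window as the
numerator makes the ratio a true budget share. Countries without an own
formula price receive the global mean price as proxy.

### 3. Future economic losses (human capital approach)

All three loss components price foregone earnings with the same primitive, a
discounted earnings stream: the country's GNI per capita, growing at the
long-term GDP growth rate $g$, discounted at rate $r$, summed over the
age-years $[\mathrm{start}, \mathrm{end})$ of productive life. The year
lived at age $a$ contributes $(1+g)^a/(1+r)^a$; discounting is to the
cohort's birth/reference year with annual end-of-year compounding (the
sources state the rates but no timing convention; this is ours, stated
once and used everywhere). Fractional first and last years are pro-rated.
With $g = r$ the stream collapses exactly to
$\text{base} \times \text{scale} \times (\text{end}-\text{start})$, a
closed form the tests exploit.

* **Child mortality:** deaths × stream over ages 18 to min(65, life
  expectancy).
* **Maternal mortality:** per pathway, deaths × stream from the mean age at
  death for that pathway to the same end point; a mean age at or past the
  end point contributes nothing.
* **Cognitive deficit:** children not breastfed per recommendation × stream
  over working ages × 2.62 IQ points × 1.067% earnings per IQ point. The
  default exposed population is children not exclusively breastfed below 6
  months; the alternative mode uses children not breastfed at 6 months.

The country total is health-system cost + child mortality loss + maternal
mortality loss + cognitive loss, also expressed as a share of GNI.

### Key parameters

| parameter | default | units | notes |
|---|---|---|---|
| `discount_rate` | 0.03 | /yr | conservative 0.05, optimistic 0.015 |
| `gdp_growth` | 0.03 | /yr | conservative 0.015, optimistic 0.05 |
| `work_start_age` | 18 | yr | productive years begin |
| `retirement_age` | 65 | yr | or life expectancy if earlier |
| `iq_gain` | 2.62 | IQ points | maternal-IQ-adjusted effect estimate |
| `earnings_per_iq` | 0.01067 | fraction/point | earnings elasticity per IQ point |
| `apply_wage_share`, `apply_lfpr` | off | — | see below |

The wage-share and labour-force-participation multipliers are provided as
toggles but are **off** by default: the indicators are part of the input
record, but the plain GNI-per-capita formulation is what the loss formulas
state, so the defaults reproduce it; whether (and where) the original
workbook applied the multipliers cannot be determined from its description.
Monetary values are nominal US$ in a single configurable base year (default
2017, the end point of the CPI series).

## Aggregation and sensitivity

Group totals (seven World Bank regions, four income groups, global) are
cumulative sums over countries with available data, never extrapolated to
the group's population: a country missing an input contributes nothing — not
zero — to the affected field, per-field inclusion counts are part of every
aggregate, and the %-of-GNI divides the group's summed loss by the summed
GNI of the same included set. Sensitivity scenarios re-run only the
discount/growth-dependent components; burden and health costs are
scenario-invariant by construction, so conservative ≤ default ≤ optimistic
ordering of losses is a structural property the tests assert.

## The synthetic generator

`simulate_countries()` draws complete country profiles from fixed plausible
ranges shaped like the open-access sources a real run would ingest: UN-WPP
demography, UNICEF/DHS/MICS breastfeeding prevalence (exclusive
breastfeeding 10–60%), GBD-like incidence and cause-specific mortality,
MICS-like care seeking, WDI macro indicators (GNI per capita $500–$60 000,
life expectancy 50–85 y loosely increasing with income), ILOSTAT labour
indicators and WHO-CHOICE-like facility unit costs scaled to income.
Relative-risk draws are placeholders inside published-literature bounds
(e.g. diarrhoea 0–5 m "none" 2.0–3.0, obesity 1.2–1.4); the upstream
analysis cites but does not print its RRs, so no specific value is encoded
as "the" estimate. Identical seeds give identical datasets and every
generated profile validates cleanly.

What the generator does **not** emulate: cross-indicator correlation beyond
the income gradients noted above, within-country subnational heterogeneity,
measurement error and survey sampling noise, and the long right tail of
country population sizes. Passing tests on synthetic data therefore
demonstrate internal consistency, invariants and determinism of the
machinery — not agreement with any real country's published estimate.

## Verification against the published tables

The headline global figures cannot be recomputed from raw data here (they
require ~130 countries of external inputs), so the published regional and
income-group table rows are shipped as checksummed fixtures and the
package's aggregation is required to reproduce the printed totals from them:
595 379 child deaths, 98 943 maternal deaths, 974 956 obesity cases, US$1 146.81 m
health-system cost, US$53.72 b / US$1.26 b / US$341.33 b losses, and the
US$91.04 b conservative bound. Where the published rows round
inconsistently with their own printed total (the cognitive-loss column sums
to 285.40 via regions and 285.38 via income groups against a printed
285.39; a handful of count columns differ by 1–2 in one grouping), the
tests assert the consistent grouping exactly and the inconsistent column to
within one 2-dp rounding ulp (±0.02), documented rather than hidden.

## Numerical choices and degenerate inputs

* PAF inputs are validated hard: category mismatch and prevalence not
  summing to 1 (tolerance 1e-6) are errors, not warnings.
* Category vectors must sum to 1 within 1e-9 at validation.
* A zero or missing wage makes the formula share undefined (NA), never
  infinite; an empty earnings stream (start ≥ end) is 0 with a warning;
  life expectancy below working age gives a zero loss with a warning.
* Missing indicators are NA plus an availability flag and propagate as
  "component not computed"; totals sum the available components and record
  which were absent.
* Display rounding (counts to integers, US$ to 2-dp millions/billions, %GNI
  to 2 dp) happens only in `print`/`summary`; all stored arithmetic is full
  precision.

## Problem sizes

The test suite and the acceptance script use 130 synthetic countries (the
scale of the published analysis) for the end-to-end, monotonicity and
determinism checks, and 1 000 random draws for each oracle-equivalence check
(PAF vs brute-force expected-risk ratio to 1e-12 absolute; present value vs
a per-year loop oracle to 1e-9 relative). The whole suite runs in well under
a minute on one CPU.

## Limitations

Uncertainty in the relative risks and epidemiology is not propagated — the
scenario grid varies only the economic rates. Excluded by design (following
the upstream scope): caregiver time and transport costs, household
out-of-pocket fees, childhood diabetes/cancer, SIDS, necrotising
enterocolitis, preterm birth, and post-partum haemorrhage/depression; the
estimates are conservative in that sense. Country results are only as good
as their inputs; the no-extrapolation aggregation makes the inclusion sets
part of the result, and the run log records every exclusion with its
reason.
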