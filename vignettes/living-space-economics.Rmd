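---
title: "Simulating the economics of living space for housed dairy cows"
author: "cowspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the economics of living space for housed dairy cows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowspace)
```

## The question

Housed dairy cows given more living space (open floor area beyond stalls and
passageways) produce more milk but take longer to conceive. More milk raises
income; delayed conception stretches calving intervals, changes how a
lactation is spent, and shortens the number of calvings a cow achieves per
year of life. Whether paying for the extra space is worthwhile is therefore
an empirical, quantitative question: the two effects pull in opposite
directions and interact with when the cow leaves the herd.

`cowspace` answers it with a paired Monte-Carlo lifetime simulation. A
simulated cow enters at first calving and lives twice — once under a control
scenario (3 m² living space, 9 m² total space per cow) and once under a
high-space scenario (6.5 m² living / 14 m² total) — with the same milk-curve
coefficients, gestation length, dry-period length, exit times and prices.
Only two things differ by scenario: an additive daily milk-yield effect and
the time-to-conception distributions. The partial-budget difference between
the two lives is the financial return of space. A second stage amortizes the
capital cost of actually providing the space (new shed, indoor or outdoor
loafing-area extension) and subtracts it from the simulated returns.

## Model components

### Milk yield

Daily yield is a Wilmink lactation curve per parity class,

$$y(t) = a + b\,e^{-kt} + c\,t,$$

with $t$ the days in milk, plus an additive scenario effect (high space
only) and an additive effect for each of five gestation stages (56-day bins
of days pregnant; configurable). Negative predicted yields are floored at
zero. Per-cow heterogeneity enters by drawing each coefficient from
$\mathcal N(\text{mean}, \text{sd})$; the root mean square of the
standardized draws is carried as a covariate summarizing how unusual the
cow's curve is.

The trial that motivates the scenario contrast fitted a mixed-effects daily
yield model whose coefficients are not published, so the curve values
shipped here are illustrative calibration, not estimates. They were chosen
once, when the generator was designed, to give realistic Holstein output —
about 7,200 L (primiparous) and 9,600 L (multiparous) over a 305-day
lactation — and to place the simulated scenario comparison in the region the
study reports (median advantage of roughly £85/cow/year for exits within
lactations 2–4, essentially all comparisons favouring high space, and an
advantage that declines with exit parity). The defaults are:

| parameter | primiparous | multiparous | units |
|---|---|---|---|
| `a` (scale) | 31 | 41 | L/day |
| `b` (ramp) | −12 | −16 | L/day |
| `k` (ramp rate) | 0.045 | 0.055 | 1/day |
| `c` (persistency slope) | −0.022 | −0.040 | L/day² |

with a scenario effect of +1.1 L/day, gestation-stage effects
(−0.8, −3.0, −5.5, −8.0, −11.0) L/day, and coefficient standard deviations
(2.5, 2.0, 0.005, 0.005). The strong late-stage gestation penalties encode
the steep pregnancy-driven decline in the weeks approaching dry-off, beyond
the baseline persistency slope. Everything is configurable through
`milk_config()` or a YAML/JSON file (see
`system.file("extdata", "default_config.yaml", package = "cowspace")`).

### Reproduction and exit

Time to conception (days from calving) is drawn per scenario × parity-class
cell from the study's normals — control/primiparous (82, 10),
high/primiparous (155, 25), control/multiparous (108, 15),
high/multiparous (133, 25) — truncated below at 21 days by redraw (the
earliest biologically plausible conception; the handling of impossible
draws is a package decision, the truncation point is configurable). The
multiparous draw is reused for every parity ≥ 2. Gestation is U(275, 285)
days and the dry period U(42, 60) days, one draw of each per cow shared by
both scenarios and all parities. Exit is pre-specified by design: every cow
is pushed through all ten exit parities crossed with five candidate
final-lactation exit times drawn once per cow from U(1, 305) days in milk
(rounded to whole days), giving 50 paired comparisons per cow. Draws are
kept continuous; rounding to the integer day grid happens once when the
timeline is laid out.

### Timelines and replacement

For each parity before exit the cow conceives at her conception draw,
calves again conception + gestation days later, and dries off one
dry-period length before that calving; in the final parity she leaves at
the pre-set days in milk. Because high-space cows conceive later, the two
scenarios' exit days differ for multi-parity lifetimes. For the per-cow-place
comparison the earlier-exiting scenario's place is immediately refilled by
a replacement heifer with the same parameter set (parity restarting at 1,
chaining further lactations if the gap is long, truncated at the shared
horizon), so both scenarios cover the same calendar span.

### Partial budget

Only items that can differ between scenarios are counted: milk valued at a
margin over purchased feed, U(£0.17, £0.23)/L around the published UK mean
of £0.2049/L, and a dry/transition-period disease-risk cost per calving —
U(£32.43, £129.72) for a first calving, U(£49.54, £198.16) for later ones,
i.e. half to double the point estimates of £64.86 and £99.08. One margin
and one cost pair are drawn per comparison and shared by both scenarios.
Cull income and all other costs are assumed identical between scenarios and
excluded.

### Two per-year normalizations

Each comparison records two related outcomes, because the annualization of
the lifetime difference is genuinely ambiguous and the choice matters:

* `return_total` and `return_per_year_place`: the Eq.-style per-cow-place
  difference over the shared horizon, replacement milk and calvings
  credited to the earlier-exiting scenario, divided by the shared span.
* `return_per_year` (the headline outcome): each scenario's focal-cow
  return divided by that scenario's own lifetime, then differenced — a
  comparison of production *rates*.

We adopted the own-span rate difference as the headline after examining
both. Under the shared-span normalization the replacement heifer's fresh,
early-lactation milk is credited against the longer-lived (usually
high-space) scenario; with the conception parameters above this makes exits
at parity 2 look *worse* than parity 3 and makes later exits look steadily
better — a V-shaped parity profile, with the fertility penalty concentrated
where the primiparous conception gap (155 vs 82 days) is large relative to
a short life. The rate difference instead declines monotonically with exit
parity and flattens toward an asymptote, which is the qualitative pattern
the study reports (early exits most favourable to high space, the advantage
shrinking with parity); it also keeps essentially every comparison positive.
Both quantities are computed, tested and exported, so either convention can
be analysed.

### Regression decomposition

`fit_return_model()` regresses the per-cow-per-year difference on the
simulation inputs: exit parity dummy-coded with reference level 3 (the
typical exit of a high-yielding herd), and the continuous inputs — the four
conception times, gestation and dry duration, final-lactation duration,
margin, the two transition costs, and the milk-curve deviation summary —
each centred and scaled by the sample (n−1) standard deviation so estimates
are per one-standard-deviation change. Lifetime days is deliberately
excluded (near-collinear with exit parity). Categorical parity is not
standardized. Confidence intervals and p-values are standard normal-theory,
two-sided, uncorrected. `forest_data()` and `plot()` produce the forest-plot
view with a reference line at zero.

### Infrastructure finance

Three ways of providing the extra 3.5 m²/cow are costed for a 100-cow herd:
a new build at £182/m² (14 vs 9 m²/cow total space, so the financed
principal is the £91,000 difference), an indoor loafing-area extension at
£248/m², and an outdoor concrete loafing area at £100.75/m². Loans are
amortized by equal annual principal installments with interest on the
outstanding balance,

$$\text{total repaid} = P\left(1 + r\,\frac{n+1}{2}\right),$$

which reproduces the published repayment totals exactly (e.g. £254,800 at
4% over 20 years → £361,816); the equal-payment annuity model is available
as an alternative (`loan_terms(model = "annuity")`) but yields different,
higher totals. `sensitivity_table()` crosses the options with rates
{0, 3.74, 4.00, 5.30, 8.00}% and terms {12, 20} years, subtracts the
annualized per-cow cost from the simulated return sample (exits within
lactations 2–4), and summarizes net return by 10th/50th/90th percentiles
(linear interpolation between order statistics) and the share of strictly
positive net returns. Values are carried at full precision and rounded
half-up to pennies only at output.

One documented discrepancy: for the outdoor option at 4% the table
arithmetic gives a median net return of sample-median − £25.04 (£62.57 for
a sample median of £87.61), while the study's prose quotes +£59.58 for that
cell; the tabulated arithmetic is internally consistent and is what this
package implements.

## Numerical and design choices

* Whole-day calendar; calving is day 0, first milking day is day in milk 1;
  a lactation span sums daily yields over days 1..end inclusive.
* One gestation and one dry-period draw per cow lifetime (the design treats
  them as cow-level covariates, not per-lactation noise).
* Transition costs apply at every calving, including the first and
  replacement first-calvings; one cost draw per parity class per comparison.
* Per-year conversions use 365.25 days/year.
* The 10,000-rejection cap in the truncation loop turns a pathological
  configuration (most of the conception mass below the floor) into an error
  rather than a hang; a degenerate (sd = 0) mean below the floor errors
  immediately.
* `space_sim()` assembles each cow's 50 comparisons from precomputed
  lactation components (full-lactation totals, cumulative final-lactation
  curves, replacement-chain arithmetic). The test suite replays the draw
  stream and asserts exact agreement with the explicit
  `build_timeline()`/`pair_and_replace()`/`lifetime_milk()` path, so the
  transparent object construction defines the semantics.
* A single seed drives one R random stream with a fixed per-cow draw order
  (coefficients, reproduction, then the 50 economic draws), which makes
  runs bit-reproducible; per-module sub-streams were considered and
  rejected as unnecessary machinery at this scale.

## Scale

The study-scale design is 40,000 cows × 50 comparisons = 2,000,000 paired
simulations. The package default is 2,000 cows (100,000 comparisons), which
reproduces all distributional summaries to well within Monte-Carlo noise of
the design proportions and runs in a few seconds; the full scale is reached
by setting `n_cows = 40000`. The test suite uses between 10 and 2,000 cows
depending on what the property under test requires.

## What the synthetic generator does and does not emulate

The generator reproduces the *structure* the analysis assumes: scenario
effects on yield and conception, cow-level heterogeneity, shared economic
draws, the exit design, and replacement. It does not reproduce the
unpublished trial-fitted milk model, herd-level management feedbacks,
seasonality, disease events beyond the aggregate transition cost, heifer
rearing costs, or milk-price dynamics. Consequently absolute simulated
magnitudes (e.g. the exit-2–4 median of ~£85/cow/year under the shipped
calibration) are calibration outcomes, not predictions, and the package's
tests treat them only as qualitative properties (sign, ordering, share
positive). The finance arithmetic, by contrast, is exact and is tested to
the penny against the published figures.

## A worked run

```{r example, eval = FALSE}
sim <- space_sim(n_cows = 2000, seed = 1)
summary(sim)
fit <- fit_return_model(sim)
fit
run_finance(sim)
```
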