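---
title: "Methods: how the composite index is built"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how the composite index is built}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(health2020)
```

This vignette is the package's account of its own method: the model behind
the composite index, the parameters that matter, what the synthetic data
generator does and does not emulate, and the design decisions taken where
the construction was genuinely open.

## The construction

The index summarises a country's standing on a health-policy monitoring
framework with 6 targets and 19 indicators, 16 of them quantitative, at the
reference years 2005, 2010 and 2015. Four stages:

**Reference-year resolution.** Raw observations arrive as
(country, indicator, year, value). For each reference year, the observation
at that year is used when present; otherwise the closest observation within
a window (default ±2 years) substitutes for it, flagged `substituted`. When
two candidates are equally close the *later* year wins — more recent data
is the better proxy, and "closest" alone does not decide. Resolution runs
*before* the country filter, so a substituted value counts as present for
inclusion purposes; this matters because the filter is meant to catch
countries with structurally absent data, not countries whose statistical
office reports a year late.

**Country filter.** A country is excluded when more than `max_missing`
(default 6) of the quantitative indicators have no resolved value at the
filter year (default 2015 — the roster is defined on the most recent
panel; the function takes the year as a parameter so per-year audits
remain possible). Missing exactly six still qualifies. Indicators whose
data do not exist at all at a reference year (2015-only indicators when
auditing 2005) are not counted against any country: otherwise every
country would lose several indicators at the early years and the filter
would stop measuring what it is meant to measure, country-specific data
poverty.

**Goalposts and rescaling.** Each indicator's goalposts are its extreme raw
values pooled over the three reference years and over *included* countries
only — excluded countries' sparse data is unreliable by the filter's own
argument, so it must not anchor the scale. The indicator index is the
affine map of the raw value onto 0–100 between the direction-oriented
goalposts, floored at 1:

$$I = \max\!\left(100 \cdot \frac{x - \text{worst}}{\text{best} - \text{worst}},\; 1\right)$$

Orienting `worst`/`best` by the indicator's declared direction makes one
formula serve both higher-is-better and lower-is-better indicators, and
makes direction a *registry* property rather than something inferred from
data. The map targets 0–100 with a floor, rather than 1–100 directly:
scores at or near zero are exactly the cases the floor exists for, and a
direct 1–100 map would make the floor vacuous. This is the single most
consequential reconstruction choice in the package; it is isolated in
`rescale()` so an alternative (e.g. `1 + 99·(x − min)/(max − min)`) can be
swapped in one place. Values outside the goalposts — possible only when
goalposts are frozen from an earlier run and new data arrive — are clipped
to the range first; with self-computed goalposts clipping is a no-op.

**Aggregation.** The target index is the geometric mean of the target's
available indicator indices; the overall index is the geometric mean of the
surviving target indices. The geometric mean encodes *partial
substitutability*: multiplying any one of $n$ components by $c$ multiplies
the mean by exactly $c^{1/n}$, so a strong indicator only partly
compensates a weak one (the arithmetic mean would compensate fully, the
harmonic mean not at all). Averaging *by target* asserts that targets are
equally important; a consequence accepted deliberately is that an indicator
aligned to two targets carries double weight in the overall index. The
floor at 1 upstream guarantees positivity; `geometric_mean()` refuses
non-positive input rather than silently repairing it, keeping the
responsibility boundary between normalisation and aggregation clean. It is
computed as `exp(mean(log(x)))` — the log-mean form is stable where a
direct product of dozens of values near 100 would not be.

**Missing-data policy.** Two policy knobs with default 1:
`min_indicators_per_target` (a target is excluded only when *no* indicator
is available — "limited data" is not quantified anywhere authoritative, so
the laxest reading is the default and the threshold is configurable) and
`min_targets_per_country` (a country becomes unscorable only at zero
surviving targets; countries scored on three of five targets are a known,
legitimate state that the output flags via `n_targets_used` rather than
hides).

**Quintiles and trends.** Scored countries are ranked on the 2015 overall
index (ties broken by country code so the ranking is total and
reproducible) and split into five contiguous rank groups of near-equal
size, larger groups first. Published quintile boundary values are
*empirical descriptions* of such groups, so here boundaries are an output
(`quintile_boundaries()`), never an input. Trend cells average, per
indicator and quintile, the per-country relative change
$s\,(x_{2015} - x_{\text{base}})/|x_{\text{base}}|$ with $s = +1$ for
higher-is-better and $-1$ for lower-is-better indicators, so positive
always means improvement. Changes are computed on **raw native-unit
values**, not on rescaled indices: index-space changes would depend on the
goalposts (a property of the panel, not of the country), while raw relative
change is goalpost-free and matches how absolute indicator values are
reported alongside such figures. Baseline is 2005, or 2010 for indicators
first observed in 2010; 2015-only indicators have no trend. Countries
missing either endpoint drop out of that cell only, and `n_countries` makes
the attrition visible; a zero baseline makes the relative change undefined,
so the cell contribution is dropped with a warning rather than invented.

## The registry is data

The indicator→target mapping is shipped as an editable JSON file rather
than code, because the authoritative mapping lives in figure/supplement
material that admits more than one reading. The default registry satisfies
every hard structural constraint — 19 indicators, 6 targets, 16
quantitative indicators, targets 1–5 quantitative, indicators 7/9/10
(and the qualitative 11) on two targets each, indicators 2 and 14 observed
only in 2015 — and resolves one genuine ambiguity explicitly: indicator 10
is read as *unemployment*, observed at all three reference years and
aligned to two targets (consistent with its multi-target role and with
trend reporting from a 2005 baseline), while *life satisfaction* is
modelled as indicator 12 with 2010-onward availability. Users who prefer
the other reading edit two JSON entries; no logic changes.

## What the synthetic generator emulates

`generate_panel()` draws, for country $i$ with position $p_i$ evenly spaced
on $[1, -1]$ (best to worst along a west–east-style axis):

- latent capacity $c_i = g\,p_i + \varepsilon_i$, $\varepsilon_i \sim N(0, \sigma)$;
- raw value $v_{ik t} = 50 + s_k \cdot 10 \cdot (c_i + d_k (t-2005)/10 + \eta)$,
  $\eta \sim N(0, \sigma)$ per cell, with $s_k = \pm 1$ matched to the
  indicator's direction, so high capacity is better on every indicator;
- cell-level missingness $\sim$ Bernoulli with probability
  `missing_rate_base + missing_rate_slope · (1 − rank01(c_i))`, so data
  gaps concentrate in low-capacity countries, as they do in countries with
  weak civil-registration systems.

Defaults are one fixed set of study-like conditions: 50 countries,
gradient strength 1, noise SD 0.1 (on the latent scale — small relative to
the gradient, as indicator noise is small relative to between-country
spread in real panels), base missingness 0.05 with slope 0.15 (visible but
not dominant attrition, concentrated at the low end), per-decade drifts
that improve the mortality-type indicators, worsen overweight, and leave
enrolment/unemployment flat so their quintile trends are noise-driven and
mixed in sign. Availability windows are honoured: 2015-only and
2010-onward indicators emit no earlier rows. Gaussian noise and
conditionally independent Bernoulli missingness are the simplest structure
exhibiting the gradient and capacity-linked missingness; real panels have
heavier tails, serially correlated errors, bounded/proportion-type
indicators and non-ignorable missingness, so passing tests show the
*pipeline* is correct, not that real data would behave this benignly.

`make_fixture_roster()` packages one deterministic 53-country panel
(internal fixed seed, so regeneration is byte-identical) in which exactly
three "microstates" miss ten indicators on the 2015 panel and fall to the
filter, leaving 50 — the roster shape of the intended application. A
deterministic guard restores any randomly-dropped cells that would push a
fourth country over the cut-off, making the 50-of-53 contract structural.
A few cells are shifted one year off the reference years to exercise the
substitution flags end to end.

## Numerical and degenerate-input choices

- All downstream arithmetic uses full double precision; rounding to one
  decimal happens only in the human-readable ranking table.
- Degenerate goalposts (all pooled values identical) are an error, never a
  stored state: no affine map exists, and inventing one would silently
  rank equals.
- Duplicate (country, indicator, year) rows resolve deterministically
  (distance, then later year, then value order) so row order never changes
  output; permutation invariance is tested.
- Equidistant substitution candidates: later year wins (documented above).
- Quintile ties at group boundaries: country-code order decides, making
  assignments a pure function of the data.
- Classed conditions (`h2020_config_error`, `h2020_parse_error`,
  `h2020_validation_error`) separate configuration, parse and validation
  failures; the command-line wrapper maps them to exit codes 2/3/4.

## Scale of the shipped checks

The test suite runs the full pipeline at the study's natural size (50–53
countries, 16 indicators, 3 years — well under a second per run),
property checks on 100 randomised cases per invariant, and the missingness
calibration over 200 generator seeds; these sizes were chosen as the
smallest at which each property is meaningfully exercised.

## Known limitations

- The index is *relative*: goalposts are pooled from the panel at hand, so
  adding or removing a country can move everyone's scores. Freezing
  goalposts (`write_goalposts()`/`read_goalposts()`) is the supported way
  to score new data on a fixed scale.
- Equal target weights and the doubled weight of multi-target indicators
  are assertions of the framework, not estimates; no uncertainty is
  propagated onto the index.
- The qualitative indicators and the qualitative sixth target are out of
  scope: they carry no scores here.
- Country codes are matched exactly; no name harmonisation is attempted.
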