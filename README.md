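# health2020

Composite-index construction for the WHO European Region's **Health 2020**
policy framework, for epidemiologists and health-policy analysts who need a
transparent, auditable country ranking from heterogeneous indicator panels.

The framework monitors 6 policy targets through 19 indicators, of which 16
are quantitative; progress is summarised by a single relative index per
country per reference year (2005, 2010, 2015). This package implements that
construction as a tested pipeline:

1. **Ingest.** Long-format observations (`country,indicator_id,year,value`)
   are resolved onto the three reference years; when a reference year is
   missing, the closest observation within ±2 years substitutes for it and
   is flagged (the asterisk of published index tables). A country missing
   more than six of the 16 quantitative indicators at 2015 is excluded from
   the roster.
2. **Rescale.** Each indicator *k* is rescaled between pooled *goalposts* —
   its extreme raw values over all included countries and all three years —
   onto a 1–100 scale, direction-adjusted so higher always means better:

   `I_k = max(100 · (x_k − worst_k) / (best_k − worst_k), 1)`

   The floor at 1 keeps the geometric mean defined; the `floored` flag
   records where it applied.
3. **Aggregate.** The index of target *t* is the geometric mean of its
   available indicator indices; the overall index is the geometric mean of
   the non-excluded target indices (targets are equally weighted, so an
   indicator aligned to two targets counts twice). The geometric mean is
   used for its *partial substitutability*: an x% change in any component
   moves the index equally, and a high score only partly offsets a low one.
   Missing indicators shrink a target; a target with no indicator drops
   out; a country is scorable while at least one target survives.
4. **Classify & trend.** Scored countries are ranked on the 2015 overall
   index and split into five equal-size quintiles (boundaries are an
   *output*, not thresholds); per indicator and quintile, the average
   direction-adjusted relative change from baseline (2005, or 2010 for
   late-starting indicators) to 2015 is tabulated.

The indicator/target registry ships as editable JSON
(`system.file("extdata", "registry.json", package = "health2020")`), and a
synthetic panel generator with a latent capacity gradient and structured
missingness provides ground-truth data for testing — the underlying WHO
databases are not required (or downloaded) by anything here.

## Worked example

The packaged deterministic fixture mirrors the shape of the WHO European
roster: 53 candidate countries of which three data-poor microstates fall to
the inclusion filter.

```r
library(health2020)
library(dplyr)

fx <- make_fixture_roster()
result <- compute_index_table(fx$observations)
result
#> <h2020_index> 50 included / 53 roster countries; 2063 indicator indices
#>   overall index 2015: median 51.3, range 7.3-98.7 (n = 50)

ov15 <- filter(result$overall_indices, reference_year == 2015, !unscorable)
qs <- assign_quintiles(select(ov15, country, index))
quintile_boundaries(qs)
#>       quintile min_index max_index  n
#> 1         high  76.78154  98.67141 10
#> 2 upper_middle  57.69294  73.37565 10
#> 3       middle  43.67563  57.28568 10
#> 4 lower_middle  27.23819  42.92533 10
#> 5          low   7.27544  26.34617 10

trend_table(resolve_reference_years(fx$observations),
            default_registry(), qs) |> head(3)
#>   indicator_id     quintile baseline_year avg_relative_change n_countries
#> 1            1         high          2005          0.11438791          10
#> 2            1 upper_middle          2005          0.10934895          10
#> 3            1       middle          2005          0.08444314           9
```

Reading this output: 50 of the 53 fixture countries are scored; the five
quintiles hold ten countries each and their empirical index boundaries are
reported per group; for indicator 1 (premature mortality, lower-is-better)
every quintile improved from 2005 to 2015 — e.g. +11.4% in the high
quintile — with one middle-quintile country dropped from its cell for
lacking an endpoint. `tidy(result)` returns the full long table of
indicator/target/overall indices with audit flags, `glance(result)` a
one-row summary, and `autoplot(result)` the ranked, quintile-coloured bar
chart.

A file-based front end (`run_simulate()`, `run_compute()`, `run_report()`,
or the `inst/scripts/h2020` wrapper) writes the resolved observations,
goalposts, index table, inclusion report, quintiles, trends and a ranked
Figure-2-style summary with substitution asterisks.

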