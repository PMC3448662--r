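# ironcma

Cost-minimization analysis of ambulatory intravenous iron strategies.

## The problem

Patients with chronic gastrointestinal iron losses (liver disease,
inflammatory bowel disease, angiodysplasia) need repeated intravenous iron in
day-care units. Two formulations dominate: **iron sucrose (IS)**, limited to
200 mg per infusion (1 h 15 min chair time), and **ferric carboxymaltose
(FCM)**, which delivers up to 1000 mg in a single 45-minute infusion but
costs far more per mg. Assuming equal efficacy and safety — the premise of a
*cost-minimization analysis* — which strategy is cheaper per patient and
year, and how robust is the answer to uncertainty in the unit costs?

`ironcma` is a reusable, tested implementation of that decision model for
health economists and day-care unit managers: a calibrated synthetic cohort
generator, the infusion-count and cost engines, deterministic one-way /
two-way sensitivity analyses with closed-form break-even prices, and a seeded
Monte Carlo probabilistic sensitivity analysis (PSA).

## The model

For patient *i* with annual requirement *d<sub>i</sub>* (mg), the infusion
count under regimen *r* with per-infusion dose *q<sub>r</sub>* is
*n<sub>i,r</sub>* = ⌈*d<sub>i</sub>* / *q<sub>r</sub>*⌉ (FCM doses are rounded
up to the next 1000 mg; IS delivers 200 mg multiples exactly). Each infusion
costs

> c<sub>r</sub> = p<sub>r</sub> + (w<sub>staff</sub> + w<sub>indirect</sub>) · t<sub>r</sub> + c<sub>dev</sub> [+ c<sub>nonhosp</sub> under the societal perspective]

with vial price *p<sub>r</sub>*, hourly staff and indirect rates, chair time
*t<sub>r</sub>*, device cost, and per-session non-hospital direct costs
(travel, missed work). The decision statistic is the **incremental cost**
ΔC = mean<sub>i</sub>(n<sub>i,IS</sub> c<sub>IS</sub>) −
mean<sub>i</sub>(n<sub>i,FCM</sub> c<sub>FCM</sub>); ΔC &gt; 0 favours FCM.
Break-even vial prices solve ΔC = 0 in closed form; the PSA samples the six
unit costs from their plausible ranges (uniform or truncated normal) and
reports the fraction of 10,000 iterations with ΔC &gt; 0. All costs are
2009 €, undiscounted.

## Worked example

```r
library(ironcma)

rep <- run_base_case(run_config())   # packaged 111-patient cohort, baseline costs
print(rep)
#> Base-case cost-minimization report (EUR, per patient per year)
#>   hospital  IS  301.1   FCM  273.6   incremental   27.4
#>   societal  IS  351.3   FCM  285.8   incremental   65.5
#>   delivered iron: IS 111 g, FCM 135 g
#>   [config 1b36907a | seed 1 | ironcma 1.0.0]

break_even_is_price(load_fixture())  # 9.96 — IS only wins below ~10 EUR/vial

print(run_psa(load_fixture(), config = psa_config(seed = 1)))
#> <psa_result> 10000 iterations, uniform sampling, societal perspective
#>   favours FCM in 95.4% of iterations; mean incremental EUR 98.8
```

Reading: FCM saves ~€27 per patient-year from the hospital's view and ~€65
once patients' travel and lost work time are counted, even though it delivers
more iron (135 g vs 111 g, an artefact of rounding doses up to 1000 mg). The
conclusion flips only if the IS vial price falls below about €10, and holds
in ~95% of Monte Carlo scenarios.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli","ironcma.R",package="ironcma"))') \
    base-case --out out/
# subcommands: generate-cohort | base-case | one-way | two-way | break-even | psa
```

## Package layout

- `R/` — cohort generator/fixture, dosing, cost model, sensitivity, PSA,
  config/reporting.
- `inst/extdata/synthetic_cohort.csv` — frozen synthetic cohort calibrated to
  the published population totals (the real chart-review data are not
  deposited).
- `inst/extdata/default_config.json` — baseline costs and sensitivity bounds.
- `vignettes/cost-minimization-methods.Rmd` — model assumptions, calibration
  strategy, numerical choices, limitations.
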