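---
title: "Methods: cost-minimization modelling of intravenous iron strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-minimization modelling of intravenous iron strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironcma)
```

## The decision problem and its assumptions

A gastrointestinal day-care unit treats patients with chronic iron losses by
repeated intravenous iron infusion. Two strategies are compared: iron sucrose
(IS; 200 mg per infusion, 1.25 h of chair time) and ferric carboxymaltose
(FCM; up to 1000 mg per infusion, 0.75 h). A cost-minimization framework is
appropriate only under the assumption that the strategies are equally
effective and equally safe for a given total iron dose, so the comparison
reduces to cost per patient per year. The package encodes that assumption; it
deliberately does not model efficacy, transfusion requirements, admissions or
mortality, and costs are undiscounted 2009 euros (the time frame is one
year).

The dosing rule is the model's one structural asymmetry: FCM doses are
rounded *up* to the next 1000 mg (a patient needing 800 mg receives one
1000 mg infusion; 1400 mg receives two), while IS delivers 200 mg multiples
exactly. FCM therefore delivers more total iron (135 g vs 111 g on the
packaged cohort), which biases drug costs *against* FCM and makes the
resulting preference for FCM conservative. `infusions_required()` applies the
same ceiling rule to both drugs; for the cohort's 200 mg-multiple doses it
reduces to exact division for IS, so no special case is needed.

## Cost parameters

| parameter | unit | baseline | bounds | meaning |
|---|---|---|---|---|
| `drug_price_is` | €/200 mg vial | 23 | 5–23 | regulated IS price |
| `drug_price_fcm` | €/1000 mg vial | 200 | 80–200 | regulated FCM price |
| `staff_rate` | €/h | 18 | 12–24 | nursing + auxiliary + medical surveillance |
| `indirect_rate` | €/h | 6 | 2–10 | structural/administrative share (full-cost accounting) |
| `device_cost` | €/infusion | 7 | 5–10 | infusion material |
| `nonhospital_cost` | €/session | 10 | 2–20 | patient travel and missed work (societal only) |

A per-infusion cost is `vial + (staff + indirect) × duration + devices`,
plus the non-hospital session cost under the societal perspective. The
published cost table also lists composite "cost of one infusion" rows (€47
IS, €35 FCM). These are treated as *redundant derived* quantities, not
additional components: reconstructing overhead from its parts gives €37
(hospital) per IS infusion and €25 per FCM infusion, and only this
decomposition reproduces the published per-patient totals within 1%. Adding
the composite rows on top would double-count staff time and overshoot by
more than 15%. The residual gap on the IS arm (reconstructed €301.1 vs
published €303.6, ≈0.8%) presumably reflects rounding inside the original
spreadsheet; it is documented rather than patched, and the acceptance
tolerance of 1% covers it.

## The synthetic cohort: what it emulates and what it does not

The original dose data come from a retrospective chart review that was never
deposited, so the package ships a *synthetic* stand-in
(`inst/extdata/synthetic_cohort.csv`, seed 42) and a generator
(`generate_cohort()`) that reproduces every published cohort-level fact
exactly:

* 111 patients in 4 indication strata (55/22/12/22);
* annual doses that are multiples of 200 mg in [200, 5200] mg, including the
  observed extremes (one patient pinned at each, placed in the highest- and
  lowest-mean strata respectively, matching the reported dose-by-indication
  pattern);
* stratum totals fixed at the 200 mg-rounded products of size × mean dose
  (means thus within 0.1% of the published 1178/800/833/864 mg, far inside
  the 5% tolerance);
* 557 IS infusions in total (equivalently 111,400 mg of iron);
* 135,000 mg of iron after FCM rounding.

Doses are first drawn per stratum from a discretised truncated log-normal
(`sdlog = 0.55`, chosen once to give the right-skewed shape reported for
this population; the published overall SD of 810 mg on mean 1033 mg implies
a log-sd near 0.7, but part of that spread is *between*-stratum), then
repaired: (1) 200 mg steps on random patients until each stratum total is
exact; (2) within-stratum 200 mg transfers — which preserve all stratum
totals — until the FCM-rounded total is exact. Step 2 is a stochastic
hill-climb: transfers that move the FCM total toward the target are always
accepted, and transfers that leave it unchanged are accepted half the time.
The neutral moves matter: an improving transfer needs a donor sitting
exactly 200 mg above a 1000 mg multiple, and such donors run out; the
shuffles replenish them, making the search ergodic. It converges in well
under a second; a hard iteration cap raises "calibration infeasible" rather
than looping forever.

Two published figures are deliberately **not** calibration constraints. The
overall mean dose of 1033 mg is arithmetically inconsistent with
557 × 200 / 111 = 1003.6 mg; the infusion count is what the cost model
consumes, so the generator calibrates to 557. The per-stratum "±SD" values
(e.g. 138 on a stratum spanning 200–5200 mg) are too small to be standard
deviations and of unclear definition; they are ignored.

What a green test therefore establishes: the cost results, which depend on
the cohort *only through* the two infusion totals (557 and 135) and the
patient count, are exactly those implied by the published population. What
it does not establish: patient-level realism beyond the constraints —
the joint distribution of doses within strata is a modelling choice, and
clinical covariates (transfusions, ASA class, mortality) are absent by
design. Indication labels carry no cost consequence; they are retained for
stratified reporting.

## Sensitivity analyses

The incremental cost is linear in every unit cost, with slope
`(N_IS × w_IS − N_FCM × w_FCM) / n` for a parameter entering with
per-infusion weight `w_r` (e.g. duration for the time rates, 1 for
devices). With 557 IS vs 135 FCM infusions every non-drug slope is positive,
which is why higher staff costs favour FCM. `one_way()` traces these lines
over the bounds; `two_way_drug_prices()` maps the favoured strategy over
both vial-price grids (defaults 0–25 € by 1 and 80–250 € by 5, covering the
bounds and both thresholds).

Break-even prices come from the closed form obtained by equating the two
cohort costs, `N_IS (p_IS + o_IS) = N_FCM (p_FCM + o_FCM)` with `o_r` the
per-infusion overhead; each is verified in the tests against a
`stats::uniroot()` bisection oracle to 1e-6 €. At baseline the societal IS
break-even is €9.96 — the conclusion flips only below ≈€10 per vial — and
the FCM break-even at the lower IS price bound is ≈€180 per 1000 mg.
Sensitivity and break-even functions default to the societal perspective:
only there do the published robustness claims (favourable at 50% staff
cost, IS threshold below €10) hold; the hospital-perspective threshold is
≈€17.5. The perspective remains an explicit argument.

## Probabilistic sensitivity analysis

`run_psa()` draws the six varied unit costs independently per iteration —
uniform over the bounds, or normal centred at the baseline with
`sd = (upper − lower) / 3.92` (the bounds read as a 95% interval),
rejection-sampled into the bounds. The source analysis names both families
but no normal parameters; centring at the baseline with the bounds as the
only dispersion information is this package's choice. Draws are consumed in
a fixed documented parameter order from one seeded generator, so a seed
pins the full result. Iterations with incremental cost exactly 0 are
counted as *not* favouring FCM (a conservative tie-break of measure zero
under continuous sampling). With 10,000 uniform iterations the model
favours FCM in ≈95–96% of scenarios (published: 97.2%); the truncated
normal gives ≈99%, consistent with the report that results were similar
under either distribution. The published Monte Carlo *mean* incremental of
€87 is not reproduced as a target: the reconstruction gives ≈€99 (uniform)
to ≈€78 (normal), and which run produced €87 is unstated.

## Numerical choices

* Monetary arithmetic in doubles; rounding to 0.1 € happens only in
  human-readable reports (`print` methods, `summary.json`); CSV outputs keep
  full precision.
* Histogram bins are half-open `[edge, edge + width)` on a grid of
  bin-width multiples, so 0 is always an edge and "iterations favouring IS"
  is exactly the mass of the negative bins.
* Degenerate bounds (lower = upper) short-circuit sampling and return the
  value exactly, making the PSA collapse bit-exactly onto the base case — a
  tested identity.
* The generator restores the caller's RNG state (`.Random.seed`) after use.
* Seeds are plain 32-bit integers throughout.

## Known limitations

* Equal-efficacy assumption: if FCM is clinically superior, cost
  minimization understates its advantage; if dose-fractionation matters, it
  may overstate it.
* Single-year horizon, no discounting, 2009 Spanish prices and salaries;
  conclusions transfer to other settings only via re-parameterisation
  (`cost_parameters()`, config JSON).
* Parameter draws are independent; correlated uncertainty (e.g. staff and
  indirect rates moving together) is out of scope, as are acceptability
  curves and value-of-information measures.
* The synthetic cohort reproduces totals, not the true patient-level dose
  distribution; analyses that depend on higher moments of the dose
  distribution (none in this package) should not rely on it.
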