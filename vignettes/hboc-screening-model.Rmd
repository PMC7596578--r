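---
title: "Modelling the cost-effectiveness of population genomic screening for HBOC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of population genomic screening for HBOC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbocScreen)
```

## The question the model answers

Roughly 0.5% of unselected women carry a pathogenic variant in one of eight
hereditary breast and ovarian cancer (HBOC) genes (*BRCA1*, *BRCA2*, *ATM*,
*CHEK2*, *MSH6*, *PALB2*, *RAD51C*, *TP53*). Current practice identifies
carriers mainly through family history, which misses most of them. A
population-wide genomic screening programme would find carriers before their
first cancer, letting them choose intensified surveillance (annual breast MRI
in addition to mammography) and risk-reducing surgery — mastectomy (RRM)
and/or salpingo-oophorectomy (RRSO). The question is economic: do the cancers
avoided and the life-years gained justify assaying an entire population of
women, almost none of whom carry a variant?

`hbocScreen` answers this with a decision tree feeding an annual-cycle Markov
cohort model, run separately for a screening strategy and a family
history-based testing strategy over the remaining lifetime of a cohort of
100,000 women of a single entry age, from a US health-sector perspective with
costs and health outcomes discounted at 3% per year.

## Model structure

**Decision tree.** `allocate_cohort()` splits the entering cohort by
participation (95%), carrier status and gene, assay result (sensitivity
0.991, specificity 0.999), and family history-based identification (17.4% of
carriers, available in both arms). To avoid double counting, family-history
testing in the screening arm applies only to non-participants and false
negatives. Identified carriers take up MRI surveillance with probability
0.75 and incur a one-year disutility of 0.05 for learning their carrier
status; every participant is charged the $200 assay and every positive (true
or false) a $200 confirmation. False-positive noncarriers return to the
noncarrier pathway after confirmation — the model assumes the confirmatory
test corrects the error. Decision-tree costs and the knowledge disutility
are booked at time zero, undiscounted; identified carriers identified
through family history are assumed to bypass the assay (no assay charge).

**Markov engine.** Sixteen health states: two cancer-free monitoring states
(mammography ± MRI), one-year tunnel states for incident early- and
late-stage breast and ovarian cancer and for the RRM and RRSO procedure
years, post-cancer and post-surgery states, and absorbing death. Each annual
cycle, competing events (cancer incidence, surgery uptake, death) are made
mutually exclusive by a first-event decomposition on the rate scale, so each
row of the transition matrix sums to one *by construction*; the engine
refuses to renormalise and raises an error instead. Accounting is
end-of-cycle with no half-cycle correction — the convention is isolated in
`accrue_trace()` and could be swapped without touching the transition
structure.

**Risk inputs.** *BRCA1/2* carriers draw annual breast/ovarian cancer
probabilities from gene-specific cumulative incidence curves via the
conditional transform `(F(a+1) − F(a)) / (1 − F(a))`. The other six genes
apply published odds ratios to the general-population annual probability on
the exact odds scale (not the rare-disease approximation — the *TP53*
ovarian OR of 18.5 would otherwise leave the unit interval); gene–cancer
pairs with no published OR (e.g. *CHEK2* for ovarian cancer) keep baseline
risk. Surgery alters subsequent risk through hazard ratios applied on the
rate scale, `1 − (1 − p)^HR`: RRM removes all breast cancer risk (HR 0),
RRSO reduces breast cancer risk (HR 0.63 for *BRCA1*, 0.36 otherwise) and
ovarian cancer risk (HR 0.31 for *BRCA1*, 0 otherwise).

**Surgery pathways.** Uptake of RRM and RRSO is restricted to *identified*
carriers and driven by cumulative uptake curves converted to conditional
annual probabilities; non-BRCA carriers take half the BRCA uptake rate
(rate ratio 0.5, applied on the rate scale). The two procedures are
independent competing uptakes. A woman who has had one procedure can still
take the other: because the single-cycle tunnel states cannot carry surgery
history, the second procedure is modelled as a direct transition from the
post-surgery state to the post-both state, with the procedure's cost and
one-year disutility attached to that transition flow. Women exit surgical
uptake after a cancer diagnosis.

**Mortality.** Background mortality comes from the life table. Cancer states
add an excess annual death probability derived from 5-year relative
mortality by age band, `1 − (1 − m₅)^(1/5)`, added to background mortality
and capped at one. Early-stage breast cancer receives the early-detection
mortality reduction: its excess mortality is `(1 − 0.943)` times the age-band
excess. The alternative reading of that parameter (a multiplier of 0.943) is
selectable via the `early_stage_reading` setting. Excess mortality persists
in post-cancer states by default (`excess_mortality_persists`), since the
source relative-survival data give no functional form for cure; both
readings are one switch apart.

**Stage at detection.** The probability that an incident breast cancer is
caught early is 0.8 under mammography + MRI, 0.5 under mammography only and
0.5 for unidentified carriers. These are *assumptions*, not published
inputs — no stage split by surveillance modality is printed in the source
material — and they are deliberately exposed in the configuration
(`stage_early_*`) as the model's most consequential unpublished inputs.
Ovarian cancer has no effective presymptomatic surveillance, so a single
early-stage probability (0.5) applies everywhere; early detection of
ovarian cancer carries no mortality advantage in the model, so screening
benefits ovarian outcomes only through RRSO.

**Cascade testing.** Carriers identified by screening (beyond those family
history would find anyway) trigger testing of first-degree female
relatives. The family is deterministic in expectation: one mother (27 years
older), one sister (same age), one daughter (27 years younger), each
discounted by life-table survival to her age. 70% of index carriers inform
relatives and 20% of informed relatives test; tested relatives carry the
variant with Mendelian probability 0.5 and are detected with assay
sensitivity. Each detected relative is run through the engine at her own age
as an identified carrier and her unidentified counterfactual is subtracted,
so the increment isolates the consequence of identification. Relatives
younger than the curve grid (daughters of young carriers) enter at age 20,
with survival to entry and discounting of the delay applied. There is no
second-order cascade, and informed-but-untested relatives incur no cost or
disutility.

**Scenarios.** The harm scenario prices the risk that screened noncarriers,
reassured by a negative result, skip recommended mammography: a one-time
disutility of 0.03 applied to 5% of screened noncarriers. The one-time
reading is the default because it reconciles with the published QALY drop
(≈142 per 100,000 30-year-olds); the lifetime-annual reading, which yields a
decrement roughly 25-fold larger, is available via `harm_one_time: false`.

## Parameter uncertainty

Every parameter carries its printed base value, low/high bound and
distribution family in `inst/extdata/table1_base.yaml`, stored on the
printed scale (the carrier prevalence is written 0.495 with `unit: percent`)
so the file stays diff-able against its source table.

Sampling for probabilistic sensitivity analysis (`draw_psa_sample()`)
parameterises each family from the printed interval:

* **Beta** — moment-matched with mean = base and SD = (high − low)/3.92.
  Where the printed interval is too wide for the mean (test specificity
  0.999 with a ±20% band has no feasible beta at that SD), the SD is clamped
  to 95% of its feasibility limit, preserving the mean at the cost of a
  slightly narrower spread.
* **Normal** — mean = base, same SD rule, truncated at zero for costs.
* **Log-normal** — median = base, sdlog = (log high − log low)/3.92.
  Proportions are truncated just below 1. For the two odds ratios with
  strongly asymmetric printed intervals (*RAD51C*, *TP53* ovarian), median =
  base and a CI-derived sdlog cannot both hold; the model keeps the median
  anchored at the base value.
* **Dirichlet** — the eight gene proportions jointly, with concentration
  100 × base proportions (configurable); no concentration is published.
* **Fixed** — hazard ratios printed as exactly 0 ("no residual risk"), the
  discount rate, and the harm-affected fraction never vary.

One-way analysis (`run_one_way()`) sets one parameter to a bound and
re-runs the model; perturbing one gene proportion rescales the others so the
block still sums to one. The PSA derives per-draw RNG substreams from the
master seed by counter, so the first *k* draws of any run equal a *k*-draw
run — results are independent of batching.

## Synthetic inputs, and what the tests do and do not show

The externally sourced inputs — per-gene cumulative incidence, cumulative
RRM/RRSO uptake, the background life table — are not tabulated in any
machine-readable source, so `default_inputs()` generates structural
stand-ins: logistic cumulative curves `make_cumulative_curve()` (zero at age
20, reaching their lifetime level at 80) and a Gompertz–Makeham life table
`make_life_table()` (c = 5e-4, b = 3e-5, g = 0.095, life expectancy at
age 20 ≈ 58 years). Defaults were chosen once for realism: lifetime breast
cancer risk 0.72/0.69 and ovarian 0.44/0.17 for *BRCA1*/*BRCA2* (the widely
cited prospective-cohort lifetime risks), 0.125/0.013 for the general
population; RRM uptake 0.45 with midpoint 40, RRSO uptake 0.75 with midpoint
45, encoding the qualitative pattern that drives the age gradient — *most
surgical uptake happens before 50, most HBOC cancer after 50*. The curve
shapes (a single logistic, flat after 80) are deliberately simple: no
incidence after 80, no cohort effects, no competing non-cancer morbidity.

Consequently the package's quantitative outputs on the default inputs are
*not* reproductions of any published estimate; tests assert published
arithmetic identities (which do not depend on curves), closed forms,
conservation properties, an engine-vs-microsimulation oracle, and the
directional results the qualitative curve structure guarantees — the ICER
rises with screening age, and removing cascade testing raises it further.
Users wishing to reproduce a specific study should supply digitized curves
through `read_inputs()`; everything downstream is unchanged.

## Numerical choices and degenerate inputs

* Transition rows must sum to 1 within 1e-9 or construction errors;
  mass conservation is checked every cycle.
* Cumulative curves are linearly interpolated to integer ages at load;
  annual probabilities are clipped to [0, 1] against rounding noise.
* A cumulative probability of 1 (`F(a) = 1`) is a degenerate population and
  errors rather than returning 0/0.
* Simultaneous surgery uptake in one cycle cannot occur (first-event
  decomposition makes events exclusive); the competing-rate split slightly
  reduces each marginal probability, vanishing as probabilities shrink.
* The horizon is age 100 or the end of the life table, whichever is first;
  the terminal life-table age must have qx = 1.
* PSA draws that error are excluded and counted, never silently dropped.

## Problem sizes

The packaged analyses run a 100,000-woman cohort (a scale factor only — the
cohort model is deterministic), 16 states over up to 80 annual cycles,
around 100 subgroup traces per full evaluation including the cascade module,
and 500-draw PSAs; the engine oracle uses a 100,000-path microsimulation of
the frozen three-state toy model. These sizes were chosen so the entire
suite re-runs in minutes while keeping Monte-Carlo checks at three standard
errors.

## Known limitations

* No second primary cancers: post-breast-cancer women face no ovarian risk
  and vice versa; cancer states track one diagnosis.
* Stage-split probabilities are assumptions (see above), and ovarian stage
  has no mortality gradient.
* The cascade family is an expectation, not a pedigree; no male relatives,
  no relatives of relatives.
* Cancer phase costs are identical below and above 65 in the packaged
  configuration (the split is retained in the data model).
* No currency-year adjustment, no budget-impact framing, no
  racial/ethnic subgroup structure.

## A worked run

```{r, eval = FALSE}
res <- screen_cea(age = 30)
summary(res)
psa <- run_psa(hboc_parameters(), n = 500, seed = 1,
               runner = cea_runner(30))
plot(psa)   # cost-effectiveness acceptability curve
```
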