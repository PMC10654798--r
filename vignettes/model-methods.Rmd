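---
title: "A Markov cohort model of colorectal cancer screening with liquid biopsy: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the model answers

Blood-based ("liquid biopsy", LB) tests for circulating tumour DNA detect
colorectal cancer (CRC) with useful sensitivity but, in their current form,
essentially no sensitivity for precancerous polyps. Because roughly 40% of
US adults refuse colonoscopy and stool testing, an easy blood test could
reach people no other modality reaches. `crcscreen` implements a
cohort-level Markov state-transition model that asks whether LB screening —
on its own, or offered to the people who refuse colonoscopy — is worth its
price, measured in US dollars per life-year gained (LYG) against a
willingness-to-pay (WTP) threshold of \$100 000/LYG.

Six strategies are compared for a US average-risk cohort entering at age
45: no screening ("natural history", NH); annual faecal immunochemical
testing (FIT); decennial colonoscopy; triennial stool DNA (S-DNA);
triennial LB at 100% adherence; and a colonoscopy–LB hybrid (C-LB) in which
the 60.6% of the cohort who accept colonoscopy get it and everyone else
gets LB. First-line adherence for the traditional arms is 60.6%;
non-adherent people follow natural history. Screening stops at 75, polyp
surveillance at 85, follow-up at annual cycles until death or age 100.

## State space and cycle structure

States: `healthy`, undetected low-risk (LR) polyp, undetected high-risk
(HR) polyp; surveillance tunnels for LR (5-year) and HR (3-year)
intervals; six diagnosed-cancer states (first-year and continuing, for
SEER summary stages local/regional/distant); and two absorbing death
states (CRC death, other-cause death). Tunnel states count years since the
last colonoscopy: year 0 is the polypectomy year, and the tunnel has
`interval + 1` positions. This is deliberate: with the fixed per-cycle
order *events → transitions → accrual*, a K-position tunnel would fire
surveillance colonoscopies every K − 1 years; K + 1 positions realize the
guideline intervals (every 3 years for HR, 5 for LR) exactly.

Each cycle: (1) screening and surveillance events; (2) natural-history and
death transitions, other-cause death applied first in every state; (3)
accrual of life-years (alive mass at cycle start) and costs. No half-cycle
correction is applied (a config flag documents the choice); alternatives
differ at second order in the annual rates.

## Natural history and the cancer-onset mechanism

The inputs are age schedules: Gompertz–Makeham other-cause mortality
(emulating a CDC-style life table; default truncated life expectancy at 45
of ≈36 years), a log-linear-in-age baseline clinical CRC onset probability
(emulating pre-screening-era registry incidence; default lifetime risk
≈5.2% under competing mortality), and a logistic-in-age LR polyp onset
schedule with prevalence target curves (emulating CORI-style registry
prevalence: LR filling roughly linearly to ~36% by 75, the rarer HR subset
quadratically to ~6% at 65).

The central structural choice is how incident cancers relate to polyps.
Baseline incidence `i(a)` is allocated mostly to the HR-polyp compartment:
people with an undetected HR polyp face `hr_cancer_mult × i(a)` (default
multiplier 20), while healthy/LR/surveillance states face the residual
direct pathway `direct_cancer_fraction × i(a)` (default 0.15). This is
what makes polypectomy durably reduce subsequent incidence — the property
that gives colonoscopy its advantage. There is no preclinical cancer
state: "cancer onset" is diagnosis, and in the unscreened cohort every
diagnosis presents symptomatically. Polyps neither regress nor co-occur;
one polyp career per person at a time.

Stage at diagnosis is local/regional/distant: symptomatic presentations
default to (0.40, 0.35, 0.25), screen-detected to (0.50, 0.32, 0.18), a
realistic screen-shift magnitude for CRC. Cancer death is a stage-specific
constant annual probability (defaults 0.02/0.10/0.40 before calibration
scaling), competing with other-cause death; age dependence of cancer
mortality enters through that competition.

## How screening acts: programme sensitivity on flows

Test performance is applied to the natural-history *flows*, not to the
prevalent stocks, for every modality ("programme sensitivity"):

* an incident cancer in a sub-cohort covered by an active programme is
  screen-detected with the test's cancer sensitivity (colonoscopy: its
  92.8% detection rate; the 7.2% complement are interval cancers that
  present symptomatically), receiving the screen-detected stage
  distribution — in every covered year, not only test years;
* a newly arising LR polyp is detected with the test's LR sensitivity, and
  a polyp progressing into the HR stock with its HR sensitivity; detected
  polyps are removed (polypectomy, follow-up colonoscopy for stool/blood
  positives) and enter surveillance;
* a lesion missed at its single interception opportunity stays undetected:
  misses are treated as persistent and lesion-driven (size, morphology,
  haemoglobin shedding), not independent coin flips per test round.

This is the cohort-level annualization of applying published per-test
sensitivities to incidence data. The alternative — re-applying polyp
sensitivity to the prevalent stock at every test round — makes annual FIT
detect polyps almost surely within a decade and invert the published
ordering of stool DNA and FIT; with flow interception the incidence
reductions scale with single-test sensitivity, reproducing the published
pattern (colonoscopy > S-DNA > FIT > LB at zero). The cost of the
simplification is that the screening *interval* affects only testing and
false-positive costs, not detection; a more granular model would track
lesion dwell explicitly.

Test years follow the interval grid anchored at 45 (FIT annual, S-DNA and
LB every 3 years, colonoscopy every 10). At a test year the test cost is
charged for everyone not yet diagnosed or under surveillance, and
lesion-free screenees of stool/blood tests false-positive with
1 − specificity, buying a follow-up colonoscopy (cost plus age-specific
complication risk, no state change). Every colonoscopy — screening,
follow-up, surveillance, and the diagnostic colonoscopy charged at every
cancer diagnosis — carries the age-specific complication probability and
cost; complications are a cost item only. Surveillance colonoscopies are
attended with 100% adherence, re-detect polyps that re-arose during the
tunnel, and stop after 85; a negative surveillance colonoscopy continues
the person on the LR (5-year) track.

## Calibration

`calibrate_natural_history()` solves four one-dimensional root-finding
problems in a block sweep: the polyp onset scale against the LR prevalence
target at 65, the LR→HR progression rate against the HR target at 65, the
incidence scale against 5.2% lifetime CRC incidence, and the lethality
scale against 1.6% lifetime CRC mortality. Sweeps repeat (at most 10)
until no rate moves by more than a relative 5 × 10⁻⁴, making calibration
deterministic and idempotent up to that tolerance. Acceptance tolerances:
±0.3 percentage points on incidence, ±0.2 on mortality, ±5 points on the
prevalence curves at ages 55/65/75; a missed target raises an error
carrying the full target/achieved/residual report. Calibration of the
default bundle takes a few seconds.

## Economics

Costs are 2022 USD: per-test costs (colonoscopy 1366 with / 1119 without
polypectomy, FIT 52, stool DNA 492, LB 949), age-specific complication
costs, and stage × phase cancer-care costs (first year, continuing, final
year before cancer death). First-year and continuing costs accrue on
state occupancy; the final-year cost is charged on the transition into CRC
death, avoiding remaining-lifetime lookahead. Costs are discounted at 3%
per year from age 45.

Effectiveness is life-years after 45. The engine computes both discounted
and undiscounted life-years; the *default effectiveness measure is
undiscounted* (a config flag switches), because published per-strategy
totals of ≈35.6 LYG from age 45 are only attainable undiscounted (the
55-year discounted maximum is ≈27.5), while costs are plainly discounted.

The incremental analysis sorts by cost, removes strict dominance (ties are
dominated, deterministically by name order — the base case has no ties, so
any consistent rule suffices), then removes extended dominance until ICERs
are non-decreasing along the frontier. Every strategy is reported against
the most expensive nondominated strategy cheaper than itself. ICERs are
kept at full floating precision; note that published tables rounded their
incremental columns before the quotient, so printed ICERs can differ from
rounded-column arithmetic by a percent or two.

## Sensitivity machinery

*One-way analysis* reruns the model at the two bounds of one parameter
(negative lower bounds clamp to 0; costs default to ±25%). *Threshold
search* bisects the price at which an ICER crosses WTP, after refusing
non-monotone samples; because strategy cost is linear in any unit price,
the crossing agrees with the closed-form linear solution. *Scenario
analyses* grant LB polyp sensitivity over an HR 10–100% × LR 5–50% grid
(polyp-positive blood tests then buy a polypectomy colonoscopy and
surveillance entry), stretch the LR surveillance interval to 7/10 years,
and extend screening to 85.

The *probabilistic sensitivity analysis* samples every input
simultaneously: beta distributions for probabilities, gamma for costs,
moment-matched from mean and standard deviation. Published inputs state
that spreads came from literature-based 95% CIs without printing them, so
defaults are: probability sd = 0.10 × min(mean, 1 − mean) — the `min`
keeps beta moments feasible for near-boundary means such as the 99.5%
specificity — and cost sd implied by reading the ±25% bounds as a 95%
interval (the LB price uses its published 0–949 range). Sampling the
colonoscopy detection rate re-derives the complementary interval-cancer
rate. Per iteration all strategies are rerun and the optimal strategy is
the highest net monetary benefit (effect × WTP − cost), the standard
acceptability-curve construction. Results are bit-reproducible for a fixed
seed.

## What the synthetic epidemiology does and does not show

The generators emulate the *shapes and magnitudes* of the registry inputs
(monotone life table, rising incidence with ~5% lifetime risk, rising
polyp prevalence, stage-shifted screen detection, distant ≫ regional >
local lethality) without any downloads, so the whole analysis is
reproducible from code. They do not reproduce the actual SEER/CDC/CORI
tables; consequently absolute per-person costs, absolute LYG, threshold
prices and PSA percentages are emulation-scale quantities, not
reproductions of published absolutes. What the test suite therefore pins
down is (i) the exact frontier arithmetic on the published base-case
table, (ii) the calibrated natural-history targets (5.2% / 1.6%), and
(iii) the structural behaviour of screening: the published effectiveness
ordering C-LB ≥ colonoscopy ≥ S-DNA ≥ FIT ≥ LB ≥ NH, FIT extendedly
dominated, S-DNA and LB strictly dominated, colonoscopy cost-effective and
modal in the PSA at \$100 000/LYG, the hybrid's ICER far above threshold
and falling when LB gains polyp sensitivity, and an LB threshold price far
below its \$949 list price. Real-data features not modelled: sex/race
stratification, birth-cohort effects, adenoma size/count microsimulation,
the serrated pathway, imperfect follow-up adherence, stool/blood test
harms, and multi-cancer detection benefits.

## Problem sizes and numerical notes

The default analysis runs 21 states × 55 annual cycles per sub-cohort;
a six-strategy base case takes well under a second, and the test suite
uses a 500-iteration PSA (the published analysis used 5000; the CEAC
fractions stabilize to the modal strategy well below 500). Transition
matrices are validated row-stochastic to 10⁻¹²; occupancy is conserved to
10⁻⁹ over all cycles; root finding uses fixed brackets and `uniroot` at
10⁻⁸, so every result in the package is deterministic given the
configuration and seed.

```{r, eval = FALSE}
library(crcscreen)
params <- calibrate_natural_history(default_parameters())
tab <- run_strategies(params)
frontier <- incremental_analysis(tab[c("strategy", "cost", "effectiveness")])
decide_cost_effective(frontier, params$policy$wtp)
```
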