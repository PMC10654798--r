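# crcscreen

A cohort-level Markov state-transition model of colorectal cancer (CRC)
screening in average-risk US adults, built to evaluate blood-based
"liquid biopsy" (LB) screening against the established options and
against offering nothing at all.

## The problem

CRC screening works, but roughly 40% of US adults do not take up
colonoscopy or stool testing. Circulating-tumour-DNA blood tests detect
CRC with ~82% sensitivity and 99.5% specificity but (today) cannot detect
precancerous polyps, and they cost ~\$949 per test. Is LB a cost-effective
first-line screen? Is it worth offering to the people who refuse
colonoscopy? `crcscreen` answers both with a full cost-effectiveness
apparatus: a calibrated natural-history model, six screening strategies,
incremental cost-effectiveness analysis with strict and extended
dominance, one-way/threshold/scenario sensitivity analyses, and
probabilistic sensitivity analysis with acceptability curves.

The six strategies: natural history (NH, no screening), annual faecal
immunochemical testing (FIT), decennial colonoscopy, triennial stool DNA
(S-DNA), triennial LB at full adherence, and a colonoscopy–LB hybrid
(C-LB: the 60.6% who accept colonoscopy get it, everyone else gets LB).

## The model in brief

An annual-cycle cohort Markov model from age 45 to death or 100. States:
healthy → undetected low/high-risk polyp → diagnosed cancer
(local/regional/distant, first-year/continuing) → death, plus polyp
surveillance tunnels (colonoscopy every 3 years after a high-risk polyp,
every 5 after a low-risk one, until 85). For a strategy *S* with
per-person discounted cost *C(S)* and life-years *E(S)*, strategies are
ranked by the incremental cost-effectiveness ratio against the next least
costly nondominated comparator,

    ICER(S) = [C(S) − C(S′)] / [E(S) − E(S′)],

and a strategy is cost-effective when its ICER is below the
willingness-to-pay threshold λ = \$100 000 per life-year gained. Costs
(2022 USD) are discounted at 3%/year; effectiveness is undiscounted
life-years by default. All epidemiological inputs (life table, baseline
incidence, polyp prevalence, stage distributions, stage-specific
lethality) are synthetic, registry-shaped schedules generated in code and
calibrated so the unscreened cohort reproduces a 5.2% lifetime CRC
incidence and 1.6% CRC mortality. See `vignette("model-methods")` for the
full specification and design rationale.

## Worked example

```r
library(crcscreen)

params <- calibrate_natural_history(default_parameters())
tab <- run_strategies(params)
tab[, c("strategy", "cost", "effectiveness",
        "crc_incidence_pct", "crc_mortality_pct")]
#>      strategy cost effectiveness crc_incidence_pct crc_mortality_pct
#> 1          NH 1886         36.08             5.200            1.6000
#> 2         FIT 2677         36.10             4.524            1.3529
#> 3 Colonoscopy 2858         36.15             2.537            0.7593
#> 4       S-DNA 3919         36.12             3.978            1.1792
#> 5        C-LB 5386         36.15             2.537            0.7339
#> 6          LB 8301         36.09             5.200            1.5356

frontier <- incremental_analysis(tab[c("strategy", "cost", "effectiveness")])
frontier
#>     strategy    cost effectiveness               status      icer
#>           NH 1885.72       36.0800            reference        NA
#>          FIT 2676.97       36.1029 extendedly_dominated        NA
#>  Colonoscopy 2858.06       36.1504         nondominated   13807.9
#>        S-DNA 3919.07       36.1178   strictly_dominated        NA
#>         C-LB 5385.55       36.1539         nondominated  724747.4
#>           LB 8300.66       36.0889   strictly_dominated        NA

decide_cost_effective(frontier, params$policy$wtp)
#> [1] "Colonoscopy"
```

Reading the output: the unscreened cohort lives 36.08 years after 45 and
5.2% develop CRC. Every screening arm cuts cancer deaths; colonoscopy and
the hybrid cut incidence the most because polypectomy removes precursors.
Colonoscopy is on the efficiency frontier at ~\$13.8k per life-year —
comfortably cost-effective. The hybrid adds a small sliver of life-years
at a steep price (ICER far above \$100 000), FIT is extendedly dominated
(its cost per life-year exceeds colonoscopy's), and stool DNA and
LB-alone are strictly dominated — LB-alone buys the *fewest* extra
life-years at the *highest* cost, because without polyp detection it
prevents no cancers. A threshold search
(`threshold_price("costs.lb", c("NH", "LB"), 1e5, c(0, 949), params = params)`)
shows the LB price would have to fall to roughly \$130 before offering it
to an unscreened population becomes cost-effective.

Other entry points: `one_way_sa()` / `tornado_table()`,
`scenario_lb_polyp()` (LB with polyp sensitivity),
`scenario_intervals_endage()`, `run_psa()` (probabilistic sensitivity
analysis with CEAC), `run_pipeline()` (writes CSV/JSON artifacts), and a
thin CLI at `inst/cli/crcscreen.R` with `calibrate`, `run`, `frontier`,
`owsa`, `threshold`, `scenario` and `psa` subcommands.

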