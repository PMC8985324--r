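# eimtd

Early identification of the maximum tolerated dose (MTD) in time-to-event
model-assisted phase I dose-finding designs.

Phase I oncology trials escalate through a small set of dose levels to find
the MTD — the dose whose probability of a dose-limiting toxicity (DLT)
within a fixed assessment window is closest to a target rate (typically
30%). Model-assisted designs (mTPI, Keyboard, BOIN) pre-tabulate their
escalate/retain/de-escalate decisions as DLT-count boundaries, and their
time-to-event (TITE) variants keep enrolling while earlier patients'
assessments are still pending by counting each pending patient's elapsed
follow-up as partial non-toxicity evidence. Even so, a TITE trial cannot
declare the MTD until the full sample size is reached. `eimtd` implements
an adaptive early-identification (EI) rule on top of the TITE designs: at
each dose-assignment decision it computes the predictive probability that
the design's decision after all remaining patients would still be
"retain", and stops the MTD-estimation phase as soon as that probability
clears a threshold. The package is for trial statisticians designing or
monitoring such studies, and for methodologists benchmarking their
operating characteristics.

## The dose-retainment probability

At the current dose let `n_DLT` be the DLT count, `n_e = n_noDLT + Σ t_i/t`
the effective DLT-free count (completed DLT-free patients plus pending
follow-up fractions of the window `t`), `r` the number of patients not yet
enrolled, and `r_pend` the effective number of future patients. With
`E_{n+r}` and `D_{n+r}` the escalation/de-escalation boundaries of the
design's table at `n + r` patients, the dose-retainment probability is

    BB(D_{n+r} − 1 − n_DLT; r_pend, n_DLT, n_e) − BB(E_{n+r} − n_DLT; r_pend, n_DLT, n_e)

where `BB(a; b, α, β)` is the cumulative beta-binomial distribution
function, generalized to a fractional number of trials `b`. When
`n_DLT = 0` both shape parameters get a 0.5 correction. The trial stops
and declares the current dose the MTD when this probability exceeds the
threshold (recommended 0.4); at the minimum and maximum doses, where only
one decision direction exists, the one-sided statistic `1 − BB(E − n_DLT; …)`
or `BB(D − 1 − n_DLT; …)` is compared against the doubled threshold (0.8).

## Worked example

The decision-boundary table for a BOIN design with a 30% target, and the
retainment probability of an interim state with 9 patients at the current
dose (3 DLTs, 4 completed DLT-free, two pending at 2 and 1 months of a
3-month window) with 6 patients remaining:

```r
library(eimtd)

design <- design_spec("BOIN", target = 0.3)
tab <- boundary_table(design, n_max = 18)
tibble::as_tibble(tab)[tab$n %% 3 == 0, ]
#>       n escalate_le deescalate_ge
#> 1     3           0             2
#> 2     6           1             3
#> 3     9           2             4
#> 4    12           2             5
#> 5    15           3             6
#> 6    18           4             7

state <- dose_state(n_dlt = 3, n_nodlt = 4,
                    pending = pending_fraction(c(2, 1), 3))
res <- retainment_probability(state, r = 6, tab)
res
#>   p_not_deescalate p_escalate p_retain   n_e r_pend boundary_e boundary_d
#> 1              0.5     0.0962    0.404     5      7          3          6
ei_decision(res, "interior")
#>   verdict statistic threshold dose_position
#> 1 stop        0.404       0.4 interior
```

The not-de-escalate probability is 0.500, the escalate probability 0.096,
so the dose is retained with predictive probability 0.404 — above the 0.4
threshold, and the MTD-estimation phase can stop at this dose.

A full simulated trial with early identification enabled:

```r
cfg <- trial_config(design, ei = ei_config())
tr <- run_trial(cfg, scenario(c(0.14, 0.30, 0.45, 0.55, 0.65, 0.75)),
                seed = 1)
tr
#> <ei_trial> early_identification; MTD = 2; n = 30; duration = 15.00 months
tidy(tr)
#>    dose     n n_dlt   rate eliminated selected
#> 1     1     9     1  0.111 FALSE      FALSE
#> 2     2    15     3  0.2   FALSE      TRUE
#> 3     3     6     4  0.667 TRUE       FALSE
#> ...
```

The trial stopped after 30 of 36 planned patients, 15 months in, declaring
dose 2 (true DLT rate 0.30) the MTD; dose 3 was eliminated for excess
toxicity. `run_simulation()` repeats this across designs and scenarios on
matched patient streams and summarises the percentage of correct MTD
selection, early-identification rate, and mean duration and sample size;
`autoplot()`, `tidy()` and `glance()` give figures and tables.

A thin command-line front end ships in `exec/eimtd` (subcommands
`boundaries`, `eiprob`, `report`, `scenario`, `simulate`).

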