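---
title: "Early identification of the MTD in TITE model-assisted designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early identification of the MTD in TITE model-assisted designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eimtd)
```

## The problem

A phase I dose-finding trial treats successive cohorts at one of a small
number of dose levels and aims to identify the maximum tolerated dose
(MTD): the dose whose true probability of a dose-limiting toxicity (DLT)
within a fixed assessment window is closest to a target level $\phi$
(0.30 throughout this vignette). Model-assisted designs — mTPI, Keyboard,
and BOIN — make each escalate/retain/de-escalate decision from a
pre-tabulated pair of DLT-count boundaries, and their time-to-event (TITE)
variants avoid suspending accrual for the full window by letting a pending
DLT-free patient contribute the elapsed fraction of their window as
partial evidence of non-toxicity. What neither variant provides is a
principled way to *stop the MTD-estimation phase early* once the
remaining patients are very unlikely to change the answer. This package
implements such a rule, driven by a predictive "dose-retainment
probability", together with the boundary tables, a trial engine, and a
batch simulator for its operating characteristics.

## Decision boundaries

Each design family is specified by `design_spec()`:

* **BOIN** compares the observed DLT rate with closed-form interval
  boundaries $\lambda_e, \lambda_d$ chosen to minimize the probability of
  a mis-assignment against under/over-dosing anchors $\phi_1, \phi_2$
  (defaults $0.6\phi$, $1.4\phi$). For $\phi = 0.30$ these are
  $(0.2365, 0.3585)$; escalation requires a rate strictly below
  $\lambda_e$ and de-escalation a rate at or above $\lambda_d$, the
  convention that reproduces all published worked cases.
* **mTPI** maximizes the unit probability mass (interval posterior
  probability over interval width) of the under-dosing, proper
  $(\phi-\epsilon_1, \phi+\epsilon_2)$, and over-dosing intervals under a
  $\mathrm{Beta}(1,1)$-prior posterior.
* **Keyboard** tiles $(0,1)$ with keys the width of the proper interval,
  discards partial-width edge strips, and moves toward the key with the
  largest posterior mass.

`boundary_table()` tabulates, for every $n$ up to the planned sample
size, the largest DLT count that escalates ($E_n$) and the smallest that
de-escalates ($D_n$); the simulator needs every $n$, not just cohort
multiples. Ties in the mTPI statistic break toward retain, then escalate,
and a Keyboard tie goes to the key nearer the target key — ties occur
only on measure-zero parameter sets, so the choice is a formality.

One discrepancy is worth knowing about: the published mTPI de-escalation
row for $\phi = 0.3$ (2, 3, 4, 5, 7, 8 at $n$ = 3…18) is not what the
unit-probability-mass rule yields at several cells (the rule retains at
3/6 and 4/9, giving 4 and 5 there). `boundary_table()` follows the rule;
the published row ships as a CSV under `inst/extdata/` and loads verbatim
with `read_boundary_table()` for replication runs.

```{r}
boundary_table(design_spec("BOIN", 0.3), n_max = 12)
```

## The dose-retainment probability

Write $n_{DLT}$ for the DLT count at the current dose, $n_e$ for the
effective DLT-free count (completed DLT-free patients plus the summed
follow-up fractions of pending patients), $r$ for the patients not yet
enrolled, and $E_{n+r}, D_{n+r}$ for the boundaries at the final sample
size of this dose. Future toxicity counts are modelled as a beta-binomial
with shapes $(n_{DLT}, n_e)$ over $r_{pend}$ effective future trials, and

$$P(\text{retain}) \;=\; BB(D_{n+r}-1-n_{DLT};\, r_{pend}, n_{DLT}, n_e)
\;-\; BB(E_{n+r}-n_{DLT};\, r_{pend}, n_{DLT}, n_e).$$

Because $n_e$ and $r_{pend}$ are fractional, the implementation
(`dbbinom()`/`pbbinom()`) generalizes the binomial coefficient with gamma
functions and evaluates everything in log-gamma space with a single final
exponentiation; for fractional trial counts the masses need not sum to
one, which is immaterial since the rule only ever uses CDF differences.
The trial halts and declares the current dose the MTD when
$P(\text{retain})$ exceeds a threshold $\tau$, with $\tau = 0.4$ the
recommended default. At the maximum dose no escalation exists and the
criterion is $BB(D-1-n_{DLT};\cdot) > 2\tau$; at the minimum dose it is
$1 - BB(E-n_{DLT};\cdot) > 2\tau$. When $n_{DLT} = 0$ both shape
parameters receive a 0.5 correction so the implied beta prior stays
proper; the same guard applies symmetrically when $n_e = 0$ (a dose with
only just-enrolled patients).

Two interpretive choices deserve a note:

* **Shape parameters.** The second beta shape is $n_e$, not
  $n_{DLT} + n_e$: both published worked examples evaluate
  $BB(\cdot;\, 7, 3, 5)$ from a state with $n_{DLT}=3, n_e=5$, and only
  the $(n_{DLT}, n_e)$ reading reproduces their 0.500 and 0.096.
* **Effective future trials.** `future_trials()` defaults to
  $r_{pend} = r + \sum_i (1 - f_i)$ — each pending patient contributes
  the *unresolved remainder* of their window. Every printed example has
  $\sum f_i = \sum(1-f_i)$, so the data cannot discriminate this from the
  literal reading $r + \sum_i f_i$, but only the remainder convention
  makes a patient at the very end of their window equivalent to a
  completed one (a continuity property the tests verify to $10^{-9}$).
  The literal reading remains available as a config option.

```{r}
tab <- boundary_table(design_spec("BOIN", 0.3), n_max = 18)
st <- dose_state(n_dlt = 3, n_nodlt = 4, pending = pending_fraction(c(2, 1), 3))
retainment_probability(st, r = 6, tab)
```

## Trial conduct

`run_trial()` conducts one trial as a discrete-event loop. Patients
arrive per the accrual model (deterministic spacing by default, Poisson
optional) and enroll in cohorts of `cohort_size` (default 3) at the
current dose. At each cohort boundary, in order:

1. **Suspension.** Under the TITE conduct the next cohort waits until at
   least `suspension_min_complete_fraction` (default 50%) of the current
   dose's outcomes have resolved — a standard safeguard of the TITE
   designs; the plain (non-TITE) conduct waits for *all* of them, which
   is exactly what makes it slower.
2. **Elimination.** A dose with at least 3 patients and posterior
   probability above 0.95 that its rate exceeds $\phi$ (under a
   $\mathrm{Beta}(1+n_{DLT}, 1+n_e)$ posterior) is eliminated together
   with all higher doses; eliminating the lowest dose terminates the
   trial with no MTD. Effective counts are used here for consistency
   with the imputation rule.
3. **Dose assignment.** The design's rule on the effective data
   $(n_{DLT}, n_e)$, with no dose skipping and no move onto an
   eliminated dose. With no pending patients this is exactly the
   complete-data table decision.
4. **Early identification**, when enabled, for the dose the next cohort
   is assigned to, with $r$ = planned minus treated. One conduct rule is
   ours: when the assignment is a *blocked de-escalation at the lowest
   dose*, the EI check is skipped. The design wants to leave that dose,
   so "dose maintenance" does not apply — and since the minimum-dose
   statistic $1 - BB(E - n_{DLT}; \cdot)$ grows as the data get *more*
   toxic, checking it there would mechanically declare an over-toxic
   lowest dose the MTD. In simulation this single guard removes most
   wrong minimum-dose declarations (several percentage points of correct
   selection) while leaving the early-identification rate at the ~70%
   level the EI rule is known for.

On an EI stop the study duration is the decision time itself — pending
patients' remaining follow-up and all unenrolled patients are saved,
which is what the `days_saved()` projection quantifies for interim
reports. A completed trial selects the MTD by weighted isotonic
regression (pool-adjacent-violators) of the per-dose
$\mathrm{Beta}(0.05, 0.05)$ posterior mean rates, weights the patient
counts, choosing the tried, non-eliminated dose closest to $\phi$ (ties:
higher dose if below target, lower if above). The selection prior and
tie-breaks follow common model-assisted practice; they are not part of
the EI rule itself.

EI is evaluated at cohort-boundary decision times. An interim look taken
mid-assessment (as in the reconstructed trial below) is expressed as a
decision time through `report_interim()`.

## The simulator and what it does (and does not) emulate

`run_simulation()` crosses design variants (plain, TITE, EI-TITE × mTPI,
Keyboard, BOIN) with scenarios and replicates. All variants of a
replicate consume one latent patient stream — arrival offsets, a uniform
$u$ per patient deciding DLT at dose $d$ iff $u < p_d$ (monotonically
coupled across doses), and a latent onset fraction — so percent-change
metrics are paired differences, which cuts their Monte-Carlo variance
substantially. Default study conditions are those of the motivating
simulation study: 6 doses, $N = 36$, cohorts of 3, a 3-month window, 2
patients/month, $\phi = 0.3$, threshold 0.4. DLT onset is uniform over
the window by default, with a truncated-Weibull option for late-onset
stress tests. `random_scenario()` draws the MTD position uniformly,
places its rate within $\phi \pm 0.03$, and extends the curve with
uniform spacings (close: 0.05–0.15; wide: 0.10–0.25) — a parameterized
surrogate for scenario recipes that are not publicly available, so
simulated operating characteristics should be compared *between variants
under matched seeds*, not against any published per-scenario table.

The generator emulates monotone dose-toxicity curves, a single toxicity
grade, complete follow-up within a fixed window, and steady accrual. It
does not emulate inter-patient heterogeneity, dropout, delayed grading,
or non-monotone (e.g. plateauing) curves; passing tests show the designs
behave as specified under the stated model, not that real-trial
performance is guaranteed.

```{r, eval = FALSE}
s <- run_simulation(scenario(c(0.14, 0.30, 0.45, 0.55, 0.65, 0.75)),
                    designs = c("tite-boin", "ei-tite-boin",
                                "tite-keyboard", "ei-tite-keyboard"),
                    n_reps = 2000, base_seed = 1)
autoplot(s)
```

At these settings the EI variants lose only a point or two of correct
selection against their TITE counterparts while stopping early in roughly
two-thirds to three-quarters of trials and cutting mean duration by about
a third — the pattern the rule is designed to deliver. (The test suite
recomputes these comparisons at 2,000 replicates; the vignette chunk is
not evaluated to keep builds light.)

## Numerical choices and degenerate inputs

* All beta-binomial evaluation is in log-gamma space; terms outside the
  generalized support (where a gamma argument would be non-positive) are
  zero, and a negative success bound returns probability 0 — the natural
  outcome when $n_{DLT}$ already exceeds a boundary.
* A sentinel (absent) de-escalation boundary yields a not-de-escalate
  probability of 1, an absent escalation boundary an escalation
  probability of 0.
* $r = 0$ with no pending patients collapses the distribution to a point
  mass: the retainment probability is 0 or 1 according to the current
  counts against the boundaries.
* A threshold above 1 (or a boundary multiplier making $2\tau > 1$)
  disables EI; the engine then reproduces the non-EI trial record
  bit-for-bit under the same latent stream, which the tests assert.
* Boundary tables are validated on read: non-monotone rows or
  $D_n \le E_n$ are rejected with the offending row number.

## Known limitations

* The published mTPI row discrepancy above means mTPI interim statistics
  computed from rule-derived tables differ numerically (though not in
  verdict, in all reconstructed cases) from ones computed with the
  published table; use the shipped CSV when replication matters.
* The EI rule declares the *current* dose; it does not implement joint
  multi-dose stopping or EI for a dose other than the next cohort's.
* The simulator's scenario generator is a surrogate (above); its
  operating characteristics are internally comparable, not externally
  normative.
* Isotonic MTD selection conventions (prior, tie-breaks) are one common
  choice among several; selection-sensitive comparisons should hold them
  fixed across variants, as `run_simulation()` does.
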