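---
title: "Pathway-based operating theatre planning: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based operating theatre planning: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(theatreplan)
library(dplyr)
```

## The problem

Elective surgery in a block-booked operating suite is planned against two
coupled resources: the weekly grid of specialty-labelled OR sessions (the
Master Surgical Schedule, MSS) and the waiting list, where patients of five
Urgency Related Groups (URG) accumulate.  The package implements an
integrated method: a **standardised surgical pathway** that converts each
patient's characteristics into a precise theatre occupation time, and a
**0–1 assignment model** that selects which waiting patients fill which OR
blocks of a target week, run three times as the week approaches
(moving-target planning).

## The pathway duration model

Every case is described by a small profile: the surgeon-declared Expected
Operating Time (EOT), one of four anesthesia types, a set of systemic risk
conditions, logistics flags (ward in the same building, elective use of a
preparation room) and the exit destination (recovery room, intensive care,
or directly to the ward).

Three phase durations are risk-sensitive: induction (base = the anesthesia
type's induction task, 10 min for type A, 15 for B/C/D), surgery (base =
EOT) and emergence (10/15 min).  A risk with incidence $p\%$ on a phase
inflates it; with several risks the default rule is additive,

$$t' = t \Big(1 + \sum_i p_i/100\Big),$$

which is order-independent and never exceeds the compounding alternative
(`combine = "multiplicative"`, $t\prod_i(1+p_i/100)$) available as an
option.  The parameter tables ship with the package and reproduce the
studied unit's printed values exactly (see `default_anesthesia_profiles()`,
`default_risk_table()`, `default_task_timings()`); they can also be loaded
from YAML with schema validation.

Two assembled durations matter downstream:

* **OR occupation time** — enter theatre + induction + surgery + emergence
  + exit transfer + anesthesia-specific preparation-and-cleaning time.
  This is what a case charges against block capacity.
* **Total pathway time** — the patient's ward-to-ward interval, which
  swaps cleaning (a theatre cost, not a patient cost) for transports and
  the destination branch (recovery stay, ICU transfer, or ward transport).

```{r}
case <- tibble::tibble(eot_min = 60, anesthesia = "B",
                       risks = list(character(0)), same_building = TRUE,
                       use_prep_room = FALSE, destination = "recovery_room")
or_occupation_time(case)$occupation_min
total_pathway_time(case)$pathway_min
```

Design choices worth recording:

* The source tables disagree on induction: the staffing table prints an
  aggregate *induction time* of 30/45 min for types C/D, while the
  task-execution table decomposes the same interval into a 15-min
  anesthesia task plus a separate 30/45-min preparation-room task.  The
  task-level decomposition is canonical here (it is the per-task account);
  the aggregate column is retained as reference metadata
  (`table6_induction_min`).
* Exit transfer times are printed only for ICU (10 min) and recovery room
  (5 min); direct-to-ward exits are charged the smaller recovery-room
  value, configurable via `ward_exit_min`.
* Risk incidences apply to induction/surgery/emergence only; transports
  and ancillary tasks are never risk-adjusted.
* Whether the operating-time incidence should inflate the surgeon's EOT is
  genuinely open — a surgeon may already account for a coagulopathy in the
  declared time.  The default inflates; `adjust_eot = FALSE` trusts the
  declaration.
* Fractional minutes from percentage adjustments are kept exact
  internally; nothing is rounded before capacity arithmetic.

## Waiting cost: Need Adjusted Waiting Days

Each URG class carries an urgency coefficient; a patient's waiting cost at
any date is $\mathrm{NAWD} = c_{\mathrm{URG}} \times \text{elapsed days}$.
The class coefficients themselves are not published; the package ships the
standard inverse-of-maximum-wait construction
($c = 360/\text{max wait days}$, giving 24, 12, 6, 2, 1 for AA–D over
maximum waits of 15, 30, 60, 180, 360 days).  Every scheduling property
tested — feasibility, optimality against enumeration, urgency dominance,
cap monotonicity — is invariant to the particular coefficients, provided
they decrease strictly from AA to D.

## The 0–1 assignment model

For a target week the model has a binary variable $x_{ib}$ for every
patient–block pair with matching specialty, and constraints:

1. each patient in at most one block;
2. per block, the summed occupation load may not exceed the 360-min block
   duration — **no overtime** ever enters the plan;
3. per specialty, the scheduled load may not exceed the phase's cumulative
   utilisation cap times the specialty's own MSS capacity (this is what
   stops one specialty "cannibalising" the week before urgent patients of
   another have arrived).

The objective minimises total waiting cost.  An unscheduled patient is
charged NAWD at a *horizon end* placed one week after the target week's
last block — the earliest date the next planning cycle could serve them; a
scheduled patient is charged coefficient × wait to the block date; moving
or dropping a previously planned patient adds the phase's postpone or
cancel penalty.  The published account fixes only the currency (NAWD) and
the penalty ordering (cancellation ≫ postponement); this functional form
is the package's reconstruction, and every term is configurable.  Defaults
resolve the penalties to 1× and 5× the median per-patient NAWD of the
phase's candidates.

Numerical choices:

* **Load definition.** Capacity constraints use the full pathway-derived
  occupation time by default (`load = "occupation"`); `load = "eot"`
  reproduces a bare-EOT variant.
* **Tie-breaks and determinism.** Waiting costs are exact integers
  (coefficient × whole days).  Perturbing them to break ties was
  considered and rejected: fractional objectives prevent the solver from
  rounding its dual bound, which measurably slows convergence on
  oversubscribed instances.  Instead patients enter the model in a
  canonical order (earlier registration, then smaller id) and the solver
  is deterministic, so a given data set always yields the same schedule;
  among exactly-tied optima the returned one is reproducible, though not
  guaranteed to be the lexicographic minimum.
* **Infinite penalties** become hard constraints (the prior assignment is
  fixed, or the patient is forced to stay scheduled) rather than big-M
  terms, keeping the matrix well scaled.
* **Solver.** The model is solved with the HiGHS MILP solver through
  SciPy's `milp`, via a bundled helper executed as a subprocess; the
  default relative gap tolerance is $10^{-4}$ — the convention of
  industrial MIP codes, and well below one waiting day on any realistic
  objective — with a 60 s limit per sub-model; tests that assert exact
  optimality against enumeration tighten the gap to $10^{-9}$ on their
  tiny instances.  When a sub-model reaches its time limit the default is
  an error; `on_timeout = "incumbent"` instead keeps the best feasible
  schedule found and records `proven_optimal = FALSE` in the solver
  statistics, which is the sensible mode for feasibility audits and
  routine planning.  Because
  blocks carry a single specialty and caps are per specialty, the
  constraint matrix is block-diagonal over specialties; the package solves
  the independent sub-models separately and batches all of them into one
  subprocess call.  An exact enumeration backend (`backend =
  "enumerate"`) exists for tiny models and cross-checks.  HiGHS is
  deterministic, so for a fixed seed the whole pipeline reproduces the
  same schedule byte for byte.

## Three-phase moving-target planning

The target week is planned three times: 5 weeks ahead (URG B/C/D, up to
50 % of each specialty's capacity), 3 weeks ahead (URG A, with B/C/D
admitted as fill when the urgent load is low, up to a cumulative 75 %) and
1 week ahead (URG AA, up to 100 %).  Scheduled patients leave the waiting
list; each later phase re-optimises with the earlier assignments as soft
constraints, so an urgent arrival can displace a planned patient — at a
price — rather than being turned away.  The phase-2 fill rule is
implemented economically: B/C/D candidates simply enter the model with
their (lower) waiting costs, so they yield exactly when priority patients
compete for the same minutes.  Phase 3 admits only AA by default; whether
it too should fill with less urgent classes is left as configuration
(`fill_urgs`).

```{r, eval = FALSE}
wl <- generate_waiting_list(630, "2026-06-15", seed = 1)
arr <- generate_arrivals(3112 / 52, 5, "2026-06-16", seed = 2)
plan <- plan_three_phase(wl, arrivals = arr)
glance(plan)
utilization_report(plan)
```

## The synthetic generator

No patient-level records are published, so the package generates waiting
lists with the statistical structure of the studied unit's annual case
load: 3112 elective cases whose specialty, URG and EOT-bin margins are the
printed annual tables.  Specialty, URG and EOT are drawn independently —
only marginals are published; a joint-weight table can be supplied where
correlations matter.  EOT is uniform within its 30-min bin; the open-ended
">150 min" bin is uniform on (150, 360], bounded by a 12-h block.
Registration dates are back-dated uniformly within each class's maximum
wait, which reproduces a standing list in which no patient has yet
breached their guarantee; arrivals are Poisson at the annual rate spread
evenly (≈60/week).

Anesthesia-type shares (A/B/C/D = 0.25/0.40/0.25/0.10), per-risk
prevalence (5 % each, independent) and logistics probabilities
(same-building 0.75; preparation room elected for half of C/D cases;
destinations 75 % recovery, 15 % ward, 10 % ICU) are **not** published
anywhere; they are conventions chosen once as clinically plausible for a
paediatric tertiary unit and marked as such in `case_mix_spec()`.  What
passing tests show is therefore structural: feasibility, optimality,
dominance and throughput properties of the method on realistic case
mixes — not a reproduction of any real hospital week, whose correlations
(e.g. long EOTs clustering in particular specialties) the independence
assumption deliberately ignores.

## Problem sizes and test design

The test suite checks optimality against an independent brute-force
enumerator on 1,000 random instances of up to 8 patients and 3 blocks
(every assignment vector enumerated and costed from first principles),
feasibility on 200 solved synthetic weeks of 150 patients, and the
throughput property — the optimised plan never schedules fewer patients
than first-come first-served packing, and strictly more on at least 80 %
of seeds — on twenty 630-patient weeks.  These sizes were chosen so the
whole suite solves tens of thousands of binary variables in minutes while
still covering every constraint family at realistic scale.

## Known limitations

* Within-block sequencing, overtime, staff rostering and same-day
  emergency insertion are out of scope by design; blocks are capacity
  bins.
* Durations are deterministic given the profile; there is no stochastic
  duration model, so the no-overtime guarantee is a guarantee about
  *expected* times.
* The objective's functional form beyond the NAWD currency is a
  reconstruction (see above); headline counts from any particular
  hospital week depend on an unpublished waiting list and are mirrored
  here only as properties (optimised ≥ FCFS, postponements occur under
  urgent load, cancellation priced above postponement).
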