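# theatreplan

Elective operating-theatre planning for block-booked surgical suites.
`theatreplan` is aimed at hospital planners and health-operations
researchers who must turn a prioritised waiting list into a weekly OR
schedule: it combines a **standardised surgical-pathway duration model**
(what exactly does this case cost the theatre, in minutes?) with a **0–1
optimisation model** (which patients fill which OR blocks?) run over a
three-phase rolling horizon.

## The method in brief

**Pathway durations.** Each case profile — surgeon-declared Expected
Operating Time (EOT), anesthesia type A–D, systemic risks, logistics,
exit destination — is converted into task-level durations.  A risk with
incidence $p\%$ inflates the induction, operating or awakening phase by
$t' = t\,(1 + \sum_i p_i/100)$.  The theatre occupation time charged
against block capacity is

enter theatre + induction + operating + awakening + exit transfer +
preparation/cleaning,

and always exceeds the bare EOT.

**Assignment model.** Patients on the waiting list belong to five Urgency
Related Groups (URG AA–D) with coefficients $c$; waiting cost is measured
in Need Adjusted Waiting Days, $\mathrm{NAWD} = c \times$ elapsed days.
Binary variables $x_{ib}$ assign patients to same-specialty OR blocks
subject to: one block per patient; per-block load ≤ 360 min (no
overtime); per-specialty load ≤ cap × own MSS capacity.  The objective
minimises total NAWD, with penalties for postponing or cancelling
previously planned patients.  Three phases plan the same target week at
5, 3 and 1 weeks ahead (URG B/C/D to 50 %, +A to 75 %, +AA to 100 %).
Models are solved with the HiGHS MILP solver (via SciPy's `milp`, bundled
helper script; a `python` interpreter with SciPy must be on the PATH).

## Worked example

```r
library(theatreplan)

# a 630-patient standing list and the default 3-room weekly MSS
wl   <- generate_waiting_list(630, "2026-06-15", seed = 7)
arr  <- generate_arrivals(3112 / 52, n_weeks = 5, "2026-06-16", seed = 8)
plan <- plan_three_phase(wl, arrivals = arr)
plan
#> <three_phase_plan> target week starting 2026-07-20
#> <or_schedule>
#>   882 patients: 90 planned, 0 postponed, 0 cancelled, 792 unscheduled
#>   solver: three_phase
#>   changelog: 0 postponement(s), 0 cancellation(s)

base <- fcfs_baseline(wl, plan$blocks)
compare_schedules(plan, base)[, 1:3]
#> # A tibble: 1 × 3
#>   planned_optimized planned_baseline throughput_gain_pct
#>               <int>            <int>               <dbl>
#> 1                90               68                32.4
```

90 of the patients considered fit the 30 blocks of the target week (the
half-day sessions of 3 rooms × 5 days) within every capacity and phase
cap; first-come first-served packing of the same list places only 68, so
the optimised plan treats ~32 % more patients from the same block time.
`utilization_report(plan)` breaks occupation down per block, specialty,
URG and phase, `tidy(plan)` returns the per-patient assignment table, and
`autoplot(plan)` draws the block-occupation chart.

Parameter tables (anesthesia types, risk incidences, task timings, URG
classes, the weekly MSS grid, phase configs) ship as validated YAML under
`inst/extdata/` and are fully configurable.  A thin command-line front
end with `generate` / `plan` / `baseline` / `report` / `compare`
subcommands lives at `inst/cli/theatreplan`.

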