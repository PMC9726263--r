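---
title: "Methods: surgical scheduling under capacity reservation and the OLAS clinic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surgical scheduling under capacity reservation and the OLAS clinic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orsched)
```

# The scheduling model

`orsched` schedules elective surgical patients into a block-structured
theatre calendar. A calendar has `days` × `blocks_per_day` cells per room;
blocks and days are 1-based and a block `t` covers wall-clock `[t, t+1)`.
An operation of duration `du` starting at block `t` occupies the inclusive
window `t … t+du−1` of one room, one surgeon and one day. Surgeries never
span days: the model defines occupancy only within a day, so day-crossing
starts are rejected at construction rather than silently wrapped.

The decision is a binary start indicator per (patient, room, surgeon,
block, day) cell. The objective sums four linear terms: assignment costs
`C[p,o,s]`, idle costs `EC[o,d]` per regular block left unused, overtime
costs `LC[o,d]` per elective block beyond the regular budget `HN[o,d]`,
and ICU shortage costs `U[d]` per bed demanded beyond the available
budget. When the rescheduling extension is active a fifth term prices
deviations from previously communicated baseline starts.

Hard constraints:

* **Coverage** — every elective patient is assigned exactly once.
* **Non-overlap** — one case per room-block and per surgeon-block.
* **Deadlines and eligibility** — enforced *structurally*: start variables
  after a patient's deadline or on ineligible rooms/surgeons are never
  created, which keeps the model small and makes these restrictions
  impossible to violate by rounding.
* **Cleaning** — an infectious case of duration `du` with cleaning
  requirement `cl` blocks all other starts in its room during
  `t … t+du+cl−1`. This is conditional on the infectious case actually
  starting at `t`; the package linearizes it with a big-M bounded by the
  window length (a start window inside one room admits at most one case
  per block, so the bound is tight).
* **Infectious-last** — within a room-day, no clean patient may start
  after an infectious one. Together with the cleaning window this means
  infectious cases close their room for the day.
* **Workload** — a shared daily elective cap `G` per surgeon (blocks/day)
  and a per-surgeon horizon cap `MT[s]` (blocks over the whole calendar).
* **ICU linkage** — a surgery on day `d` admits the patient to the ICU on
  `d` (big-M = `blocks_per_day`, the largest possible daily occupancy of
  one patient), opening a bed-occupancy window of `icu_days` consecutive
  days, clipped at the horizon; `icu_days = 0` opens no window.

## Emergency arrivals as chance constraints

Emergency patients are not scheduled — they are random demand. Three
quantities are modelled as normal random variables: emergency
operating-room demand `HM̃[o,d]`, emergency ICU demand `WICŨ[d]`, and ICU
capacity `Cicũ[d]`. The package converts each capacity restriction that
contains them into its deterministic equivalent at a user-chosen
reliability `α ∈ (0,1)` (`reserve_margin()`): a normal inequality holds
with probability `α` iff the deterministic version holds with
`z_α = qnorm(α)` standard deviations added to the mean. Concretely,

* elective room budget: `HN + HO − (E[HM̃] + z_α·sd[HM̃])`, floored at 0 —
  a reservation larger than the physical budget empties the elective
  budget rather than making it negative;
* ICU bed budget: `E[Cicũ] − E[WICŨ] − z_α·√(Var[Cicũ] + Var[WICŨ])`,
  treating supply and demand as independent normals so their difference
  is normal with summed variances. The budget may be negative; the
  shortage variable `Z[d] ≥ 0` is unbounded above (the model's stance is
  that extra beds can always be found at linear cost `U[d]` — no hard cap
  is imposed because none is defined).

Two limiting behaviours are useful checks and are tested: `α = 0.5` gives
`z = 0`, i.e. the pure expected-value model; zero variances make the
margin independent of `α`, so all reliabilities give identical feasible
regions. Raising `α` only shrinks the feasible region, so the optimal cost
is non-decreasing in `α` — the difference is the price of reliability.
Whether stochastic capacities should enter at their means or with a
safety margin is genuinely open in this model class; exposing `α` (default
0.95, a conventional service level) rather than hard-coding either choice
was the package's resolution.

## Solvers and the oracle chain

Three independent routes produce or audit schedules:

1. `solve_milp()` builds the sparse constraint matrix in R and solves it
   with the HiGHS branch-and-cut solver (driven through a bundled SciPy
   bridge), single-threaded with a relative gap of 1e-6, so results are
   deterministic and exact to tolerance. Ties among equal-cost optima are
   broken by the solver; tests therefore compare objective values, never
   the argmin.
2. `solve_enumeration()` is a depth-first exhaustive search with
   incremental feasibility pruning and direct cost evaluation at the
   leaves. It shares no code with the MILP assembly and serves as the
   ground-truth oracle on instances with a handful of patients.
3. `validate_schedule()` + `evaluate_cost()` check and price *any*
   schedule from the constraint definitions alone. The validator reports
   violations as data (equation number, indices, slack), sorted
   deterministically; the evaluator recomputes idle, overtime and
   shortage *tight* from the starts, so its total equals the optimization
   objective of the same assignment.

The heuristic (`construct_schedule()` + `improve_schedule()`) is
deliberately simple, and is the package's own design: patients ordered by
(deadline, decreasing duration) are placed greedily in the cheapest
feasible cell by full incremental cost; infectious patients prefer late
blocks and clean patients early blocks among cost ties, which keeps
room-days open; hill climbing then explores relocation, swap and
reassignment neighbourhoods, accepting only improving feasible moves
(best- or first-improvement), so cost is monotone over iterations and
every intermediate schedule is feasible. Restarts rebuild from randomized
construction orders. Incompleteness is handled lexicographically: an
unplaced patient dominates any cost difference (internal penalty 1e8), so
the search always prefers completing the schedule. No metaheuristic
machinery (tabu, annealing, genetic operators) is included on purpose —
the role of this module is a fast, auditable baseline whose solutions the
validator certifies, with quality measured against the exact solvers.

## The instance generator

`generator_spec()` describes an instance family; `generate_instance()` is
a deterministic function of the spec including its seed. The defaults
reproduce the *shape* of the small-scale class the package targets: 10
patients of whom the first 3 are infectious, 3 rooms, 3 surgeons, 6
blocks per day over a 5-day week. Numeric values — durations 1–3 blocks,
deadlines 2–5 days, ICU stays 0–3 days, regular room budgets 4–6 blocks,
and the cost and stochastic-parameter ranges — are the generator's own
documented choices of realistic magnitudes, not reproductions of any
particular hospital's data: assignment costs (10–50) dominate idle costs
(1–5), overtime (5–15) is dearer than idleness, and ICU shortage (20–60)
is dearer still, so every cost term is active at the optimum without one
term drowning the rest. Each field group draws from its own seeded
substream, so extending the generator with a new field never perturbs
previously generated values. Eligibility is Bernoulli with density 0.8,
resampled per patient until at least one room and one surgeon are
eligible (the model requires it). Feasibility of the *instance* is not
guaranteed — tight draws produce infeasible instances, which are
legitimate outputs and are reported as such by all three solvers.

What the generator does **not** emulate: correlated surgery durations,
weekday patterns in emergency arrivals, surgeon specialties beyond random
eligibility, or block release policies. Tests passing on generated
instances therefore certify the algebra and the solver contracts, not
calibration to any real theatre suite.

## The OLAS clinic model

The clinic model merges two appointment streams — overlapping-appointment
(OLAS) patients and doctor-only patients — at a single server. Appointment
times are ordered integers in `[0, T]` (minutes); arrivals are punctual by
default, optionally jittered by truncated normal noise, optionally thinned
by Bernoulli no-shows (off by default). Patients are served
first-come-first-served in realized arrival order, ties broken by
appointment time, then stream, then booking index.

Waiting and idling follow the single-server Lindley recursion on
inter-arrival gaps; overtime is the last completion's excess over `T`. Two
readings of the recursion's printed forms are possible in this model
class — appointment-anchored or arrival-anchored gaps — and the package
uses the standard arrival-anchored (Lindley) reading, under which the
idle-time and overtime expressions come out in their usual max-form and
the server-timeline identity

```
A(K) + W(K) + S(K) − A(1)  =  ΣS + ΣI
```

holds exactly (the busy period decomposes into service and idle time).
This identity is asserted to machine precision in the tests for every
replication, which is the strongest available internal check that the
three recursions are mutually consistent. The first patient's idle term is
defined as 0: time before the first arrival is not billed as idleness,
matching the recursion's `I(1) = 0` convention.

`estimate_template()` averages stream-wise waiting totals, idle total and
overtime over seeded replications; the objective is the cost-weighted sum
of the component means (exact by linearity, and asserted). Standard errors
come from replication variance, so deterministic service times give
exactly zero. `optimize_template()` evaluates candidates under common
random numbers — the same replication seeds for every template — so
comparisons are exact under identical noise. When the whole grid of
ordered integer templates fits into the evaluation budget
(`C(T+N,N)·C(T+M,M)` templates) it is enumerated exhaustively; otherwise
coordinate descent from evenly spaced appointments scans each appointment
time over its full feasible range between its neighbours, until a full
pass yields no improvement or the budget is spent. A budget of 1 returns
the evenly spaced template itself.

## Numerical choices

* Continuous comparisons in the validator use an absolute tolerance of
  1e-9; the MILP gap tolerance is 1e-6; negative service-time draws (not
  possible for the built-in families, kept for safety) are resampled.
* Degenerate inputs: empty schedules are valid *objects* (they simply
  violate coverage); zero-patient clinics simulate to an all-zero day;
  `icu_days = 0` opens no ICU window; a zero-variance "random" parameter
  collapses to its mean for every reliability level.
* Reproducibility: every stochastic routine takes an explicit seed;
  per-replication seeds are drawn once from the master seed and stored in
  the result.

## Problem sizes used by the test suite

The suite exercises the exact-vs-enumeration cross-check on 100 seeded
instances with ≤ 3 patients, 2 rooms, 2 surgeons, 4 blocks, 2 days — large
enough that every constraint family is active across the batch, small
enough that exhaustive enumeration is instant; mutation coverage on 50
corrupted optima; the reliability sweep `α ∈ {0.5, 0.8, 0.95, 0.99}` on 20
instances; 1 000 random templates against an independent event-timeline
simulator; and a 100 000-replication Monte-Carlo consistency check against
numeric quadrature. These sizes are the package's chosen balance between
coverage and a test run of a few minutes.

## Known limitations

* Only operating rooms and the ICU are modelled; pre-operative holding
  and post-anaesthesia care units are assumed unconstrained, and nurse
  rostering is out of scope.
* Emergency patients affect electives only through reserved capacity;
  there is no online re-optimization when an emergency actually arrives.
* The clinic model is a single-server merge; multi-doctor, multi-exam-room
  queueing networks are out of scope.
* Chance constraints are individual per room-day and per day, not joint:
  the reliability `α` applies to each constraint separately, so the
  probability that *all* constraints hold simultaneously is lower.
* The heuristic certifies feasibility, not optimality; its quality is
  only measured against the exact solvers on small instances.
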