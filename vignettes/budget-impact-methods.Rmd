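---
title: "Methods: a deterministic budget-impact model for pre-conception lifestyle interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a deterministic budget-impact model for pre-conception lifestyle interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preconbia)
```

## The model and its assumptions

`preconbia` implements a single-year, deterministic cohort model of the
budget impact of pre-conception lifestyle interventions in subfertile
couples undergoing assisted reproductive technology (ART: IVF, ICSI, IUI).
The model is intentionally simple arithmetic over a small set of published
parameters, which is what makes it auditable cell by cell:

1. **Baseline volumes.** The prevalent cohort of couples seeking ART is
   split over modalities by fixed shares; each treated couple undergoes a
   fixed mean number of cycles. There is no per-cycle success or attrition
   modelling: the mean-cycles parameters already absorb sequential
   behaviour.
2. **Outcome deltas.** Each intervention is described by effect-rate
   magnitudes — an uplift in spontaneous ongoing pregnancies, proportional
   reductions in treatments per modality, proportional reductions in
   pregnancy complications (IUGR, gestational diabetes, hypertensive
   complications, preterm birth). A rate is a proportion of the
   intervention's *target group* (whole cohort, obese subset, smoking men,
   or first-cycle women — recorded per effect row, because the combined
   program applies cohort-wide treatment effects but obese-subset
   complication effects), so every delta is `rate * group size`. Outcomes
   without published evidence carry no effect row at all: they are
   structural zeros, rendered as em-dashes, never as numeric zeros.
3. **Costing.** Per-couple benefit = (avoided treatment costs + avoided
   complication costs) / group size − program cost per couple; total
   saving = per-couple benefit × prevalent group size. A single year, a
   health-care payer perspective, no discounting, no indirect costs, and no
   ovulation-induction costs — all deliberate scope restrictions of the
   underlying analysis.

Key structural assumptions: modality shares are exhaustive over couples
receiving ART (they sum to one; couples conceiving spontaneously before
treatment are outside the cohort count), the prevalent group — not the
annual incident inflow, which is stored for reference but used in no
computation — is the operative denominator for all per-year figures, and
interventions are evaluated independently (no joint uptake modelling).

## Two costing modes and why both exist

The published analysis prints per-couple benefit triples and group sizes,
but not the unit costs behind them (those live in unavailable appendices).
The package therefore has two costing modes:

- **printed-benefit** (default, evidence-bearing): the per-couple triples
  are primitive inputs; the package's claim is the multiplication chain to
  totals and bounds, which the audit verifies against every printed cell.
- **computed-from-deltas** (research surface): per-couple benefits are
  derived from outcome deltas and unit costs. The shipped unit costs are
  assumption-tagged placeholders — plausible 2016 Dutch magnitudes (EUR
  3000 per IVF cycle, EUR 3500 per ICSI cycle, EUR 900 per IUI cycle, EUR
  3000/2000/8000/15,000 per avoided IUGR / gestational-diabetes /
  hypertensive / preterm case) with per-intervention program costs solved
  so the central computed benefit equals the central printed benefit. They
  let users explore cost sensitivity, but nothing in the package's
  validation rests on them; swapping in real unit costs is the intended
  use.

ART-only savings are taken from the published last column in
printed-benefit mode (they are not derivable from the per-couple chain) and
are the avoided-cycle cost term in computed mode.

## Scenario bounds and their propagation

Least/central/most-favorable values are stored as ordered triples on the
benefit scale. The published analysis gives bounds only for per-couple
benefits — not for the underlying rates — so the shipped fixture's
effect-rate triples are degenerate and the bounds propagate through the
printed-benefit mode. The scenario-ordering property (least ≤ central ≤
most for every saving) is a theorem when inputs are ordered, and is
property-tested on 1000 generated configurations. How the original
analysts constructed their bounds (which parameters moved) is not stated
in the source; the package treats the per-couple triples as primitive
rather than guessing.

The probabilistic sensitivity analysis extends the two-point bounds: each
intervention's per-couple benefit is drawn independently, uniformly on
`[least, most]` or triangularly with mode at the central value. No joint
distribution across interventions or parameters is published, so
independence is the declared default. One root seed spawns a deterministic
child stream per intervention (a fixed hash of the intervention id mixed
into a linear-congruential step), so draws are reproducible and adding an
intervention leaves the others' streams untouched. The caller's RNG state
is saved and restored.

## Display conventions and numerical choices

- Counts print to the nearest 100, money totals to a magnitude-dependent
  grain (whole millions from EUR 10 M, tenths of a million above EUR 1 M,
  finer below), ties rounding away from zero. All model arithmetic is
  unrounded; only rendering and the audit's printed-precision comparisons
  round. This is forced by the source tables themselves, whose percentages
  only reconcile with unrounded intermediates (e.g. 0.044 × 5400 = 237.6
  printed as −200).
- `display_round()` guards the ties-away-from-zero rule against binary
  floating-point droop with a relative epsilon; it is idempotent.
- Money is kept in plain doubles: every identity the package asserts
  (total = per-couple × group) is a single multiplication, so no
  accumulation error can arise that would warrant a decimal type.
- Configurations serialize to JSON at 17 significant digits, which
  round-trips IEEE doubles exactly; `load_config(save_config(x))` is the
  identity, and the constructor canonicalises all numerics to double so
  integer/double representation cannot break that identity.
- Validation collects *all* invariant violations before reporting, so a
  config file with three problems names three fields.

## The audit and the source's internal inconsistencies

`audit_printed()` compares every published cell — 103 of them — with its
recomputation and classifies each as `match` (within half the printed
resolution), `mismatch`, `flagged-inconsistency`, or `not-recomputable`.
Four cells are internally inconsistent in the source and are registered so
they flag rather than silently mismatch:

- the smoking-cessation percentages (−0.8%, −0.4%): the printed counts
  (−300, −100) are not 0.8%/0.4% of any constructible denominator. The
  fixture stores the counts as authoritative (rates 300/3200 and 100/3200
  of smoking men) and flags the percentages;
- the mindfulness per-couple benefit printed as EUR 36: EUR 360 is
  consistent with both the abstract and the printed EUR 4.9 M total over
  13,700 couples, so 360 is the operative value and the 36 cell is
  flagged;
- the LIFEstyle most-favorable ART-only bound of EUR 101 M, an order of
  magnitude above the row's own EUR 8.6 M overall bound. This is caught by
  a consistency rule — ART-only savings cannot exceed overall savings in
  the central and most-favorable scenarios, because the overall figure
  adds complication savings before subtracting program costs. The
  least-favorable scenario is exempt from the rule since the program-cost
  subtraction can legitimately invert the ordering there (and does, in the
  smoking row).

Per-cell printed resolutions are stored with the fixture rather than
derived from a global rule, because the source mixes precisions
(EUR 24 M next to EUR 101.2 M next to EUR 0.130 M); sub-million cells
printed with a trailing zero are treated as rounded at EUR 0.01 M, which
is the precision their own arithmetic implies (41 × 3200 = EUR 0.131 M
printed as EUR 0.130 M).

An audit mismatch that is *not* registered stays a `mismatch` and fails
the CLI `audit` subcommand with exit code 1 — corrupting any parameter
surfaces immediately.

## What the synthetic generator emulates — and what it does not

`generate_config(seed)` draws complete, valid parameter sets: simplex
modality shares, subgroups bounded by the cohort, ordered rate triples
capped so avoided cycles never exceed baseline cycles, non-negative costs,
and per-couple benefit triples derived by actually running the computed
costing mode (so generated "printed" benefits are self-consistent by
construction). Boundary cases appear with positive probability:
interventions with all-zero rates, degenerate triples, and program costs
exceeding gross savings. All cardinalities (interventions, modalities,
complication types) are parameters, so tests cannot silently hard-code the
fixture's shape.

The generator makes no attempt at realistic Dutch cost or prevalence
distributions — ranges are test scaffolding. Passing property tests on
generated configs therefore demonstrates structural correctness
(ordering, linearity, round-trips, audit self-consistency), not
calibration to any real health system; the only empirical claims the
package makes run through the shipped fixture and its audit.

## Problem sizes and defaults

The property suite runs the scenario-ordering theorem on 1000 generated
configurations (two interventions each) and the full-pipeline
never-raises battery on 25; PSA defaults to 10,000 draws per intervention,
with 100,000 used for the mean-convergence check (3 standard errors of the
closed-form uniform mean). These sizes give comfortable statistical margins
while keeping the whole suite in the minutes range on a single core.

## Known limitations

- Single-year horizon, direct medical costs only; no discounting, QALYs or
  ICERs, and no indirect savings (workforce return, child health), so the
  totals are conservative by construction.
- Effect rates are inputs, not estimated from trial microdata; the package
  deliberately contains no evidence synthesis.
- The combined program is parameterised by its own published rates rather
  than composed from its two components — simple addition over-counts the
  obese subset, as `compose_interventions()` demonstrates; that helper
  exists for exploration with an explicit overlap correction and carries
  no evidential weight.
- The incident target-group column of the source is stored but
  deliberately unused: its relationship to the prevalent groups is
  undefined in the source text.
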