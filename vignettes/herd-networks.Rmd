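---
title: "Herd dynamics and patron-client networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Herd dynamics and patron-client networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdnet)
```

## The model

`herdnet` simulates a population of nomadic pastoral households herding
privately owned animals on a communal pasture. Each household is an agent
whose only state is its herd size (its wealth), its alive flag, and its
position in a patron-client support network. The environment enters through
two variables: a system-wide **carrying capacity** (the total number of
animals the pasture can sustain, a proxy for available biomass) and a
per-household **disaster frequency** (the probability, each time step, of a
drought, storm, disease outbreak or management failure that destroys a
fixed fraction of the herd). One time step is loosely a year; the default
run length is 2,000 steps.

Every step, each household works through the same schedule:

1. **Growth.** Households are visited in a fresh uniformly random order.
   A visited household grows its herd by the growth rate (default 10%)
   *if and only if* the system-wide animal total is still below carrying
   capacity at its visiting moment. The total is re-read before every
   grant, so one wealthy household's growth can exhaust the remaining
   headroom and block everyone visited after it. The grant that reaches
   capacity may overshoot it; overshoot is not clipped.
2. **Disasters.** Independently, with probability `disaster_prob`, a
   household loses `disaster_intensity` (default 50%) of its herd. The
   uniform-intensity variant instead draws a fresh loss fraction from
   Uniform(0, 1) per event; an optional system-wide disaster (off by
   default) additionally strikes every household at once.
3. **Poverty resolution.** Again in a fresh random order, each household
   whose herd has fallen below the poverty threshold (60 animals) seeks
   support: if it already has a patron, the patron transfers it 60 animals;
   otherwise it picks a patron uniformly at random among living households
   whose herd exceeds the patron threshold (800 animals), receives the
   transfer, and a link is formed. If no eligible patron exists and its
   herd is below the death threshold (2 animals), the household dies and
   is removed permanently.
4. **Patron floor.** At the end of the step, every patron whose herd has
   dropped below the floor (500 animals) loses patron status and its
   client links dissolve; clients keep the animals they received.

The dependent variables, recorded per run, are the **Gini index** of herd
wealth over living households at the final step, the **largest network
size** (the maximum number of clients any patron held simultaneously), the
**duration** of that run-maximal network (the longest consecutive stretch
of steps during which it was the reigning largest network in the system),
and the **end population**.

The mechanism of interest is that inequality is generated by environmental
heterogeneity alone: disasters strike households differentially, and once
the pasture is full, growth becomes a zero-sum scramble in which large
herds can monopolise the headroom freed by other households' losses.
Patron-client networks then convert that inequality into hierarchy, and
their attainable size and stability rise with carrying capacity, because
the absolute thresholds (800 to accept clients, 500 to keep them, 60 per
transfer) become proportionally easier to sustain when herds are large.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `n_households` | 100 | households | population size |
| `initial_herd` | 60 | animals | starting herd per household |
| `growth_rate` | 0.10 | fraction/step | herd growth below capacity |
| `disaster_prob` | 0.10 | probability | per-household event rate per step |
| `disaster_intensity` | 0.50 | fraction | herd lost per event |
| `carrying_capacity` | 25,000 | animals | system-wide ceiling |
| `poverty_threshold` | 60 | animals | below: seek support |
| `patron_threshold` | 800 | animals | above: may accept clients |
| `patron_floor` | 500 | animals | below: patron status lost |
| `transfer_amount` | 60 | animals | per support event |
| `death_threshold` | 2 | animals | below, unsupported: death |
| `n_steps` | 2,000 | steps | run length |

The experiment batteries sweep `carrying_capacity` over 5,000-50,000 in
steps of 5,000 (50 to 500 animals per household if shared equally; recent
Mongolian herding averages sit near the middle of that range, which is why
25,000 is the single-run default) and `disaster_prob` over 5-20% (the
sensitivity-regression grid uses 1/5/10/15%, pairing ten capacities with
four frequencies). With 10% growth and 50% intensity, the expected loss
rate is `disaster_prob / 2` per step, so the 5-15% band keeps expected
growth positive, while 20% puts average losses equal to average growth
(1.1 × 0.9 = 0.99 per step) — the regime boundary at which accumulation,
and with it network formation, becomes impossible.

## Design choices

**Real-valued herds by default.** Herds are non-negative reals and no
rounding is applied; every threshold is a strict comparison (`< 60`,
`> 800`, `< 500`, `< 2`). A count-valued variant (`round_herds = TRUE`,
round-half-up after every growth and disaster update) is provided because
the two representations differ *qualitatively* in the decline regime:
with real herds, households in a collapsing economy scatter over
ever-smaller fractions and the (scale-invariant) Gini index drifts to its
`(n-1)/n` ceiling, whereas count-valued herds pile up at one animal and
measured inequality collapses toward zero. Above the decline boundary the
two variants are practically indistinguishable. Analyses of inequality
under sustained decline should therefore state which representation they
mean; the package tests pin both behaviours.

**Transfers are flat.** A poor client receives the fixed `transfer_amount`
(not a top-up to the poverty threshold), every step its herd is below the
threshold. A patron pays only if its own herd covers the transfer;
transfers conserve the animal total exactly. Mid-step depletion is
allowed: transfers may push a patron below the floor, and the status loss
is applied only at the end-of-step check.

**Role exclusivity.** By default a household is never patron and client at
once: clients are excluded from the candidate pool when a poor household
searches. The alternative (`client_patrons = TRUE`) lets any household
above the patron threshold accept clients, producing layered networks; in
practice it splits the client flow over more patrons and shrinks the
largest network by roughly ten percent at high capacity without changing
any qualitative trend. Households that currently hold clients never
request a patron under either setting, which rules out support cycles.

**Patron selection is uniform.** The model has no spatial structure, so
there is no basis for distance- or size-weighted choice among eligible
patrons.

**Largest-network bookkeeping.** A network is identified by its patron
*and* its formation step, so a patron that collapses and later rebuilds
counts as a new network. Ties for the reigning largest break by earliest
formation, then lowest household id. The run's duration metric is the
longest consecutive reign of the network that first attained the run's
maximum size.

**System-wide disasters are off by default.** The per-step schedule and
the expected-loss arithmetic (`disaster_prob × disaster_intensity`)
account for individual disasters only; the global variant is exposed as a
flag for exploration and leaves the Gini of the no-interaction baseline
untouched (it rescales every herd equally).

**Capacity shift.** `capacity_shift_run()` starts at a low capacity and
raises it to a high value at the end of any step in which some network
holds at least `trigger_size` clients, reverting when no such network
remains. Because client counts only grow until a patron collapses, the
elevated state in practice persists exactly as long as the triggering
network lives. The experiment asks whether a biomass increase arriving
while a burgeoning network is still small lets it grow far beyond what
the low-capacity environment could sustain.

## Determinism and the two engines

Every run is a pure function of its parameters and one integer seed. The
optimized engine is written in C++; a deliberately naive, loop-per-agent
reference engine is written in R. Both consume R's random stream under an
identical draw protocol — per step: one uniform per living household for
the growth order (the visiting order is the ordering of those draws), one
uniform per household for the disaster check (plus one per event under
uniform intensity, plus one for the global draw when enabled), one uniform
per household for the poverty-resolution order, and one uniform per patron
search with a non-empty candidate set — and use the same floating-point
expression order, so the two engines are bit-identical for any seed. The
test suite asserts this equivalence on randomized parameter sets across
all variants; it is the package's strongest guard against engine bugs.

Batch runners derive per-replicate seeds up front from one root seed, so a
batch is reproducible as a whole and each replicate can be regenerated in
isolation, independent of execution order.

Once the population is extinct, remaining steps are no-ops that consume no
random draws; the optimized engine exits the loop early, which makes
collapse-regime batches cheap. A run that ends with no living households
reports `NA` for the final Gini (the index is undefined on an empty or
all-zero wealth vector).

## What the simulator does and does not capture

All experiments are self-generated; there is no external data. The model
deliberately omits spatial structure and mobility (pasture patches,
distance between camps), violence and raiding, trade with sedentary
neighbours, demographic household dynamics (households are implicitly
multi-generational and never die of old age), benefits to patrons from
their clients (patronage is pure redistribution here, which shortens
network durations uniformly but does not affect sizes), and interactions
between rival networks. Passing tests therefore certify the internal
logic and the environmental-gradient findings of this abstract model, not
the behaviour of any particular historical herding economy.

Two empirical regularities of the model are worth flagging for users:

* **Low-capacity mortality.** At low capacities the early run phase is
  harsh: capacity binds within a few steps, poor households cannot regrow,
  and no patron exists until the first household crosses 800 animals
  (typically after step 40 at capacity 10,000), so the population loses
  10-25% of households before any support network exists, and rare
  multi-disaster streaks kill isolated households at *every* capacity.
  Consequently end populations fall below the starting count even in rich
  environments (99.8 of 100 on average at capacity 45,000, 10% risk), and
  capacity-shift runs launched from capacity 10,000 operate on a reduced
  surviving population, which caps how large their elevated networks can
  grow.
* **Regime boundary.** At 20% risk with 50% intensity, expected losses
  equal expected growth; populations then collapse to zero well before
  2,000 steps and only transient, small networks ever form.

## Problem sizes and numerical tolerances

The test suite and the results-reproduction script run the full factorial
batteries at 25-100 replicates per parameter combination (25 for the
4,000-cell regression design, 100 for the focal capacity sweeps), sizes
chosen to keep Monte-Carlo error on per-combination means a small fraction
of the effects of interest while keeping a complete run of the battery in
the minutes range on one core. Analytic checks (the expected herd
multiplier `growth × (1 − risk × intensity)` and the expected per-step
loss fraction) are asserted within three standard errors of their
Monte-Carlo estimates. Exact identities — transfer conservation, the
closed-form trajectory `initial × (1 + g)^t` without disasters, engine
equivalence — are asserted bitwise or at numerical round-off (1e-9 on
running totals).

## Limitations

The model is a thought tool, not a calibrated forecast: parameter values
are ethnographically motivated but not fitted, one "year" has no seasonal
structure, and wealth is one-dimensional. The duration metric tracks only
the run-maximal network, so secondary networks' lifetimes are not
reported (the per-step series and the reference engine's event log expose
them if needed). Gini values under sustained decline depend on the herd
representation, as discussed above.
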