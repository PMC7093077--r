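---
title: "Calibrating SBML kinetic models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating SBML kinetic models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmlfit)
```

This vignette explains the models, numerical methods and design choices
behind `sbmlfit`: how an SBML document becomes an ODE system, how that
system is integrated, how the calibration objective is defined, how the
optimizers search the parameter box, and what the repeated-fit
identifiability analysis does and does not establish.

## From SBML to an ODE system

A model document contributes species $y$, reactions with kinetic laws
$v_j(y, t)$ and a stoichiometry matrix $N$, giving

$$ \frac{dy}{dt} = N\,v(y, t) + \text{rate-rule contributions}. $$

Design choices that matter:

* **Amounts, not concentrations, are integrated.**  Stoichiometric
  bookkeeping is exact in amounts under constant compartment volume;
  kinetic laws still see concentrations (amount divided by compartment
  size) unless a species declares substance units, and trajectory
  output reports concentrations.  Rules on compartment sizes are
  rejected at compile time rather than mis-handled.
* **The state vector** holds non-constant, non-boundary species in
  document order, then rate-rule variables.  Boundary and constant
  species never receive reaction flux.
* **Assignment rules** are ordered once at compile time by topological
  sort (ties broken by document order, cycles are a compile error) and
  evaluated before every rate evaluation.
* **Reaction-local parameters** are name-mangled
  (`reactionId.paramId`) into one flat symbol table so evaluation needs
  a single context.
* **Kinetic laws are compiled to a stack bytecode** evaluated in C++.
  This is what makes large estimation studies feasible: one fitness
  evaluation costs roughly a millisecond for a six-species stiff
  model.  A recursive R evaluator (`eval_math`) covers everything else
  and doubles as a cross-check in the tests, which compare the compiled
  derivatives against an independent document-walking interpreter at
  random states.
* **Scope.**  SBML Level 2 (v1-5) and Level 3 (v1-2) core only.  Event
  delays, algebraic rules, constraints, fast reactions and conversion
  factors raise an "unsupported construct" error naming the construct;
  silently ignoring semantics a model relies on would corrupt results.

## Integration

The default solver is a 4-stage linearly implicit Rosenbrock method in
Kaps–Rentrop form with the GRK4T/Shampine coefficient set: order 4 with
an embedded order-3 error estimate, solving
$(I/(\gamma h) - J)\,g_i = \dots$ stage systems with a
forward-difference Jacobian.  Non-autonomous terms are handled by
augmenting the state with time itself (derivative 1), which makes the
autonomous tableau exact and avoids separate time-derivative
coefficients.

Numerical notes:

* **Stability.**  The scheme is strongly A-stable with
  $|R(\infty)| \approx 0.454$: stiff modes are damped by more than half
  per step at any step size, which is what stiff kinetic systems need
  in practice.  It is not strictly L-stable ($R(\infty) \ne 0$); the
  property tests assert boundedness of the stability function, a
  measured convergence order of at least 3, and that the stiff
  two-timescale benchmark finishes within the step budget where the
  explicit method does not.
* **Embedded weights.**  The order-3 companion weights were derived
  from the order conditions (the order-3 family for this tableau has
  one free direction); the reported error estimate tracks the embedded
  method's true local error within about 30 % on the linear test
  problem.
* **Step control.**  RMS error norm scaled by
  `abs_tol + rel_tol * |y|`; accept iff the norm is at most 1; next
  step `h * clamp(0.9 * norm^(-1/4), 0.2, 5)`.  Step-size underflow
  (below `1e-14` of the span) and exhausted step budgets are *failure
  statuses*, not exceptions, so optimizers can penalize them.
* **Output** is by cubic Hermite interpolation between accepted steps;
  the internal step is additionally capped at a tenth of the span so
  the interpolant honors the requested tolerances.  The user-facing
  "step size" is therefore purely an output grid.
* **Events**: persistent triggers, no delays, no priorities.  A
  false-to-true crossing is located by bisection on the interpolant to
  `1e-9` of the step; simultaneous events fire in document order; the
  integration restarts at the event time.  The
  `initial_trigger_value` flag gives the assumed trigger value before
  the start, so a trigger already true at $t_0$ fires immediately only
  when that flag is `FALSE`.
* **Tolerances** default to the estimation-study settings: absolute
  `1e-12`, relative `1e-6`.

## The calibration objective

The fitness of a parameter vector is a distance between the simulated
trajectory and the dataset.  The default is the **relative squared
error**: squared residuals divided by the experimental value, summed
over mapped columns and time points.  Normalizing by the data magnitude
makes species observed at very different concentration scales
contribute comparably.

The denominator needs an explicit zero policy, which is a design
decision of this package: when $|data| \le 10^{-10}$ the mean magnitude
of the column's non-zero values is used instead, and an all-zero column
falls back to absolute squared error.  Missing cells are skipped.
Simulated values at data times come from linear interpolation on the
output grid (the grid should be at least ten times finer than the
smallest data interval; the fitness path sidesteps the issue entirely
by requesting solver output exactly at the data times, where dense
output is accurate to the integration tolerances).  Failed simulations
score `Inf`, which the estimation layer converts to the finite sentinel
`1e300` so that candidate ordering never involves IEEE infinities.

## Optimizers

All five algorithms minimize over the box $[\min_i, \max_i]$ given by
the parameter specification, initialize inside the (possibly narrower)
initialization box, are fully reproducible from their seed, and record
a monotone best-so-far trace.

* **Differential evolution** (DE/rand/1/bin; default `F = 0.7`,
  `CR = 0.9`, population `min(10·dim, 100)`): mutation
  $v = a + F (b - c)$, binomial crossover with one forced component,
  greedy selection.  Out-of-box components are *reflected* back.
* **(μ,λ) evolution strategy** with global log-normal step-size
  self-adaptation ($\tau = 1/\sqrt{2n}$), steps expressed as fractions
  of box width, offspring clipped into the box.
* **Particle swarm** with inertia 0.729 and both acceleration
  coefficients 1.49445; velocities clamped to 20 % of the box width.
* **Hill climbing**: (1+1) Gaussian perturbation with 1/5-success step
  adaptation.
* **Simulated annealing**: same proposal, Metropolis acceptance with a
  geometric schedule ($T_0 \alpha^{k/100}$, $\alpha = 0.95$).

Box handling differs deliberately (DE reflects, ES/PSO clip): both are
legitimate, each is documented, and the corner-optimum test pins the
reflection behavior.  A fully degenerate initialization box pins DE
forever (difference vectors vanish), which is why the
"initialization-box versus search-box" behavior is asserted with DE for
generation zero and with the ES for later generations.

## The synthetic estimation study

The study generator emulates the *architecture* of a published
two-compartment drug-biotransformation network without bundling it: a
medium (1 mL) and a cell (0.01 mL) compartment; per metabolite a
first-order import and export (rate constants in mL/min, scaled by an
unbound fraction) and a Michaelis–Menten conversion of each
intracellular metabolite into the next; a 100 pmol/mL dose of the first
metabolite in the medium; 12 log-spaced sampling times over 240 min.

Parameter magnitudes are drawn log-uniformly (the search boxes span
five orders of magnitude, so uniform draws would concentrate near the
upper bound) from the *upper decades* of the search boxes: transport
constants in [0.01, 0.1] mL/min, unbound fractions in [0.25, 1], Vmax
in [5, 100] pmol/min, Km in [2, 20] pmol/mL.  This choice is physical,
made once: with the small cell volume it yields fast intracellular
equilibration against slow medium depletion (a mildly stiff system,
which is the regime the Rosenbrock solver exists for) and time
constants that fit inside the observation span, so the data actually
carry information about every drawn parameter.  Draws from the full
boxes would regularly produce dynamics too slow to observe, turning
parameter recovery into a lottery independent of optimizer quality.

The search boxes handed to the optimizer still follow the published
table's scales — transport [1e-6, 0.1], fractions [1e-6, 1], Vmax
[1e-6, 100] — with initialization interval equal to search interval.

The fixture deletes five parameters (import/export of the first
metabolite, the first two Vmax values, import of the second metabolite)
and the acceptance study refits them 20 times with DE (population 50,
30,000 evaluations), retains the best half, and requires every
normalized mean in [0.9, 1.1] with CV ≤ 0.2.

The **negative control** is a one-pair variant in which the unbound
fraction multiplies only the import flux, so the data constrain the
product $k_{imp} \cdot fu$ but neither factor: retained fits scatter
along the product ridge (CV > 0.2 for each factor) while the tracked
product has CV < 0.1.

What a green study does *not* establish: the generator is noise-free by
default and observes every species.  Real data have measurement error,
partial observability, and model misspecification; the study validates
the estimation machinery, not the practical identifiability of any
real model.

## Identifiability analysis

Repeated estimation is a pragmatic identifiability heuristic: run the
same problem $n$ times from independent random initializations, sort by
final fitness, keep the best `ceiling(fraction * n)` (ties broken by
seed for determinism), divide each retained estimate by its reference
value, and report mean/sd/CV per parameter.  The identifiable flag uses
a CV threshold of 0.2 — the literature says only "low" versus "very
high" spread, so the threshold is an explicit, configurable choice that
is always reported alongside the numbers, never silently applied.  This
is not profile likelihood and carries no statistical guarantee; it
answers "did independent optimizer runs agree?", which is exactly the
question cluster practitioners ask first.

## Known limitations

* SBML packages (comp, fbc, layout), delays, algebraic rules,
  constraints, fast reactions, conversion factors and unit conversion
  beyond amount/concentration handling are out of scope and rejected
  loudly.
* Event semantics are the persistent, no-priority subset; firing order
  of simultaneous events is document order.
* No covariance matrix adaptation, niching, or gradient refinement in
  the optimizer set; no BDF multistep solver or sensitivity
  integration.
* The compiled-system external pointer is rebuilt transparently after
  serialization, but compiled evaluators themselves are not serialized.
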