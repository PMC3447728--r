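---
title: "Models and methods behind fluxdraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fluxdraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxdraft)
```

This vignette explains the science and the numerical machinery inside
`fluxdraft`: what is being modelled, which choices were genuinely open and
how they were settled, and what the packaged synthetic data can and cannot
tell you about real organisms.

## Constraint-based flux analysis

A stoichiometric model is a signed incidence structure: each reaction
carries a map from metabolite ids to coefficients (negative = consumed,
positive = produced), and the stoichiometric matrix $S$ collects these as
columns over the *internal* metabolites. At metabolic steady state no
internal pool accumulates, so a flux vector $v$ (mmol per gram dry cell
weight per hour) must satisfy $S v = 0$ within bounds $lb \le v \le ub$.
Flux balance analysis (FBA) selects among the admissible fluxes by linear
programming:

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub.$$

Key conventions, all of which were open design decisions:

* **External species** (boundary metabolites) are represented explicitly
  with `external = TRUE` rather than as implicit sinks, so SBML export can
  mark `boundaryCondition="true"`; their rows are simply omitted from $S$.
  Exchange reactions are one-sided: an inflow `∅ → M` whose flux is the
  uptake rate, an outflow `M → ∅` whose flux is the secretion rate. An
  inflow may target any internal metabolite, so a lumped transport +
  phosphorylation step such as "glucose → G6P" is expressed directly.
* **Reversibility lives in the bounds**: a reversible reaction defaults to
  $[-M, M]$ and an irreversible one to $[0, M]$ with $M = 1000$
  mmol/g DCW/h, the conventional "effectively unbounded" cap ($M$ is
  configurable per reaction). The solver requires finite bounds, so $M$ is
  also what "unbounded" means operationally.
* **Row/column order is sorted lexicographically**, making matrices, SBML
  documents and SVG renderings reproducible and diffable.
* **Alternate optima.** FBA optima are unique in objective value but not in
  the flux vector; at a degenerate vertex many flux patterns tie. All
  quantitative claims in the package (tests, acceptance script) therefore
  compare objective values, or re-optimize a secondary objective with the
  primary fixed — never raw witness vectors.

### The LP engine

No linear-programming library ships with this R stack, so the package
carries its own solver (`lp_solve()`): a two-phase primal simplex for
bounded variables. Phase 1 drives signed artificial variables to zero
(feasibility is declared when their sum falls below $10^{-6}$ relative to
the right-hand side scale); phase 2 optimizes the real objective with the
artificials pinned at zero. The basis inverse is maintained explicitly with
eta-style rank-one updates and refactorized every 200 pivots; pricing is
Dantzig's rule with a Bland's-rule fallback after $2(n+m)$ consecutive
degenerate steps, which excludes cycling. Tolerances: $10^{-9}$ for pricing
and ratio tests, $10^{-6}$ for steady-state residuals in tests. Every
optimum the test suite reports is cross-checked against an independently
formulated oracle (`boot::simplex` on the shifted problem
$x = v - lb \ge 0$ with explicit upper-bound rows) to $10^{-6}$ relative.

## Drafting from pathway files

KGML pathway documents name the reactions an organism's annotation supports
and their directionality, but carry no stoichiometric coefficients and omit
cofactors. A LIGAND-style reaction table supplies the equations. The
drafting rules are:

* **Stoichiometry authority is the equation, never the KGML
  substrate/product lists** — the lists are used only for an orientation
  check. When they disagree with the equation's left side, the equation's
  orientation wins and a warning is logged, because silently flipping
  stoichiometry is worse than a logged disagreement.
* **Reversibility comes from the KGML `type` attribute**; a reaction marked
  reversible on one map and irreversible on another is kept reversible
  (least restrictive — reconstruction can always tighten later). A missing
  attribute defaults to reversible with a warning.
* **Equations the grammar cannot commit to are excluded, not
  approximated**: non-numeric coefficients (`n`, `(n+1)` repeat units),
  glycan `G#####` terms, and one-sided equations yield `parse_ok = FALSE`
  and a reason in the draft report. A wrong stoichiometry is a silent
  corruption of every downstream LP; a reported gap is a to-do item. For
  the same reason, mass-balance checking reports `"unchecked"` for any
  reaction touching a metabolite whose formula has repeat units rather than
  guessing a monomer count.
* Duplicate reaction ids across maps enter the draft once; duplicate
  records in the table keep the first with a warning.

## Reconstruction operations

All reconstruction verbs are pure: they return a new model and never mutate
their input, so callers can diff before/after. Knockouts pin bounds to
$[0,0]$ but keep the reaction — reports still show it and the knockout can
be reversed. Direction edits renormalize so stored stoichiometry always
reads left-to-right forward (setting "backward" negates the coefficients
and closes the reverse direction). Edit scripts are ordered and atomic: the
first failing directive aborts with its position and the input model is
returned unchanged.

The biomass reaction consumes each building block in mmol per g DCW, plus
the growth-associated maintenance (GAM) couple
$\mathrm{GAM}\cdot(\mathrm{ATP} + \mathrm{H_2O} \to \mathrm{ADP} +
\mathrm{P_i})$, and its flux is therefore the specific growth rate in 1/h.
Non-growth-associated maintenance (NGAM) is a separate reaction with
$lb = ub = \mathrm{NGAM}$ mmol ATP/g DCW/h. Keeping *all* biomass-coupled
ATP in the GAM term of the biomass reaction (anabolic ATP belongs in the
building-block syntheses) is what lets `fit_gam()` vary GAM on models loaded
from SBML: it rewrites exactly the four energy-couple coefficients.

`fit_gam()` exploits that growth is monotone non-increasing in GAM (more
ATP per gram leaves less substrate for mass) and bisects the bracket
(default $[0, 1000]$ mmol ATP/g DCW, $\le 60$ iterations) until predicted
growth matches the measurement within `tolerance` (default $10^{-4}$ 1/h).
The substrate uptake must be fixed beforehand — the fitted GAM is only
meaningful relative to that uptake, so the uptake is an explicit parameter
of the analysis, not a hidden default.

`production_envelope()` computes the unconstrained growth maximum
$\mu^\*$, then maximizes the target flux at each point of a uniform growth
grid over $[0, \mu^\*]$. The curve is concave (it is the value function of
an LP over a parameterized feasible set). Note that the extreme point
$\mu = \mu^\*$ is usually degenerate — at the exact growth optimum every
spare electron and phosphate bond is already committed, so the attainable
product flux can collapse there; trade-off readouts should compare interior
grid points.

## Dynamic FBA by static optimization

The time course $[t_0, t_{end}]$ is split into intervals of width `dt`.
Per interval: exchange bounds are resolved at the interval start
(piecewise-constant tables are **left-closed** step functions — a
breakpoint's value holds until the next breakpoint; Monod uptakes use
$ub = v_{max} S_k/(K_s + S_k)$ with the current tracked concentration),
one FBA is solved, and pools are integrated:

$$X_{k+1} = X_k e^{\mu_k \Delta t}, \qquad
S_{k+1} = \max\!\big(0,\; S_k - v_{uptake,k}\, \bar X_k\, \Delta t\big),$$

with $\bar X_k = (X_{k+1}-X_k)/(\mu_k \Delta t)$ the exact
interval-average biomass when $\mu_k > 0$. The exponential update is exact
for constant $\mu$ (first-order overall on Monod problems, verified against
a stiff ODE integration in the tests); substrate clamping plus per-interval
bound recomputation prevents negative concentrations. An infeasible
interval terminates the simulation gracefully with the partial trajectory
and a reason — late-time infeasibility (maintenance unpayable after
substrate exhaustion) is a biologically meaningful endpoint, not an error.
Units are chosen so $dS/dt = -vX$ is dimensionally consistent: biomass in
g DCW/L, concentrations in mmol/L, fluxes in mmol/g DCW/h.

## SBML and SVG

The writer emits SBML Level 3 with flux-balance-constraints (fbc v2)
annotations: species with `boundaryCondition`, bounds as shared flux-bound
parameters, the objective as an fbc objective, and — because 2012-era
models are still in circulation — the reader additionally accepts legacy
Level 2 documents with `LOWER_BOUND` / `UPPER_BOUND` /
`OBJECTIVE_COEFFICIENT` / `FLUX_VALUE` kinetic-law parameters. Bounds are
searched in that order (fbc attributes, kinetic-law parameters, notes);
reactions with no bound information get reversibility defaults with a
warning. Identifiers that are not valid SBML SIds are sanitized reversibly:
the original id travels in the element's notes and is restored on read.
Reaction kinds and flux values travel the same way. Numbers are printed
with enough digits to survive a read-back exactly, so write→read is the
identity on every model the test suite constructs. Exported documents are
well-formed XML by construction (the writer re-parses its own output);
full schema validation is out of scope offline.

The SVG renderer draws the bipartite graph — metabolites on an outer ring,
reaction nodes on an inner ring, both in sorted-id order — which makes the
layout a pure function of the model: same model, byte-identical file. Edge
width scales with $|v|$ and zero-flux edges are dashed when a flux
distribution is supplied; labels are suppressed above 2000 nodes.

## Synthetic data: what it emulates and what it does not

Two generators make the package testable offline.

`generate_fixture_organism()` emits KGML documents and a LIGAND-style table
for a fully synthetic organism together with the exact model drafting must
produce. It emulates the *structural* hazards of real drafting — reactions
shared by several maps (deduplication), records with polymer equations
(exclusion), orphaned dead-end metabolites, an always-present backbone path
so exchanges make the draft solvable — under a fixed seed with
byte-identical output. It does not emulate KGML map graphics, ortholog
entries, or the scale of a real genome; passing its round-trip says the
parsers and assembler are faithful, not that any real annotation is.

`x514_surrogate()` is a synthetic medium-scale model of a
thermophilic, ethanol-producing anaerobe, generated in code and pinned to
the canonical draft dimensions (196 metabolites; 229 reactions: 162
intracellular, 19 exchanges, 39 gap-fills, 9 biomass-related). Its core is
textbook anaerobic fermentation: glycolysis yields 2 ATP and 2 NADH per
glucose, pyruvate oxidation yields acetyl-CoA plus NADH, and acetyl-CoA
either buys a third and fourth ATP via acetate kinase or sinks electrons
into ethanol (2 NADH each), with hydrogenases venting surplus reductant as
H₂. Substrate-level phosphorylation is deliberately restricted to
glycolysis and acetate kinase — the lumped oxidative TCA branch carries no
ADP phosphorylation — because that competition between acetate (ATP) and
ethanol (electron sink) is precisely what creates the growth-versus-ethanol
trade-off and the response to acetate restriction that the analysis
functions exist to expose. Eight anabolic chains drain central precursors
(consuming ATP and NADPH at a fixed cadence) into biomass building blocks;
39 gap-fill reactions — a Re-type citrate synthase and 38
metabolite-exchange drains (UTP first, mirroring the standard trick of
draining a metabolite whose consuming pathway is out of scope) — keep the
network free of dead ends. The default GAM is 150 mmol ATP/g DCW, a typical
thermophile-scale prior; glucose uptake is capped at 10 mmol/g DCW/h until
an analysis fixes it.

The surrogate's calibration conditions (glucose uptake 3.92 mmol/g DCW/h,
NGAM 7.6 mmol ATP/g DCW/h, target growth 0.042 1/h) are the standard
chemostat-style operating point for this kind of organism, and under them
the fitted GAM, envelope readouts and acetate-restriction improvement are
the surrogate's own regenerated gold values, computed at run time by
`scripts/acceptance.R` and the acceptance tests — they are properties of
this synthetic network, not measurements of any real strain. In particular,
with purely fermentative ATP yields (at most 4 ATP per glucose), growth at
that operating point is ATP-limited, which is what makes GAM fitting
well-posed (growth strictly decreasing in GAM) and the ethanol trade-off
genuine.

## Problem sizes and runtimes

The test suite runs entirely on models built in code: LP cross-checks on
~60 random programs of up to 8 variables, monotonicity properties on 100
random networks of 6–10 reactions, drafting round-trips over 20 seeds of a
40–60-reaction synthetic organism, and the 229-reaction surrogate for the
case-study procedures (about 35 LP solves for a GAM fit at tolerance
$10^{-4}$). A dynamic-FBA accuracy check integrates 1000 intervals at
`dt = 0.01` h over a 10-hour Monod batch. These sizes keep the whole suite
around a minute while still exercising every code path at the scale the
package targets (medium-scale models of a few hundred reactions).

## Known limitations

* No compound charging, charge balance, reaction compartments, or
  gene–protein–reaction associations; no automated gap-finding — gaps are
  surfaced (dead-end lists, draft reports) for the user to fill manually.
* No flux variability analysis or MILP strain design; the solver is a
  dense simplex adequate for medium-scale models, not a sparse
  genome-scale workhorse.
* Thermodynamic direction prediction is out of scope; reversibility is
  whatever the pathway files (or the user) say.
* Mass-balance checking requires parsable elemental formulas and abstains
  otherwise.
* The dFBA integrator is fixed-step SOA; there is no stiffness control
  beyond choosing `dt`.
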