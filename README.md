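# fluxdraft

Draft, reconstruct and analyse constraint-based metabolic models of
microbes — offline, from pathway files to flux predictions.

`fluxdraft` is for microbiologists and systems biologists who want to go
from a genome annotation to testable flux predictions without hand-building
a stoichiometric model in a spreadsheet. It covers the full small-lab
workflow:

1. **Draft** a stoichiometric network from KGML pathway files (the XML
   encoding of KEGG pathway maps) cross-referenced with a KEGG-LIGAND-style
   reaction table that supplies the actual equation of every reaction.
2. **Reconstruct** the draft with the edits every draft needs before it can
   grow: inflow/outflow exchange reactions, a biomass reaction built from a
   measured composition, maintenance energy, heterologous or gap-filling
   reactions, knockouts, and direction/participant changes — interactively
   or through an ordered, atomic YAML edit script.
3. **Analyse** the result with flux balance analysis (FBA),
   growth-associated-maintenance (GAM) fitting against a measured growth
   rate, growth-versus-product trade-off envelopes, and dynamic FBA by the
   static optimization approach (SOA) for batch-culture time courses.
4. **Exchange** models as SBML (Level 3 + flux-balance constraints on
   write; 2012-era Level 2 bound encodings on read) and render networks to
   SVG.

## The model

A metabolic network with stoichiometric matrix *S* (rows internal
metabolites, columns reactions) is assumed to operate at steady state, so a
flux vector *v* (mmol/g DCW/h) must satisfy

```
maximize  c' v     subject to   S v = 0,   lb <= v <= ub
```

a linear program whose objective *c* is usually the biomass pseudo-reaction
(its flux is the specific growth rate, 1/h) but can be any linear
combination of fluxes. Measured rates enter as bound constraints
(`lb = ub = measured value`). The biomass reaction consumes building blocks
in measured proportions (mmol per g DCW) plus the GAM ATP cost; a separate
maintenance reaction hydrolyses NGAM mmol ATP/g DCW/h unconditionally.
Dynamic FBA splits a fermentation into intervals, solves one steady-state
FBA per interval with time-dependent exchange bounds (tables or Monod
kinetics `ub = vmax·S/(Ks+S)`), and integrates biomass
(`X_{k+1} = X_k e^{mu_k dt}`) and substrate pools between intervals.

All linear programs are solved by the package's own bounded-variable
two-phase simplex (`lp_solve()`); an independently formulated oracle
(`boot::simplex`) cross-checks every optimum in the test suite.

## Worked example

The packaged TOY model is a 10-metabolite central-carbon network
(glycolysis, pentose phosphate pathway, lumped TCA, anaplerosis) with a
glucose inflow fixed at 11.0 and an acetate outflow fixed at 6.4
mmol/g DCW/h:

```r
library(fluxdraft)
toy <- toy_model()
toy
#> <metabolic_model> TOY [toy]
#>   metabolites: 10 (10 internal)
#>   reactions:   16
#>     biomass: 1, inflow: 1, intracellular: 13, outflow: 1
#>   objective:   maximize +1 BIOMASS

solve_fba(toy)
#> <flux_distribution> model TOY: optimal, maximized objective = 1.095198
```

The optimum 1.0952 is the maximal specific growth rate (1/h) compatible
with the two fixed exchange rates; `tidy(sol, model = toy)` returns the
per-reaction flux table and `render_network_svg(toy, sol, "toy.svg")` draws
the network with edge widths proportional to flux.

The same workflow scales to the packaged medium-scale surrogate of an
ethanol-producing thermophilic anaerobe (196 metabolites, 229 reactions,
generated in code — see the methods vignette). Calibrating its GAM against
a measured growth rate of 0.042 1/h at a glucose uptake of 3.92 mmol/g
DCW/h and NGAM 7.6:

```r
x <- x514_surrogate() |>
  set_maintenance(7.6) |>
  fix_flux("glc_in", 3.92)
fit_gam(x, target_growth = 0.042)
#> <gam_fit> GAM = 107.422 mmol ATP/g DCW  (growth 0.04192 vs target 0.042 1/h)
```

`production_envelope(x, "etoh_out")` then traces how much ethanol the
network can secrete at each growth rate, and
`constrain_and_resolve(x, list(ac_out = c(0, 0.6)))` asks what happens when
acetate secretion is choked — the classic strain-design questions.

A command-line front end (`inst/cli/fluxdraft.R`) exposes the pipeline as
`fixture`, `draft`, `edit`, `fba`, `envelope`, `fitgam`, `dfba` and
`render` subcommands for shell use.

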