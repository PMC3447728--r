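#' The canonical TOY central-carbon model
#'
#' A small didactic network covering glycolysis, the pentose phosphate
#' pathway, a lumped TCA cycle and the anaplerotic node: 10 internal
#' metabolites and, in the reconstructed form, 16 reactions (13 intracellular
#' steps, a lumped biomass drain, a glucose inflow and an acetate outflow).
#' Glucose is the carbon substrate (the inflow lumps transport and
#' phosphorylation into "glucose -> G6P") and acetate the extracellular
#' product (outflow "AcCoA -> acetate"). Carbon dioxide and cofactors are
#' deliberately not tracked — the model exists to exercise drafting,
#' reconstruction and FBA end to end, not to be biologically complete.
#'
#' The biomass drain consumes the ten canonical precursors in conventional
#' proportions (mmol per g DCW), so its flux is the specific growth rate in
#' 1/h.
#'
#' @param reconstructed If `TRUE` (default) the model includes the glucose
#'   inflow fixed at `glucose_uptake`, the acetate outflow fixed at
#'   `acetate_outflow`, and a maximize-biomass objective — ready for FBA. If
#'   `FALSE`, only the intracellular network plus biomass drain is returned
#'   (the starting point of the reconstruction walkthrough).
#' @param glucose_uptake Fixed glucose uptake, mmol/g DCW/h.
#' @param acetate_outflow Fixed acetate secretion, mmol/g DCW/h.
#' @return A `metabolic_model`.
#' @export
#' @examples
#' toy <- toy_model()
#' sol <- solve_fba(toy)
#' glance(sol)
toy_model <- function(reconstructed = TRUE, glucose_uptake = 11.0,
                      acetate_outflow = 6.4) {
  mets <- tibble(
    id = c("G6P", "F6P", "GAP", "PEP", "PYR",
           "ACCOA", "OAA", "AKG", "R5P", "E4P"),
    name = c("glucose 6-phosphate", "fructose 6-phosphate",
             "glyceraldehyde 3-phosphate", "phosphoenolpyruvate",
             "pyruvate", "acetyl-CoA", "oxaloacetate",
             "2-oxoglutarate", "ribose 5-phosphate",
             "erythrose 4-phosphate"),
    formula = NA_character_,
    external = FALSE
  )
  rx <- function(id, name, s, rev = FALSE, kind = "intracellular") {
    tibble(id = id, name = name, stoichiometry = list(s), reversible = rev,
           lower_bound = if (rev) -FD_BIG else 0, upper_bound = FD_BIG,
           kind = kind, ec_numbers = list(character()))
  }
  # classic precursor demands, mmol per g DCW
  biomass <- c(G6P = -0.205, F6P = -0.071, R5P = -0.898, E4P = -0.361,
               GAP = -0.129, PEP = -0.519, PYR = -2.833, ACCOA = -3.748,
               OAA = -1.787, AKG = -1.079)
  rxns <- bind_rows(
    rx("pgi",  "glucose-6-phosphate isomerase", c(G6P = -1, F6P = 1), rev = TRUE),
    rx("pfk",  "phosphofructokinase + aldolase (lumped)", c(F6P = -1, GAP = 2)),
    rx("gap_pep", "lower glycolysis to PEP (lumped)", c(GAP = -1, PEP = 1)),
    rx("pyk",  "pyruvate kinase", c(PEP = -1, PYR = 1)),
    rx("pdh",  "pyruvate dehydrogenase", c(PYR = -1, ACCOA = 1)),
    rx("cs",   "citrate synthase to 2-oxoglutarate (lumped)",
       c(ACCOA = -1, OAA = -1, AKG = 1)),
    rx("tca",  "oxidative TCA return (lumped)", c(AKG = -1, OAA = 1)),
    rx("ppc",  "PEP carboxylase (anaplerotic)", c(PEP = -1, OAA = 1)),
    rx("zwf",  "oxidative pentose phosphate (lumped)", c(G6P = -1, R5P = 1)),
    rx("tkt1", "transketolase I (lumped)", c(R5P = -2, F6P = 1, E4P = 1)),
    rx("tkt2", "transketolase II (lumped)", c(R5P = -1, E4P = -1, F6P = 1, GAP = 1)),
    rx("fbp",  "fructose bisphosphatase (gluconeogenic)", c(GAP = -2, F6P = 1)),
    rx("mae",  "malic enzyme (lumped decarboxylating)", c(OAA = -1, PYR = 1)),
    rx("BIOMASS", "lumped biomass production", biomass, kind = "biomass")
  )
  m <- metabolic_model("TOY", organism = "toy",
                       metabolites = mets, reactions = rxns)
  if (!reconstructed) return(m)
  m |>
    add_inflow("G6P", "glc_in", fixed = glucose_uptake,
               name = "glucose uptake (glucose -> G6P)") |>
    add_outflow("ACCOA", "ac_out", fixed = acetate_outflow,
                name = "acetate secretion (AcCoA -> acetate)") |>
    set_objective("BIOMASS", "maximize")
}
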