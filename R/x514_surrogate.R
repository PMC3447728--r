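#' Synthetic X514-like medium-scale fermentation model
#'
#' A fully synthetic stand-in for a medium-scale draft model of a
#' thermophilic, ethanol-producing anaerobe (a *Thermoanaerobacter*-style
#' metabolism): glycolysis with a PTS and a non-phosphorylating GAPN branch,
#' pentose phosphate and Entner-Doudoroff lumps, a split (reductive +
#' oxidative) TCA with a Re-type citrate synthase carried as a gap-fill,
#' fermentative branches to acetate (ATP-yielding), ethanol (NADH sink),
#' lactate, succinate and hydrogen, ammonia assimilation, eight anabolic
#' chains feeding biomass building blocks, and metabolite-exchange gap
#' fills (including a UTP exchange) that drain pathway byproducts whose
#' consuming pathways are outside the model's scope.
#'
#' The model is generated in code — it is a synthetic surrogate, not a
#' published reconstruction — and is sized to the canonical medium-scale
#' draft dimensions: 196 metabolites and 229 reactions, of which 162 are
#' intracellular, 19 inflow/outflow exchanges, 39 gap-fills and 9 biomass
#' building-block syntheses plus biomass production. Growth is ATP-limited
#' under glucose-capped anaerobic fermentation, so fitting the
#' growth-associated maintenance ([fit_gam()]) and tracing
#' growth-versus-ethanol envelopes ([production_envelope()]) behave the way
#' they do on real draft reconstructions.
#'
#' @param gam Growth-associated maintenance embedded in the biomass
#'   reaction, mmol ATP/g DCW.
#' @param glucose_upper Upper bound of the glucose inflow, mmol/g DCW/h.
#' @return A validated `metabolic_model` with a maximize-biomass objective
#'   (no NGAM reaction; add one with [set_maintenance()]).
#' @export
x514_surrogate <- function(gam = 150, glucose_upper = 10) {
  GLC <- "C00031"; G6P <- "C00668"; F6P <- "C00085"; FDP <- "C00354"
  GAP <- "C00118"; PEP <- "C00074"; PYR <- "C00022"; ACA <- "C00024"
  ACE <- "C00033"; ETH <- "C00469"; LAC <- "C00186"; R5P <- "C00117"
  E4P <- "C00279"; OAA <- "C00036"; AKG <- "C00026"; SUC <- "C00042"
  MAL <- "C00149"; FUM <- "C00122"; GLU <- "C00025"; GLN <- "C00064"
  ASP <- "C00049"; ALA <- "C00041"
  ATP <- "C00002"; ADP <- "C00008"; PI <- "C00009"; H2O <- "C00001"
  NAD <- "C00003"; NADH <- "C00004"; NADPH <- "C00005"; NADP <- "C00006"
  CO2 <- "C00011"; H2 <- "C00282"; NH3 <- "C00014"; UTP <- "C00075"

  rxs <- list()
  rx <- function(id, name, s, rev = FALSE, kind = "intracellular",
                 lb = NULL, ub = FD_BIG) {
    rxs[[length(rxs) + 1]] <<- tibble(
      id = id, name = name, stoichiometry = list(s), reversible = rev,
      lower_bound = lb %||% if (rev) -FD_BIG else 0, upper_bound = ub,
      kind = kind, ec_numbers = list(character()))
  }
  S <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }

  # --- central carbon core (45 intracellular reactions, 33 metabolites) ---
  rx("HEX1", "hexokinase", S(`C00031` = -1, `C00002` = -1, `C00668` = 1, `C00008` = 1))
  rx("PTS", "phosphotransferase glucose uptake",
     S(`C00031` = -1, `C00074` = -1, `C00668` = 1, `C00022` = 1))
  rx("PGI", "glucose-6-phosphate isomerase", S(`C00668` = -1, `C00085` = 1), rev = TRUE)
  rx("PFK", "phosphofructokinase", S(`C00085` = -1, `C00002` = -1, `C00354` = 1, `C00008` = 1))
  rx("FBA", "aldolase + triose isomerase (lumped)", S(`C00354` = -1, `C00118` = 2), rev = TRUE)
  rx("FBP", "fructose bisphosphatase", S(`C00354` = -1, `C00001` = -1, `C00085` = 1, `C00009` = 1))
  rx("GAPD", "lower glycolysis to PEP (phosphorylating, lumped)",
     S(`C00118` = -1, `C00003` = -1, `C00008` = -1, `C00009` = -1,
       `C00074` = 1, `C00004` = 1, `C00002` = 1, `C00001` = 1))
  rx("GAPN", "non-phosphorylating lower glycolysis (lumped)",
     S(`C00118` = -1, `C00006` = -1, `C00001` = -1, `C00074` = 1, `C00005` = 1))
  rx("PYK", "pyruvate kinase", S(`C00074` = -1, `C00008` = -1, `C00022` = 1, `C00002` = 1))
  rx("PPS", "PEP synthetase", S(`C00022` = -1, `C00002` = -1, `C00001` = -1,
                                `C00074` = 1, `C00008` = 1, `C00009` = 1))
  rx("PFOR", "pyruvate:ferredoxin oxidoreductase (as NADH, lumped)",
     S(`C00022` = -1, `C00003` = -1, `C00024` = 1, `C00011` = 1, `C00004` = 1))
  rx("PTAACK", "phosphotransacetylase + acetate kinase (lumped)",
     S(`C00024` = -1, `C00008` = -1, `C00009` = -1, `C00033` = 1, `C00002` = 1))
  rx("ACS", "acetyl-CoA synthetase",
     S(`C00033` = -1, `C00002` = -2, `C00024` = 1, `C00008` = 2, `C00009` = 2))
  rx("ADHE", "aldehyde/alcohol dehydrogenase (NADH, lumped)",
     S(`C00024` = -1, `C00004` = -2, `C00469` = 1, `C00003` = 2))
  rx("ADHP", "aldehyde/alcohol dehydrogenase (NADPH, lumped)",
     S(`C00024` = -1, `C00005` = -2, `C00469` = 1, `C00006` = 2))
  rx("LDH", "lactate dehydrogenase", S(`C00022` = -1, `C00004` = -1,
                                       `C00186` = 1, `C00003` = 1), rev = TRUE)
  rx("LDHP", "lactate dehydrogenase (NADPH)",
     S(`C00022` = -1, `C00005` = -1, `C00186` = 1, `C00006` = 1))
  rx("HYD", "NADH-dependent hydrogenase", S(`C00004` = -1, `C00003` = 1, `C00282` = 1))
  rx("HYDP", "NADPH-dependent hydrogenase", S(`C00005` = -1, `C00006` = 1, `C00282` = 1))
  rx("TH", "transhydrogenase", S(`C00004` = -1, `C00006` = -1,
                                 `C00003` = 1, `C00005` = 1), rev = TRUE)
  rx("ZWF", "oxidative pentose phosphate (lumped)",
     S(`C00668` = -1, `C00006` = -2, `C00001` = -1,
       `C00117` = 1, `C00011` = 1, `C00005` = 2))
  rx("TKT1", "transketolase I (lumped)", S(`C00117` = -2, `C00085` = 1, `C00279` = 1), rev = TRUE)
  rx("TKT2", "transketolase II (lumped)",
     S(`C00117` = -1, `C00279` = -1, `C00085` = 1, `C00118` = 1), rev = TRUE)
  rx("TKT3", "pentose recycling (lumped)",
     S(`C00117` = -3, `C00085` = 2, `C00118` = 1))
  rx("EDD", "Entner-Doudoroff (lumped)",
     S(`C00668` = -1, `C00006` = -1, `C00118` = 1, `C00022` = 1, `C00005` = 1))
  rx("PPC", "PEP carboxylase", S(`C00074` = -1, `C00011` = -1, `C00001` = -1,
                                 `C00036` = 1, `C00009` = 1))
  rx("PCK", "PEP carboxykinase", S(`C00036` = -1, `C00002` = -1,
                                   `C00074` = 1, `C00011` = 1, `C00008` = 1))
  rx("OAADC", "oxaloacetate decarboxylase", S(`C00036` = -1, `C00022` = 1, `C00011` = 1))
  rx("MDH", "malate dehydrogenase", S(`C00149` = -1, `C00003` = -1,
                                      `C00036` = 1, `C00004` = 1), rev = TRUE)
  rx("FUMR", "fumarase", S(`C00149` = -1, `C00122` = 1, `C00001` = 1), rev = TRUE)
  rx("FRD", "fumarate reductase", S(`C00122` = -1, `C00004` = -1,
                                    `C00042` = 1, `C00003` = 1))
  rx("SUCDH", "succinate dehydrogenase (NAD, lumped)",
     S(`C00042` = -1, `C00003` = -1, `C00122` = 1, `C00004` = 1))
  rx("ME1", "malic enzyme (NADP)", S(`C00149` = -1, `C00006` = -1,
                                     `C00022` = 1, `C00011` = 1, `C00005` = 1))
  rx("ME2", "malic enzyme (NAD)", S(`C00149` = -1, `C00003` = -1,
                                    `C00022` = 1, `C00011` = 1, `C00004` = 1))
  rx("AKGDH", "2-oxoglutarate oxidation to succinate (NADP, lumped)",
     S(`C00026` = -1, `C00006` = -1, `C00042` = 1, `C00011` = 1, `C00005` = 1))
  rx("AKGDC", "2-oxoglutarate decarboxylase branch (lumped)",
     S(`C00026` = -1, `C00003` = -1, `C00042` = 1, `C00011` = 1, `C00004` = 1))
  rx("GDH1", "glutamate dehydrogenase (NADPH)",
     S(`C00026` = -1, `C00014` = -1, `C00005` = -1,
       `C00025` = 1, `C00006` = 1, `C00001` = 1), rev = TRUE)
  rx("GDH2", "glutamate dehydrogenase (NADH)",
     S(`C00026` = -1, `C00014` = -1, `C00004` = -1,
       `C00025` = 1, `C00003` = 1, `C00001` = 1))
  rx("GS", "glutamine synthetase",
     S(`C00025` = -1, `C00014` = -1, `C00002` = -1,
       `C00064` = 1, `C00008` = 1, `C00009` = 1))
  rx("GOGAT", "glutamate synthase",
     S(`C00026` = -1, `C00064` = -1, `C00005` = -1, `C00025` = 2, `C00006` = 1))
  rx("GLNASE", "glutaminase", S(`C00064` = -1, `C00001` = -1, `C00025` = 1, `C00014` = 1))
  rx("AST", "aspartate transaminase", S(`C00036` = -1, `C00025` = -1,
                                        `C00049` = 1, `C00026` = 1), rev = TRUE)
  rx("ALT", "alanine transaminase", S(`C00022` = -1, `C00025` = -1,
                                      `C00041` = 1, `C00026` = 1), rev = TRUE)
  rx("ASPASE", "aspartase", S(`C00049` = -1, `C00122` = 1, `C00014` = 1))
  rx("ALADH", "alanine dehydrogenase",
     S(`C00041` = -1, `C00003` = -1, `C00001` = -1,
       `C00022` = 1, `C00014` = 1, `C00004` = 1))

  # Re-type citrate synthase: unannotated pathway carried as a gap fill
  rx("CS_RE", "Re-type citrate synthase to 2-oxoglutarate (lumped)",
     S(`C00024` = -1, `C00036` = -1, `C00003` = -1,
       `C00026` = 1, `C00011` = 1, `C00004` = 1), kind = "gap_fill")

  # --- anabolic chains to biomass building blocks ------------------------
  chain_lens <- c(15L, 15L, 15L, 15L, 15L, 14L, 14L, 14L)
  precursors <- c(PYR, OAA, GLU, PEP, R5P, E4P, GAP, ACA)
  block_names <- c("alanine-family protein pool", "aspartate-family protein pool",
                   "glutamate-family protein pool", "aromatic protein pool",
                   "nucleotide pool", "cell-wall pool", "lipid pool",
                   "cofactor pool")
  byproducts <- c(UTP, sprintf("X%03d", seq_len(37)))
  bp_counter <- 0L
  for (k in seq_len(8L)) {
    prev <- precursors[k]
    for (j in seq_len(chain_lens[k])) {
      iid <- sprintf("I%d_%02d", k, j)
      s <- S(-1, 1); names(s) <- c(prev, iid)
      if (k %in% c(1L, 2L, 4L) && j == 1L) {
        # transamination: nitrogen enters the chain from glutamate
        s[GLU] <- -1; s[AKG] <- 1
      }
      if (j %% 3 == 1) {
        s[ATP] <- -1; s[H2O] <- -1; s[ADP] <- 1; s[PI] <- 1
      } else if (j %% 3 == 2) {
        s[NADPH] <- -1; s[NADP] <- 1
      }
      if (bp_counter < length(byproducts)) {
        bp_counter <- bp_counter + 1L
        s[byproducts[bp_counter]] <- 1
      }
      rx(sprintf("CH%d_%02d", k, j),
         sprintf("anabolic step %d of chain %d", j, k), s)
      prev <- iid
    }
    bbs <- S(-1, -2, -2, -1, 1, 2, 2, 1, 1)
    names(bbs) <- c(prev, ATP, H2O, NADPH, NADP, ADP, PI,
                    sprintf("BB%d", k), CO2)
    rx(sprintf("BBS%d", k),
       paste0("building-block synthesis: ", block_names[k]),
       bbs, kind = "biomass")
  }

  # metabolite-exchange gap fills draining pathway byproducts (UTP first)
  for (b in seq_along(byproducts)) {
    rx(sprintf("GF_%02d", b),
       paste0("metabolite-exchange gap fill: ", byproducts[b]),
       stats::setNames(-1, byproducts[b]), kind = "gap_fill")
  }

  # biomass production: building-block demands (mmol/g DCW) + GAM energy
  demands <- stats::setNames(c(1.8, 1.5, 1.4, 1.1, 0.9, 0.8, 1.0, 0.6),
                             sprintf("BB%d", 1:8))
  bio <- -demands
  if (gam > 0) {
    bio <- c(bio, stats::setNames(c(-gam, -gam, gam, gam),
                                  c(ATP, H2O, ADP, PI)))
  }
  rx("BIOMASS", "biomass production", bio, kind = "biomass")

  # --- exchanges (19) -----------------------------------------------------
  infl <- c(glc_in = GLC, nh3_in = NH3, h2o_in = H2O, pi_in = PI)
  for (i in seq_along(infl)) {
    rx(names(infl)[i], paste0("inflow: ", infl[i]),
       stats::setNames(1, infl[i]), kind = "inflow",
       ub = if (names(infl)[i] == "glc_in") glucose_upper else FD_BIG)
  }
  outf <- c(h2o_out = H2O, co2_out = CO2, h2_out = H2, ac_out = ACE,
            etoh_out = ETH, lac_out = LAC, succ_out = SUC, mal_out = MAL,
            fum_out = FUM, pyr_out = PYR, ala_out = ALA, asp_out = ASP,
            glu_out = GLU, gln_out = GLN, akg_out = AKG)
  for (i in seq_along(outf)) {
    rx(names(outf)[i], paste0("outflow: ", outf[i]),
       stats::setNames(-1, outf[i]), kind = "outflow")
  }

  reactions <- bind_rows(rxs)
  met_ids <- sort(unique(unlist(lapply(reactions$stoichiometry, names))))
  model <- metabolic_model(
    id = "X514_surrogate", organism = "tex-like (synthetic)",
    metabolites = tibble(id = met_ids, name = met_ids,
                         formula = NA_character_, external = FALSE),
    reactions = reactions,
    objective = list(coefficients = c(BIOMASS = 1), direction = "maximize")
  )
  # the surrogate is pinned to the canonical medium-scale dimensions
  stopifnot(
    nrow(model$metabolites) == 196L,
    nrow(model$reactions) == 229L,
    sum(model$reactions$kind == "intracellular") == 162L,
    sum(model$reactions$kind %in% c("inflow", "outflow")) == 19L,
    sum(model$reactions$kind == "gap_fill") == 39L,
    sum(model$reactions$kind == "biomass") == 9L
  )
  model
}
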