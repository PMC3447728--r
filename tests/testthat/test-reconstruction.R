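test_that("exchange reactions pin uptake and secretion rates", {
  toy <- toy_model(reconstructed = FALSE)
  m <- toy |>
    add_inflow("G6P", "glc_in", fixed = 11.0) |>
    add_outflow("ACCOA", "ac_out", fixed = 6.4)
  i <- match(c("glc_in", "ac_out"), m$reactions$id)
  expect_equal(m$reactions$lower_bound[i], c(11.0, 6.4))
  expect_equal(m$reactions$upper_bound[i], c(11.0, 6.4))
  expect_equal(m$reactions$kind[i], c("inflow", "outflow"))
  expect_equal(m$reactions$stoichiometry[[i[1]]], c(G6P = 1))
  expect_equal(m$reactions$stoichiometry[[i[2]]], c(ACCOA = -1))
  expect_error(add_inflow(m, "G6P", "glc_in"), "already in model")

  # a zero-fixed inflow exists but cannot carry flux
  m0 <- add_inflow(toy, "G6P", "glc0", fixed = 0) |>
    set_objective("BIOMASS")
  sol <- solve_fba(m0)
  expect_equal(unname(sol$fluxes["glc0"]), 0)
})

test_that("an inflow flips a starved chain from infeasible to growing", {
  chain <- metabolic_model(
    "starved", metabolites = tibble::tibble(id = c("A", "B")),
    reactions = tibble::tibble(
      id = c("A2B", "out_B"),
      stoichiometry = list(c(A = -1, B = 1), c(B = -1)),
      lower_bound = c(0, 1), upper_bound = c(1000, 1000),
      kind = c("intracellular", "outflow")),
    objective = list(coefficients = c(out_B = 1), direction = "maximize"))
  expect_identical(solve_fba(chain)$status, "infeasible")
  fed <- add_inflow(chain, "A", "in_A", upper_bound = 10)
  sol <- solve_fba(fed)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
})

test_that("knockouts zero bounds, keep reactions, and are idempotent", {
  toy <- toy_model()
  ko <- knockout(toy, "BIOMASS")
  sol_ko <- solve_fba(ko)
  # excess carbon is burned through the lumped TCA loop; growth drops to zero
  expect_identical(sol_ko$status, "optimal")
  expect_equal(sol_ko$objective_value, 0)
  expect_true("BIOMASS" %in% ko$reactions$id)
  expect_identical(knockout(ko, "BIOMASS")$reactions, ko$reactions)
  expect_error(knockout(toy, "nope"), "nope")

  # knocking out one of two redundant routes leaves the optimum unchanged
  tp <- two_path_model()
  base <- solve_fba(tp)$objective_value
  expect_equal(solve_fba(knockout(tp, "p2"))$objective_value, base)
  # knocking out the sole inflow kills it entirely
  expect_equal(solve_fba(knockout(tp, "in_A"))$objective_value, 0)
})

test_that("add_reaction registers metabolites and reverses under knockout", {
  tp <- two_path_model()
  base <- solve_fba(tp)$objective_value
  added <- add_reaction(tp, "shunt", c(A = -1, C = 1), kind = "gap_fill")
  expect_true("C" %in% added$metabolites$id)
  expect_equal(added$reactions$kind[added$reactions$id == "shunt"], "gap_fill")
  expect_equal(solve_fba(knockout(added, "shunt"))$objective_value, base)
  expect_error(add_reaction(tp, "p1", c(A = -1)), "already in model")
  expect_error(add_reaction(tp, "zz", numeric()), "empty stoichiometry")

  # LP relaxation: an added reaction can only help a maximization
  for (seed in 1:10) {
    m <- random_fba_model(seed)
    before <- solve_fba(m)$objective_value
    m2 <- add_reaction(m, "extra",
                       stats::setNames(c(-1, 1),
                                       sample(m$metabolites$id, 2)))
    expect_gte(solve_fba(m2)$objective_value, before - 1e-8)
  }
})

test_that("modify_reaction renormalizes direction and participants", {
  m <- metabolic_model(
    "mod", metabolites = tibble::tibble(id = c("A", "B", "C")),
    reactions = tibble::tibble(
      id = "r", stoichiometry = list(c(A = -1, B = 1)), reversible = TRUE))
  fwd <- modify_reaction(m, "r", new_direction = "forward")
  expect_equal(fwd$reactions$lower_bound[1], 0)
  expect_false(fwd$reactions$reversible[1])

  bwd <- modify_reaction(m, "r", new_direction = "backward")
  expect_equal(bwd$reactions$stoichiometry[[1]], c(A = 1, B = -1))
  expect_equal(bwd$reactions$lower_bound[1], 0)

  pe <- modify_reaction(m, "r", participant_edits = c(C = 2, B = NA))
  expect_equal(pe$reactions$stoichiometry[[1]], c(A = -1, C = 2))
  expect_error(modify_reaction(m, "r", participant_edits = c(B = NA)),
               "without substrates or products")

  # tightening a direction never raises a maximization optimum
  for (seed in 1:8) {
    fx <- random_fba_model(seed)
    fx$reactions$reversible[2] <- TRUE
    fx$reactions$lower_bound[2] <- -1000
    before <- solve_fba(fx)$objective_value
    after <- solve_fba(modify_reaction(fx, fx$reactions$id[2],
                                       new_direction = "forward"))
    val <- if (after$status == "optimal") after$objective_value else 0
    expect_lte(val, before + 1e-8)
  }
})

test_that("biomass installation wires demands, GAM couple and drain", {
  m <- metabolic_model(
    "bm", metabolites = tibble::tibble(
      id = c("A", "C00002", "C00008", "C00009", "C00001")),
    reactions = tibble::tibble(
      id = "in_A", stoichiometry = list(c(A = 1)), kind = "inflow",
      lower_bound = 4, upper_bound = 4))
  comp <- biomass_composition(c(A = 2), gam = 10)
  mb <- set_biomass(m, comp)
  s <- mb$reactions$stoichiometry[[match("BIOMASS", mb$reactions$id)]]
  expect_equal(s[["A"]], -2)
  expect_equal(s[["C00002"]], -10)
  expect_equal(s[["C00008"]], 10)
  expect_equal(s[["biomass"]], 1)
  expect_true("BIOMASS_drain" %in% mb$reactions$id)

  nog <- set_biomass(m, biomass_composition(c(A = 2), gam = 0))
  s0 <- nog$reactions$stoichiometry[[match("BIOMASS", nog$reactions$id)]]
  expect_false("C00002" %in% names(s0))

  expect_error(set_biomass(m, biomass_composition(c(missing_met = 1))),
               "not in model")
  expect_error(biomass_composition(numeric()), "non-empty")
  expect_error(biomass_composition(c(A = 1), gam = -5), "gam")
})

test_that("doubling biomass demands halves growth at fixed uptake", {
  base <- metabolic_model(
    "y", metabolites = tibble::tibble(id = "A"),
    reactions = tibble::tibble(
      id = "in_A", stoichiometry = list(c(A = 1)), kind = "inflow",
      lower_bound = 6, upper_bound = 6))
  m1 <- set_biomass(base, biomass_composition(c(A = 1.5))) |>
    set_objective("BIOMASS")
  m2 <- set_biomass(base, biomass_composition(c(A = 3))) |>
    set_objective("BIOMASS")
  expect_equal(solve_fba(m1)$objective_value,
               2 * solve_fba(m2)$objective_value, tolerance = 1e-9)
})

test_that("maintenance is pinned and monotone against growth", {
  x <- x514_surrogate() |> fix_flux("glc_in", 3.92)
  m1 <- set_maintenance(x, 7.6)
  sol <- solve_fba(m1)
  expect_equal(unname(sol$fluxes["ATPM"]), 7.6)
  m0 <- set_maintenance(x, 0)
  m2 <- set_maintenance(x, 12)
  g <- vapply(list(m0, m1, m2), function(m) solve_fba(m)$objective_value,
              numeric(1))
  expect_true(all(diff(g) < 1e-9))
  expect_error(set_maintenance(x, -1), "ngam")
})

test_that("edit scripts apply in order, atomically, from YAML", {
  toy <- toy_model(reconstructed = FALSE)
  script <- list(
    list(op = "add_inflow", target_metabolite = "G6P",
         reaction_id = "glc_in", fixed = 11.0),
    list(op = "add_outflow", source_metabolite = "ACCOA",
         reaction_id = "ac_out", fixed = 6.4),
    list(op = "set_objective", coefficients = list(BIOMASS = 1))
  )
  m <- apply_edit_script(toy, script)
  expect_model_equal(m, toy_model())
  expect_identical(apply_edit_script(toy, list()), toy)

  bad <- c(script[1:2],
           list(list(op = "knockout", reaction_ids = "does_not_exist")),
           script[3])
  expect_error(apply_edit_script(toy, bad), "directive 3")

  # YAML round trip
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(edits = script), path)
  m2 <- apply_edit_script(toy, read_edit_script(path))
  expect_model_equal(m2, toy_model())
})
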