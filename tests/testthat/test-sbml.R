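# hand-authored legacy L2 encoding of a 3-reaction chain, with bounds,
# objective and flux values in COBRA-style kinetic-law parameters
l2_doc <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
  <model id="legacy" name="legacy">
    <listOfCompartments><compartment id="c"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" name="A" compartment="c" boundaryCondition="false"/>
      <species id="B" name="B" compartment="c" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="in_A" name="in_A" reversible="false">
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="5"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
            <parameter id="FLUX_VALUE" value="5"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="A2B" name="A2B" reversible="false">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
            <parameter id="FLUX_VALUE" value="5"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="out_B" name="out_B" reversible="false">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>
            <parameter id="FLUX_VALUE" value="5"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'

test_that("write -> read is the identity on canonical and fixture models", {
  toy <- toy_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(toy, path = path)
  expect_model_equal(read_sbml(path), toy)

  for (seed in c(2, 5)) {
    m <- random_fba_model(seed)
    expect_model_equal(read_sbml(write_sbml(m)), m)
    fx <- generate_fixture_organism(seed, n_reactions = 30, n_pathways = 2)
    expect_model_equal(read_sbml(write_sbml(fx$ground_truth)),
                       fx$ground_truth)
  }
})

test_that("the surrogate exports at its canonical dimensions and round-trips", {
  x <- x514_surrogate()
  doc <- write_sbml(x)
  n_species <- length(xml2::xml_find_all(
    xml2::read_xml(doc), "//*[local-name()='species']"))
  expect_equal(n_species, 196L)
  back <- read_sbml(doc)
  expect_equal(nrow(back$metabolites), 196L)
  expect_equal(nrow(back$reactions), 229L)
  expect_model_equal(back, x)
  expect_identical(table(back$reactions$kind), table(x$reactions$kind))
})

test_that("the TOY export carries its ten species and embedded fluxes", {
  toy <- toy_model()
  sol <- solve_fba(toy)
  doc <- write_sbml(toy, fluxes = sol)
  xml <- xml2::read_xml(doc)
  expect_equal(length(xml2::xml_find_all(xml, "//*[local-name()='species']")),
               10L)
  back <- read_sbml(doc)
  expect_equal(back$notes$flux_values[["glc_in"]], 11.0)
  expect_equal(back$notes$flux_values[["ac_out"]], 6.4)
  expect_equal(sort(names(back$notes$flux_values)), sort(names(sol$fluxes)))
})

test_that("awkward identifiers are sanitized reversibly", {
  m <- metabolic_model(
    "6pg model",
    metabolites = tibble::tibble(id = c("6PG", "a b")),
    reactions = tibble::tibble(id = "6pgd",
                               stoichiometry = list(c(`6PG` = -1, `a b` = 1))))
  doc <- write_sbml(m)
  xml <- xml2::read_xml(doc)
  ids <- xml2::xml_attr(
    xml2::xml_find_all(xml, "//*[local-name()='species']"), "id")
  expect_true(all(grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)))
  back <- read_sbml(doc)
  expect_model_equal(back, m)
  expect_true(all(c("6PG", "a b", "6pgd") %in% back$notes$id_map))
})

test_that("legacy L2 kinetic-law bounds read identically to L3 FBC", {
  l2 <- read_sbml(l2_doc)
  l3 <- read_sbml(write_sbml(chain_model()))
  expect_model_equal(l2, l3)
  expect_equal(l2$objective$coefficients, c(out_B = 1))
  # embedded flux values recovered from FLUX_VALUE
  expect_equal(unname(l2$notes$flux_values[c("in_A", "A2B", "out_B")]),
               c(5, 5, 5))
  # and the read model solves to the same optimum as the source model
  expect_equal(solve_fba(l2)$objective_value,
               solve_fba(chain_model())$objective_value)
})

test_that("missing bounds fall back to reversibility defaults with a warning", {
  doc <- '<?xml version="1.0"?>
  <sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
    <model id="nobounds">
      <listOfSpecies>
        <species id="A" boundaryCondition="false"/>
        <species id="B" boundaryCondition="false"/>
      </listOfSpecies>
      <listOfReactions>
        <reaction id="r1" reversible="true">
          <listOfReactants><speciesReference species="A"/></listOfReactants>
          <listOfProducts><speciesReference species="B"/></listOfProducts>
        </reaction>
        <reaction id="r2" reversible="false">
          <listOfReactants><speciesReference species="B"/></listOfReactants>
          <listOfProducts><speciesReference species="A"/></listOfProducts>
        </reaction>
      </listOfReactions>
    </model>
  </sbml>'
  expect_warning(m <- read_sbml(doc), "bound")
  expect_equal(m$reactions$lower_bound, c(-1000, 0))
  expect_equal(m$reactions$upper_bound, c(1000, 1000))
  # default stoichiometry of an omitted attribute is one
  expect_equal(m$reactions$stoichiometry[[1]], c(A = -1, B = 1))
})

test_that("non-SBML XML is refused with a format error", {
  expect_error(read_sbml("<pathway name='x' org='y'/>"), "not an SBML")
})

test_that("boundary species are excluded from balance but kept in SBML", {
  m <- chain_model()
  m$metabolites <- dplyr::bind_rows(
    m$metabolites, tibble::tibble(id = "Xext", name = "Xext",
                                  formula = NA_character_, external = TRUE))
  m <- add_reaction(m, "leak", c(B = -1, Xext = 1), kind = "outflow")
  doc <- write_sbml(m)
  xml <- xml2::read_xml(doc)
  bc <- xml2::xml_attr(
    xml2::xml_find_all(xml, "//*[local-name()='species']"),
    "boundaryCondition")
  expect_equal(sum(bc == "true"), 1L)
  back <- read_sbml(doc)
  expect_model_equal(back, m)
  S <- build_stoichiometric_matrix(back)
  expect_false("Xext" %in% rownames(S))
})
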