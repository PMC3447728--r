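kgml_one <- '<?xml version="1.0"?>
<pathway name="path:tex00010" org="tex" number="00010" title="demo">
  <reaction id="1" name="rn:R00299" type="irreversible">
    <substrate id="10" name="cpd:C00031"/>
    <product id="11" name="cpd:C00092"/>
  </reaction>
</pathway>'

test_that("KGML reaction entries map through with prefixes stripped", {
  pw <- parse_kgml(kgml_one)
  expect_s3_class(pw, "kgml_pathway")
  expect_equal(pw$pathway_id, "tex00010")
  expect_equal(pw$organism, "tex")
  expect_equal(nrow(pw$reactions), 1L)
  expect_equal(pw$reactions$reaction_id, "R00299")
  expect_equal(pw$reactions$type, "irreversible")
  expect_equal(pw$reactions$substrates[[1]], "C00031")
  expect_equal(pw$reactions$products[[1]], "C00092")

  empty <- parse_kgml('<pathway name="path:tex00020" org="tex"/>')
  expect_equal(nrow(empty$reactions), 0L)

  expect_warning(
    pw2 <- parse_kgml(sub(' type="irreversible"', "", kgml_one)),
    "assuming reversible")
  expect_equal(pw2$reactions$type, "reversible")

  expect_error(parse_kgml("<pathway name='x' org='y'><reaction id='1' name='rn:BAD1' type='reversible'/></pathway>"),
               "R#####")
  expect_error(parse_kgml("not xml <"))
})

test_that("LIGAND equation grammar: signs, coefficients, netting, rejections", {
  expect_equal(parse_equation("C00031 + C00002 <=> C00092 + C00008"),
               c(C00031 = -1, C00002 = -1, C00092 = 1, C00008 = 1))
  expect_equal(parse_equation("2 C00005 + C00007 <=> 2 C00006"),
               c(C00005 = -2, C00007 = -1, C00006 = 2))
  # omitted coefficient is one; same compound on both sides nets out
  expect_equal(parse_equation("C00001 + C00002 <=> C00002 + C00003"),
               c(C00001 = -1, C00003 = 1))
  expect_null(parse_equation("C00031 + n C00001 <=> C00092"))
  expect_null(parse_equation("C00031 <=> G00001"))
  expect_null(parse_equation("(n+1) C00001 <=> C00002"))
  expect_null(parse_equation("C00001 + C00002"))
  # net-zero equations are one-sided, hence rejected
  expect_null(parse_equation("C00001 <=> C00001"))
  r <- parse_equation("C00031 + n C00001 <=> C00092", detail = TRUE)
  expect_match(attr(r, "reason"), "non-numeric coefficient")
})

test_that("reaction tables parse from flat files and TSV with flagged failures", {
  flat <- paste0(
    "ENTRY       R00001                      Reaction\n",
    "NAME        hexokinase\n",
    "EQUATION    C00031 + C00002 <=> C00092 + C00008\n///\n",
    "ENTRY       R00002                      Reaction\n",
    "NAME        polymer case\n",
    "EQUATION    C00031 + n C00001 <=> C00092\n///")
  defs <- parse_reaction_table(flat)
  expect_equal(nrow(defs), 2L)
  expect_equal(defs$parse_ok, c(TRUE, FALSE))
  expect_equal(defs$stoichiometry[[1]],
               c(C00031 = -1, C00002 = -1, C00092 = 1, C00008 = 1))
  expect_match(defs$reason[2], "non-numeric")

  tsv <- "R00001\thexokinase\tC00031 + C00002 <=> C00092 + C00008"
  defs2 <- parse_reaction_table(tsv)
  expect_equal(defs2$stoichiometry[[1]], defs$stoichiometry[[1]])

  dup <- paste(tsv, "R00001\tcopy\tC00031 <=> C00092", sep = "\n")
  expect_warning(defs3 <- parse_reaction_table(dup), "duplicate")
  expect_equal(nrow(defs3), 1L)
  expect_equal(defs3$name, "hexokinase")
})

test_that("drafting dedupes across maps and reports skipped reactions", {
  kg_a <- '<pathway name="path:tex00010" org="tex">
    <reaction id="1" name="rn:R00001" type="irreversible">
      <substrate id="1" name="cpd:C00001"/><product id="2" name="cpd:C00002"/>
    </reaction></pathway>'
  kg_b <- '<pathway name="path:tex00020" org="tex">
    <reaction id="1" name="rn:R00001" type="reversible">
      <substrate id="1" name="cpd:C00001"/><product id="2" name="cpd:C00002"/>
    </reaction>
    <reaction id="2" name="rn:R00002" type="irreversible">
      <substrate id="1" name="cpd:C00002"/><product id="2" name="cpd:C00003"/>
    </reaction>
    <reaction id="3" name="rn:R00003" type="irreversible">
      <substrate id="1" name="cpd:C00003"/><product id="2" name="cpd:C00004"/>
    </reaction></pathway>'
  defs <- parse_reaction_table(paste(
    "R00001\tone\tC00001 <=> C00002",
    "R00002\ttwo\tC00002 + n C00001 <=> C00003",
    sep = "\n"))
  draft <- assemble_draft(list(parse_kgml(kg_a), parse_kgml(kg_b)),
                          defs, "tex")
  # dedupe: R00001 once; reversibility conflict resolved to reversible
  expect_equal(draft$reactions$id, "R00001")
  expect_true(draft$reactions$reversible[1])
  # skipped: R00002 unparsable, R00003 undefined
  expect_setequal(draft$notes$draft_report$reaction_id, c("R00002", "R00003"))
  expect_error(assemble_draft(list(parse_kgml(kg_a)), defs, "eco"),
               "organism mismatch")
  nodefs <- parse_reaction_table("R99999\tx\tC00001 <=> C00002")
  expect_error(assemble_draft(list(parse_kgml(kg_a)), nodefs, "tex"),
               "empty draft")
})

test_that("orientation disagreement keeps LIGAND sides with a warning", {
  kg <- '<pathway name="path:tex00010" org="tex">
    <reaction id="1" name="rn:R00001" type="irreversible">
      <substrate id="1" name="cpd:C00002"/><product id="2" name="cpd:C00001"/>
    </reaction></pathway>'
  defs <- parse_reaction_table("R00001\tflip\tC00001 <=> C00002")
  expect_warning(draft <- assemble_draft(list(parse_kgml(kg)), defs, "tex"),
                 "LIGAND orientation")
  expect_equal(draft$reactions$stoichiometry[[1]], c(C00001 = -1, C00002 = 1))
})

test_that("fixture organisms round-trip through parsing and drafting", {
  for (seed in c(1, 3, 7, 11, 23)) {
    fx <- generate_fixture_organism(seed, n_pathways = 4, n_reactions = 60,
                                    overlap_fraction = 8 / 60,
                                    corrupt_fraction = 0.05)
    pathways <- lapply(fx$kgml, parse_kgml)
    defs <- parse_reaction_table(fx$reaction_table)
    expect_equal(sum(!defs$parse_ok), length(fx$annotations$corrupted))
    expect_setequal(defs$reaction_id[!defs$parse_ok], fx$annotations$corrupted)
    draft <- assemble_draft(pathways, defs, "syn")
    expect_model_equal(draft, fx$ground_truth)
    expect_equal(draft$notes$draft_report$reaction_id,
                 fx$ground_truth$notes$draft_report$reaction_id)
  }
})

test_that("fixture generation is deterministic and validates arguments", {
  a <- generate_fixture_organism(5, corrupt_fraction = 0.1)
  b <- generate_fixture_organism(5, corrupt_fraction = 0.1)
  expect_identical(a$kgml, b$kgml)
  expect_identical(a$reaction_table, b$reaction_table)
  expect_model_equal(a$ground_truth, b$ground_truth)

  clean <- generate_fixture_organism(4, corrupt_fraction = 0)
  expect_true(all(parse_reaction_table(clean$reaction_table)$parse_ok))

  expect_error(generate_fixture_organism(1, overlap_fraction = 1.5), "overlap")
  expect_error(generate_fixture_organism(1, corrupt_fraction = -0.1), "corrupt")
})

test_that("adding a pathway never removes reactions; corruption is local", {
  fx <- generate_fixture_organism(13, n_pathways = 4, n_reactions = 40,
                                  overlap_fraction = 0.1)
  pathways <- lapply(fx$kgml, parse_kgml)
  defs <- parse_reaction_table(fx$reaction_table)
  partial <- assemble_draft(pathways[1:3], defs, "syn")
  full <- assemble_draft(pathways, defs, "syn")
  expect_true(all(partial$reactions$id %in% full$reactions$id))

  # corrupt a single non-backbone record by hand: at most one reaction changes
  victim <- setdiff(full$reactions$id, fx$annotations$backbone)[1]
  defs2 <- defs
  k <- match(victim, defs2$reaction_id)
  defs2$parse_ok[k] <- FALSE
  defs2$stoichiometry[k] <- list(NULL)
  defs2$reason[k] <- "hand-corrupted"
  dented <- assemble_draft(pathways, defs2, "syn")
  expect_setequal(setdiff(full$reactions$id, dented$reactions$id), victim)
})
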