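test_that("a three-reaction toy loads with the documented shapes", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "A", compartment = "c"),
                       list(id = "B", compartment = "c")),
    reactions = list(
      list(id = "EX_A", mets = list(A = -1), lb = -1000, ub = 1000,
           exchange = TRUE),
      list(id = "R1", mets = list(A = -1, B = 1)), # no bounds in file
      list(id = "EX_B", mets = list(B = -1), lb = -1000, ub = 1000,
           exchange = TRUE))), path, auto_unbox = TRUE)
  m <- load_model(path, format = "json")
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(nrow(m$reactions), 3)
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 3L))
  # default bounds where unspecified
  expect_equal(m$reactions$lb[m$reactions$id == "R1"], -1000)
  expect_equal(m$reactions$ub[m$reactions$id == "R1"], 1000)
  # exchange column: single nonzero -1 in the metabolite's row
  expect_equal(unname(S[, "EX_A"]), c(-1, 0))
})

test_that("validation errors name the offending record", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "A", compartment = "c")),
    reactions = list(list(id = "R1", mets = list(A = -1, X = 1)))),
    path, auto_unbox = TRUE)
  expect_error(load_model(path, format = "json"), "X")

  mets <- data.frame(id = "A", name = "A", compartment = "c")
  expect_error(
    metabolic_model(mets,
                    data.frame(id = c("R1", "R1"), lb = 0, ub = 1),
                    list(R1 = c(A = -1))),
    "duplicate reaction")
  expect_error(
    metabolic_model(mets, data.frame(id = "R1", lb = 2, ub = 1),
                    list(R1 = c(A = -1))),
    "lower bound")
  expect_error(
    metabolic_model(mets,
                    data.frame(id = "R1", lb = 0, ub = 1, exchange = TRUE),
                    list(R1 = c(A = -1, A2 = 1))),
    "exactly one metabolite|undefined")
})

test_that("JSON round trip preserves the model field by field", {
  m <- fig_fixture()$model
  path <- write_tmp_json(m)
  m2 <- load_model(path)
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$reactions, m$reactions)
  for (rid in m$reactions$id)
    expect_equal(m2$stoich[[rid]], m$stoich[[rid]])
  expect_equal(m2$genes, m$genes)
})

test_that("stoichiometric matrix columns match the stoichiometry maps", {
  m <- generate_toy_model(2, 3, seed = 4, gpr_complexity = 0.5)
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(nrow(m$metabolites), nrow(m$reactions)))
  for (rid in m$reactions$id) {
    col <- S[, rid]
    nz <- col[col != 0]
    expect_equal(sort(names(nz)), sort(names(m$stoich[[rid]])))
    expect_equal(nz[names(m$stoich[[rid]])], m$stoich[[rid]],
                 ignore_attr = FALSE)
  }
})

test_that("the SBML subset reader recovers ids, bounds, GPR and pathway", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="toy">
  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
  <listOfSpecies>
    <species id="A" name="met A" compartment="c" boundaryCondition="false"/>
    <species id="B" compartment="c" boundaryCondition="false"/>
  </listOfSpecies>
  <listOfParameters>
    <parameter id="lb_r1" value="0" constant="true"/>
    <parameter id="ub_r1" value="500" constant="true"/>
  </listOfParameters>
  <listOfReactions>
    <reaction id="R1" reversible="false" lowerFluxBound="lb_r1" upperFluxBound="ub_r1">
      <notes><body xmlns="http://www.w3.org/1999/xhtml">
        <p>GENE_ASSOCIATION: g1 and g2</p>
        <p>SUBSYSTEM: Core</p>
      </body></notes>
      <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
      <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
    </reaction>
    <reaction id="EX_A" reversible="true">
      <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
    </reaction>
    <reaction id="EX_B" reversible="true">
      <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
    </reaction>
  </listOfReactions>
</model></sbml>'
  path <- tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- load_model(path) # format guessed from extension
  expect_equal(nrow(m$reactions), 3)
  r1 <- m$reactions[m$reactions$id == "R1", ]
  expect_equal(r1$lb, 0)
  expect_equal(r1$ub, 500)
  expect_equal(r1$pathway, "Core")
  expect_setequal(m$genes, c("g1", "g2"))
  expect_true(all(m$reactions$exchange[m$reactions$id %in% c("EX_A", "EX_B")]))
  expect_equal(m$stoich$R1, c(A = -1, B = 1))
  # reversible exchange without explicit bounds gets the defaults
  expect_equal(m$reactions$lb[m$reactions$id == "EX_A"], -1000)
})
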