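# SBML reading, writing, validation.

minimal_xml <- paste0(
  '<?xml version="1.0" encoding="UTF-8"?>',
  '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
  'level="3" version="2"><model id="m">',
  '<listOfCompartments><compartment id="c" size="1" constant="true"/>',
  "</listOfCompartments>",
  '<listOfSpecies><species id="A" compartment="c" initialAmount="1" ',
  'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
  'constant="false"/></listOfSpecies>',
  '<listOfParameters><parameter id="k" value="2" constant="true"/>',
  "</listOfParameters>",
  '<listOfReactions><reaction id="r" reversible="false">',
  '<listOfReactants><speciesReference species="A" stoichiometry="1" ',
  'constant="true"/></listOfReactants><kineticLaw>',
  '<math xmlns="http://www.w3.org/1998/Math/MathML">',
  "<apply><times/><ci>k</ci><ci>A</ci></apply></math>",
  "</kineticLaw></reaction></listOfReactions></model></sbml>")

test_that("a minimal one-species, one-reaction document parses", {
  m <- parse_sbml(minimal_xml)
  expect_s3_class(m, "sbml_model")
  expect_length(m$species, 1)
  expect_length(m$reactions, 1)
  expect_equal(m$species$A$initial_amount, 1)
  expect_equal(eval_math(m$reactions$r$kinetic_law, list(k = 2, A = 3)), 6)
})

test_that("unsupported constructs raise named errors", {
  alg <- sub("<listOfReactions",
             paste0("<listOfRules><algebraicRule>",
                    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
                    "<ci>A</ci></math></algebraicRule></listOfRules>",
                    "<listOfReactions"),
             minimal_xml)
  expect_error(parse_sbml(alg), "unsupported construct: algebraicRule")
  fast <- sub('reaction id="r" reversible="false"',
              'reaction id="r" reversible="false" fast="true"',
              minimal_xml)
  expect_error(parse_sbml(fast), "unsupported construct: fast")
  cf <- sub('<model id="m">', '<model id="m" conversionFactor="k">',
            minimal_xml)
  expect_error(parse_sbml(cf), "unsupported construct: conversionFactor")
  lvl <- sub('level="3" version="2"', 'level="1" version="2"',
             minimal_xml)
  lvl <- sub("level3/version2", "level1", lvl)
  expect_error(parse_sbml(lvl), "unsupported construct: SBML Level 1")
})

test_that("malformed XML and dangling references are rejected", {
  expect_error(parse_sbml("<sbml><model>"), "parse error")
  bad <- gsub('species="A"', 'species="X"', minimal_xml)
  expect_error(parse_sbml(bad), "X")
})

test_that("generated models round-trip through write_sbml/parse_sbml", {
  for (m in fixture_models()) {
    xml <- write_sbml(m)
    m2 <- parse_sbml(xml)
    expect_equal(m2, m, info = m$id)
  }
})

test_that("events survive a round trip", {
  m <- fixture_models()$misc
  m2 <- parse_sbml(write_sbml(m))
  ev <- m2$events$e1
  expect_false(is.null(ev))
  expect_equal(ev$initial_trigger_value, TRUE)
  expect_equal(names(ev$assignments), "drv")
  expect_equal(eval_math(ev$trigger, list(time = 1500)), 1)
  expect_equal(eval_math(ev$trigger, list(time = 10)), 0)
})

test_that("an empty model writes a minimal valid document", {
  m <- sbml_model(id = "empty")
  m2 <- parse_sbml(write_sbml(m))
  expect_equal(m2$id, "empty")
  expect_length(m2$species, 0)
})

test_that("Level 2 documents with kineticLaw listOfParameters parse", {
  l2 <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" ',
    'level="2" version="4"><model id="m2">',
    '<listOfCompartments><compartment id="c" size="1"/>',
    "</listOfCompartments>",
    '<listOfSpecies><species id="A" compartment="c" initialAmount="1"/>',
    "</listOfSpecies>",
    '<listOfReactions><reaction id="r">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    "<kineticLaw>",
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    "<apply><times/><ci>k</ci><ci>A</ci></apply></math>",
    '<listOfParameters><parameter id="k" value="3"/></listOfParameters>',
    "</kineticLaw></reaction></listOfReactions></model></sbml>")
  m <- parse_sbml(l2)
  expect_equal(m$level, 2L)
  expect_equal(unname(m$reactions$r$local_parameters["k"]), 3)
  # defaults: missing stoichiometry is 1, L2 reversible default is true
  expect_equal(unname(m$reactions$r$reactants["A"]), 1)
  expect_true(m$reactions$r$reversible)
})

test_that("validate_model reports findings instead of throwing", {
  m <- fixture_models()$three_pair
  expect_equal(nrow(validate_model(m)), 0)

  bad <- m
  bad$reactions[[1]]$reactants <- c(X = 1)
  f <- validate_model(bad)
  expect_true(any(grepl("'X'", f$message)))
  expect_true(all(f$severity == "error"))

  two_rules <- fixture_models()$misc
  two_rules$rules <- c(two_rules$rules,
                       list(sbml_rule("assignment", "tot", "1")))
  f <- validate_model(two_rules)
  expect_true(any(grepl("more than one rule", f$message)))

  cyc <- sbml_model(
    id = "cyc",
    parameters = list(sbml_parameter("p", NA, constant = FALSE),
                      sbml_parameter("q", NA, constant = FALSE)),
    rules = list(sbml_rule("assignment", "p", "q + 1"),
                 sbml_rule("assignment", "q", "p - 1")))
  f <- validate_model(cyc)
  expect_true(any(grepl("cyclic", f$message)))
})
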