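# System compilation, derivative evaluation, initial state, events.

test_that("stoichiometry matrices are built correctly", {
  m <- sbml_model(
    id = "ab",
    compartments = list(sbml_compartment("c", 1)),
    species = list(sbml_species("A", "c", initial_concentration = 2),
                   sbml_species("B", "c", initial_concentration = 0)),
    parameters = list(sbml_parameter("k", 1)),
    reactions = list(sbml_reaction("r", reactants = c(A = 1),
                                   products = c(B = 1),
                                   kinetic_law = "k * A")))
  sys <- compile_system(m)
  expect_equal(unname(sys$N), matrix(c(-1, 1), 2, 1))
  dy <- derivatives(sys, 0, c(A = 2, B = 0))
  expect_equal(unname(dy), c(-2, 2))

  # reversible reaction: one signed column
  mr <- m
  mr$reactions$r <- sbml_reaction("r", reactants = c(A = 1),
                                  products = c(B = 1),
                                  kinetic_law = "k*A - 2*B",
                                  reversible = TRUE)
  sysr <- compile_system(mr)
  expect_equal(ncol(sysr$N), 1)
  dy <- derivatives(sysr, 0, c(A = 0, B = 3))
  expect_equal(unname(dy), c(6, -6))
})

test_that("Michaelis-Menten rate at S = Km gives Vmax/2 with sign -1", {
  m <- sbml_model(
    id = "mm",
    compartments = list(sbml_compartment("c", 1)),
    species = list(sbml_species("S", "c", initial_concentration = 1),
                   sbml_species("P", "c", initial_concentration = 0)),
    parameters = list(sbml_parameter("Vmax", 100),
                      sbml_parameter("Km", 1)),
    reactions = list(sbml_reaction("v", reactants = c(S = 1),
                                   products = c(P = 1),
                                   kinetic_law = "Vmax*S/(Km+S)")))
  sys <- compile_system(m)
  dy <- derivatives(sys, 0, c(S = 1, P = 0))
  expect_equal(unname(dy), c(-50, 50))
})

test_that("derivatives match the naive document-walking oracle", {
  set.seed(11)
  for (nm in names(fixture_models())) {
    m <- fixture_models()[[nm]]
    sys <- compile_system(m)
    for (i in 1:100) {
      t <- runif(1, 0, 100)
      y <- random_state(sys)
      dy <- derivatives(sys, t, y)
      dy_o <- naive_derivatives(m, t, y)
      expect_equal(dy, dy_o, tolerance = 1e-12, info = nm)
    }
  }
})

test_that("closed conversion subnetworks conserve total amount", {
  gen <- generate_chain_model(chain_model_spec(3, seed = 4,
                                               transport = FALSE))
  sys <- compile_system(gen$model)
  expect_true(all(abs(colSums(sys$N)) == 0))
  set.seed(2)
  for (i in 1:20) {
    y <- random_state(sys)
    expect_equal(sum(derivatives(sys, runif(1, 0, 10), y)), 0,
                 tolerance = 1e-12)
  }
})

test_that("initial_state honors amounts, concentrations and rules", {
  m <- sbml_model(
    id = "init",
    compartments = list(sbml_compartment("c", 3)),
    species = list(sbml_species("A", "c", initial_concentration = 2)),
    parameters = list(sbml_parameter("p", 5),
                      sbml_parameter("x", NA, constant = FALSE)),
    rules = list(sbml_rule("assignment", "x", "2 * p")))
  sys <- compile_system(m)
  y0 <- initial_state(sys)
  expect_equal(unname(y0["A"]), 6)  # concentration 2 in volume 3
  expect_equal(unname(attr(y0, "context")["x"]), 10)

  m2 <- m
  m2$species$A$initial_concentration <- NA_real_
  sys2 <- compile_system(m2)
  expect_error(initial_state(sys2), "missing initial value for 'A'")

  # synthetic generator bookkeeping: first medium species carries the dose
  spec <- chain_model_spec(2, seed = 8)
  gen <- generate_chain_model(spec)
  y0 <- initial_state(compile_system(gen$model))
  expect_equal(unname(y0["M1_med"]), spec$dose * spec$medium_size)
  expect_true(all(y0[names(y0) != "M1_med"] == 0))
})

test_that("local parameters shadow globals inside their reaction", {
  m <- sbml_model(
    id = "shadow",
    compartments = list(sbml_compartment("c", 1)),
    species = list(sbml_species("A", "c", initial_concentration = 1)),
    parameters = list(sbml_parameter("k", 100)),
    reactions = list(
      sbml_reaction("r1", reactants = c(A = 1), kinetic_law = "k*A",
                    local_parameters = c(k = 1)),
      sbml_reaction("r2", reactants = c(A = 1), kinetic_law = "k*A")))
  sys <- compile_system(m)
  dy <- derivatives(sys, 0, c(A = 1))
  expect_equal(unname(dy), -101)  # 1 from r1 (local k), 100 from r2
})

test_that("cyclic assignment rules abort compilation with the cycle", {
  m <- sbml_model(
    id = "cyc",
    parameters = list(sbml_parameter("p", NA, constant = FALSE),
                      sbml_parameter("q", NA, constant = FALSE)),
    rules = list(sbml_rule("assignment", "p", "q + 1"),
                 sbml_rule("assignment", "q", "p - 1")))
  expect_error(compile_system(m), "cyclic")
})

event_model <- function(init_trigger = FALSE, trigger = "time >= 5") {
  sbml_model(
    id = "ev",
    compartments = list(sbml_compartment("c", 1)),
    species = list(sbml_species("X", "c", initial_concentration = 10)),
    parameters = list(sbml_parameter("k", 0.1)),
    reactions = list(sbml_reaction("decay", reactants = c(X = 1),
                                   kinetic_law = "k*X")),
    events = list(sbml_event("reset", trigger, list(X = "0"),
                             initial_trigger_value = init_trigger)))
}

test_that("locate_and_fire_events finds a linear trigger crossing", {
  sys <- compile_system(event_model())
  # no crossing on [0, 2]
  expect_null(locate_and_fire_events(sys, 0, c(X = 10), 2, c(X = 9)))
  # crossing of t >= 5 inside [4, 6]
  hit <- locate_and_fire_events(sys, 4, c(X = 8), 6, c(X = 7))
  expect_equal(hit$t_star, 5, tolerance = 1e-8)
  expect_equal(unname(hit$y_star["X"]), 0)
  expect_equal(hit$fired, "reset")
})

test_that("integration applies events and restarts at the crossing", {
  sys <- compile_system(event_model())
  s <- solver_settings(t_start = 0, t_end = 10, abs_tol = 1e-10,
                       rel_tol = 1e-8, output_step = 0.5)
  tr <- integrate_ode(sys, s)
  expect_equal(tr$status, "success")
  x <- tr$values[, "X"]
  tt <- tr$times
  # exponential decay before t = 5
  expect_equal(x[tt == 4.5], 10 * exp(-0.45), tolerance = 1e-6)
  # reset to zero at the event, stays zero afterwards
  expect_lt(max(abs(x[tt >= 5.5])), 1e-8)
})

test_that("initial trigger value controls firing at the start", {
  # trigger already true at t0, assumed true before: must NOT fire
  sys <- compile_system(event_model(init_trigger = TRUE,
                                    trigger = "time >= -1"))
  s <- solver_settings(t_start = 0, t_end = 2, abs_tol = 1e-10,
                       rel_tol = 1e-8, output_step = 1)
  tr <- integrate_ode(sys, s)
  expect_equal(unname(tr$values[1, "X"]), 10)
  expect_equal(unname(tr$values[3, "X"]), 10 * exp(-0.2),
               tolerance = 1e-6)

  # same trigger assumed false before t0: fires immediately
  sys2 <- compile_system(event_model(init_trigger = FALSE,
                                     trigger = "time >= -1"))
  tr2 <- integrate_ode(sys2, s)
  expect_equal(unname(tr2$values[1, "X"]), 0)
})

test_that("boundary species stay constant under reactions", {
  m <- sbml_model(
    id = "bnd",
    compartments = list(sbml_compartment("c", 1)),
    species = list(sbml_species("Src", "c", initial_concentration = 5,
                                boundary_condition = TRUE),
                   sbml_species("A", "c", initial_concentration = 0)),
    parameters = list(sbml_parameter("k", 1)),
    reactions = list(sbml_reaction("inflow", reactants = c(Src = 1),
                                   products = c(A = 1),
                                   kinetic_law = "k*Src")))
  sys <- compile_system(m)
  expect_equal(sys$state_ids, "A")   # Src excluded from the state
  s <- solver_settings(t_start = 0, t_end = 1, output_step = 0.5)
  tr <- integrate_ode(sys, s)
  expect_equal(unname(tr$values[, "Src"]), rep(5, 3))
  expect_equal(unname(tr$values[3, "A"]), 5, tolerance = 1e-6) # k*Src*t
})
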