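# Adaptive integration: accuracy, order, stiffness, controller.

test_that("y' = -y reproduces exp(-1) at the study tolerances", {
  s <- solver_settings("rosenbrock", abs_tol = 1e-12, rel_tol = 1e-6,
                       t_start = 0, t_end = 1, output_step = 0.1)
  tr <- integrate_ode(function(t, y) -y, s, y0 = 1)
  expect_equal(tr$status, "success")
  expect_lt(abs(tr$values[11, 1] - exp(-1)), 10 * 1e-6)
  s2 <- solver_settings("rk45", t_start = 0, t_end = 1, output_step = 0.1)
  tr2 <- integrate_ode(function(t, y) -y, s2, y0 = 1)
  expect_lt(abs(tr2$values[11, 1] - exp(-1)), 10 * 1e-6)
})

test_that("a linear chain matches its matrix-exponential solution", {
  m <- sbml_model(
    id = "chain2",
    compartments = list(sbml_compartment("c", 1)),
    species = list(sbml_species("A", "c", initial_concentration = 1),
                   sbml_species("B", "c", initial_concentration = 0)),
    parameters = list(sbml_parameter("k1", 1), sbml_parameter("k2", 3)),
    reactions = list(
      sbml_reaction("r1", reactants = c(A = 1), products = c(B = 1),
                    kinetic_law = "k1*A"),
      sbml_reaction("r2", reactants = c(B = 1), kinetic_law = "k2*B")))
  sys <- compile_system(m)
  for (method in c("rosenbrock", "rk45")) {
    s <- solver_settings(method, t_start = 0, t_end = 2,
                         output_step = 0.2)
    tr <- integrate_ode(sys, s)
    tt <- tr$times
    expect_equal(unname(tr$values[, "A"]), exp(-tt), tolerance = 1e-5)
    expect_equal(unname(tr$values[, "B"]),
                 (exp(-tt) - exp(-3 * tt)) / 2, tolerance = 1e-5)
  }
})

test_that("rosenbrock handles the stiff two-timescale system, rk45 fails", {
  A <- matrix(c(-1, 0, 0, -1e5), 2, 2)
  f <- function(t, y) A %*% y
  sros <- solver_settings("rosenbrock", t_start = 0, t_end = 1,
                          output_step = 0.1, max_steps = 10000L)
  tr <- integrate_ode(f, sros, y0 = c(1, 1))
  expect_equal(tr$status, "success")
  expect_lt(tr$n_steps, 1e4)
  expect_lt(abs(tr$values[11, 1] - exp(-1)), 1e-5)
  srk <- solver_settings("rk45", t_start = 0, t_end = 1,
                         output_step = 0.1, max_steps = 10000L)
  tr2 <- integrate_ode(f, srk, y0 = c(1, 1))
  expect_equal(tr2$status, "failure")
  expect_match(tr2$reason, "max_steps")
})

test_that("rosenbrock single steps converge at order >= 3", {
  exact <- function(t) (sin(t) - cos(t)) / 2 + 1.5 * exp(-t)
  f <- function(t, y) -y + sin(t)
  hs <- c(0.1, 0.05, 0.025)
  errs <- vapply(hs, function(h) {
    t <- 0; y <- 1
    while (t < 1 - 1e-12) {
      st <- rosenbrock_step(f, t, y, h)
      expect_true(st$ok)
      y <- st$y_new
      t <- t + h
    }
    abs(y - exact(1))
  }, numeric(1))
  fit <- lm(log(errs) ~ log(hs))
  expect_gte(unname(coef(fit)[2]), 3)
})

test_that("the stability function stays bounded for hl -> -inf", {
  for (z in c(-1e3, -1e6, -1e9)) {
    st <- rosenbrock_step(function(t, y) z * y, 0, 1, 1)
    expect_true(st$ok)
    expect_lte(abs(st$y_new), 1)
  }
})

test_that("the error estimate tracks the embedded local error", {
  f <- function(t, y) -y
  for (h in c(0.2, 0.1, 0.05)) {
    st <- rosenbrock_step(f, 0, 1, h)
    est <- abs(st$err)
    emb <- st$y_new - st$err         # embedded order-3 solution
    true_emb <- abs(emb - exp(-h))   # its closed-form local error
    expect_lt(est / true_emb, 10)
    expect_gt(est / true_emb, 1 / 10)
    # and the estimate bounds the (higher-order) taken-step error
    expect_lt(abs(st$y_new - exp(-h)), 10 * est)
  }
})

test_that("step controller follows the accept/propose contract", {
  r <- step_controller(1, 0.1, 4)
  expect_true(r$accept)
  expect_equal(r$h_next, 0.09)
  r0 <- step_controller(0, 0.1, 4)
  expect_true(r0$accept)
  expect_equal(r0$h_next, 0.5)       # clamped to 5x
  rbig <- step_controller(100, 0.1, 4)
  expect_false(rbig$accept)
  expect_gte(rbig$h_next, 0.02)      # clamped to 0.2x
  # deterministic replay of a recorded error sequence
  seq1 <- c(0.3, 1.2, 0.8, 0, 2.5, 0.99)
  replay <- function() {
    h <- 0.05
    path <- numeric(0)
    for (e in seq1) {
      r <- step_controller(e, h, 4)
      h <- r$h_next
      path <- c(path, h)
    }
    path
  }
  expect_identical(replay(), replay())
})

test_that("numerical_jacobian matches analytic Jacobians", {
  A <- matrix(c(-1, 2, 0.5, -3), 2, 2)
  J <- numerical_jacobian(function(t, y) A %*% y, 0, c(1, 2))
  expect_equal(J, A, tolerance = 1e-6)

  m <- sbml_model(
    id = "mmj",
    compartments = list(sbml_compartment("c", 1)),
    species = list(sbml_species("S", "c", initial_concentration = 1)),
    parameters = list(sbml_parameter("Vmax", 100),
                      sbml_parameter("Km", 1)),
    reactions = list(sbml_reaction("v", reactants = c(S = 1),
                                   kinetic_law = "Vmax*S/(Km+S)")))
  sys <- compile_system(m)
  J <- numerical_jacobian(sys, 0, c(S = 1))   # S = Km
  expect_equal(J[1, 1], -100 / 4, tolerance = 1e-5)
})

test_that("jacobian of random polynomial systems matches symbolic diff", {
  set.seed(31)
  vars <- c("u", "v")
  sym <- setNames(1:2, vars)
  for (rep in 1:20) {
    e1 <- random_mexpr(3, vars, polynomial = TRUE)
    e2 <- random_mexpr(3, vars, polynomial = TRUE)
    f <- function(t, y) {
      env <- list(u = y[1], v = y[2], time = t)
      c(oracle_eval(e1, env), oracle_eval(e2, env))
    }
    y <- runif(2, 0.5, 1.5)
    J <- numerical_jacobian(f, 0, y)
    env <- list(u = y[1], v = y[2], time = 0)
    Jsym <- matrix(c(oracle_eval(diff_mexpr(e1, "u"), env),
                     oracle_eval(diff_mexpr(e2, "u"), env),
                     oracle_eval(diff_mexpr(e1, "v"), env),
                     oracle_eval(diff_mexpr(e2, "v"), env)), 2, 2)
    expect_equal(J, Jsym, tolerance = 1e-5)
  }
})

test_that("tightening rel_tol never worsens the linear test battery", {
  battery <- list(
    list(f = function(t, y) -y, y0 = 1, sol = function(t) exp(-t)),
    list(f = function(t, y) matrix(c(-2, 1, 0, -0.5), 2, 2) %*% y,
         y0 = c(1, 1),
         sol = function(t) c(exp(-2 * t),
                             (5 / 3) * exp(-0.5 * t) -
                               (2 / 3) * exp(-2 * t))))
  for (case in battery) {
    errs <- vapply(c(1e-4, 1e-5, 1e-6), function(rt) {
      s <- solver_settings("rosenbrock", abs_tol = 1e-12, rel_tol = rt,
                           t_start = 0, t_end = 1, output_step = 1)
      tr <- integrate_ode(case$f, s, y0 = case$y0)
      max(abs(tr$values[2, ] - case$sol(1)))
    }, numeric(1))
    expect_true(all(diff(errs) <= 0))
  }
})

test_that("halving the output step leaves shared output values unchanged", {
  gen <- generate_chain_model(chain_model_spec(2, seed = 12))
  sys <- compile_system(gen$model)
  s1 <- solver_settings(t_start = 0, t_end = 100, output_step = 10)
  s2 <- solver_settings(t_start = 0, t_end = 100, output_step = 5)
  tr1 <- integrate_ode(sys, s1)
  tr2 <- integrate_ode(sys, s2)
  shared <- match(tr1$times, tr2$times)
  scale <- max(abs(tr1$values))
  expect_lt(max(abs(tr1$values - tr2$values[shared, ])),
            10 * 1e-6 * scale)
})

test_that("closed networks conserve total amount over the full span", {
  gen <- generate_chain_model(chain_model_spec(3, seed = 4,
                                               transport = FALSE))
  m <- gen$model
  m$species$M1_cell$initial_concentration <- 50   # something to convert
  sys <- compile_system(m)
  s <- solver_settings("rosenbrock", abs_tol = 1e-12, rel_tol = 1e-6,
                       t_start = 0, t_end = 240, output_step = 10)
  tr <- integrate_ode(sys, s)
  expect_equal(tr$status, "success")
  cells <- paste0("M", 1:3, "_cell")
  totals <- tr$values[, cells] %*% rep(0.01, 3)  # amounts = conc * volume
  expect_lt(max(abs(totals - totals[1])), 1e3 * 1e-12)
})

test_that("invalid solver settings raise configuration errors", {
  expect_error(solver_settings(abs_tol = 0), "configuration error")
  expect_error(solver_settings(t_start = 1, t_end = 0),
               "configuration error")
  expect_error(solver_settings(output_step = -1), "configuration error")
})

test_that("integration failure is a status, not an exception", {
  blow <- function(t, y) y^2
  s <- solver_settings("rk45", t_start = 0, t_end = 1, output_step = 0.1,
                       abs_tol = 1e-10, rel_tol = 1e-8)
  tr <- integrate_ode(blow, s, y0 = 1000)   # finite-time blow-up at 1e-3
  expect_equal(tr$status, "failure")
  expect_true(is.finite(tr$t_fail))
})
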