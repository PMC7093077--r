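# Optimizers and the fitness function.

sphere <- function(d = 5) list(fn = function(x) sum(x^2),
                               lower = rep(-5, d), upper = rep(5, d))

test_that("optimizers are seed-deterministic with monotone traces", {
  for (alg in c("de", "es", "pso", "hill_climbing",
                "simulated_annealing")) {
    cfg <- opt_config(alg, pop_size = 12, max_evals = 400, seed = 5)
    r1 <- estimate(sphere(3), cfg)
    r2 <- estimate(sphere(3), cfg)
    expect_identical(r1$best_par, r2$best_par, info = alg)
    expect_identical(r1$trace, r2$trace, info = alg)
    expect_true(all(diff(r1$trace[, "best"]) <= 0), info = alg)
    expect_equal(r1$best_fitness,
                 unname(r1$trace[nrow(r1$trace), "best"]), info = alg)
    # final best respects the box
    expect_true(all(r1$best_par >= -5 & r1$best_par <= 5), info = alg)
  }
})

test_that("DE converges to a box-corner optimum (reflection correctness)", {
  corner <- list(fn = function(x) (x[1] - 10)^2, lower = -1, upper = 2)
  r <- differential_evolution(corner,
                              opt_config("de", pop_size = 10,
                                         max_evals = 2000, seed = 1))
  expect_equal(unname(r$best_par), 2, tolerance = 1e-6)
})

test_that("degenerate init boxes pin generation zero only", {
  seen <- new.env()
  seen$xs <- list()
  prob <- list(fn = function(x) {
    seen$xs[[length(seen$xs) + 1L]] <- x
    sum((x - 1)^2)
  }, lower = c(-5, -5), upper = c(5, 5),
  init_lower = c(2, 2), init_upper = c(2, 2))
  # DE: generation zero is pinned at v (and a fully degenerate DE
  # population cannot move by construction)
  differential_evolution(prob, opt_config("de", pop_size = 8,
                                          max_evals = 16, seed = 2))
  gen0 <- do.call(rbind, seen$xs[1:8])
  expect_true(all(gen0 == 2))
  # ES: parents start at v, Gaussian mutation leaves v afterwards
  seen$xs <- list()
  r <- evolution_strategy(prob, opt_config("es", mu = 4, lambda = 8,
                                           max_evals = 100, seed = 2))
  gen0 <- do.call(rbind, seen$xs[1:4])
  expect_true(all(gen0 == 2))
  later <- do.call(rbind, seen$xs[-(1:4)])
  expect_true(any(later != 2))
  expect_lt(r$best_fitness, 2)
})

test_that("ES and PSO handle degenerate populations", {
  cfg <- opt_config("es", mu = 1, lambda = 1, max_evals = 50, seed = 3)
  r <- evolution_strategy(sphere(2), cfg)
  expect_s3_class(r, "estimation_result")
  expect_true(is.finite(r$best_fitness))
  expect_error(evolution_strategy(sphere(2),
                                  opt_config("es", mu = 5, lambda = 2)),
               "lambda")

  r2 <- particle_swarm(sphere(2), opt_config("pso", pop_size = 1,
                                             max_evals = 50, seed = 3))
  expect_true(is.finite(r2$best_fitness))

  expect_error(differential_evolution(sphere(2),
                                      opt_config("de", pop_size = 3)),
               "at least 4")
})

test_that("hill climbing converges on a 1-D quadratic; budget 1 returns the start", {
  quad <- list(fn = function(x) (x[1] - 0.3)^2, lower = -2, upper = 2)
  r <- hill_climbing(quad, opt_config("hill_climbing", max_evals = 2000,
                                      seed = 4))
  expect_equal(unname(r$best_par), 0.3, tolerance = 1e-3)
  r0 <- hill_climbing(quad, opt_config("hill_climbing", max_evals = 1,
                                       seed = 4))
  expect_equal(r0$n_evals, 1L)
})

test_that("simulated annealing escapes a wrong basin where hill climbing stalls", {
  dw <- list(fn = function(x) (x[1]^2 - 1)^2 + 0.4 * x[1],
             lower = -2, upper = 2, init_lower = 0.8, init_upper = 1.2)
  hc_hits <- 0; sa_hits <- 0
  for (s in 1:100) {
    rh <- hill_climbing(dw, opt_config("hill_climbing", max_evals = 2000,
                                       seed = s, sigma0 = 0.05))
    rs <- simulated_annealing(dw, opt_config("simulated_annealing",
                                             max_evals = 2000, seed = s,
                                             sigma0 = 0.05, T0 = 0.5))
    if (rh$best_par < 0) hc_hits <- hc_hits + 1
    if (rs$best_par < 0) sa_hits <- sa_hits + 1
  }
  expect_gte(sa_hits, 50)
  expect_lte(hc_hits, 10)
})

test_that("annealing at T -> 0 behaves like greedy descent", {
  quad <- list(fn = function(x) (x[1] - 0.3)^2, lower = -2, upper = 2)
  r <- simulated_annealing(quad, opt_config("simulated_annealing",
                                            max_evals = 1500, seed = 6,
                                            T0 = 1e-12, sigma0 = 0.1))
  expect_lt(r$best_fitness, 1e-3)
  expect_true(all(diff(r$trace[, "best"]) <= 0))
})

test_that("a sentinel-only landscape returns the sentinel without crashing", {
  bad <- list(fn = function(x) Inf, lower = c(0, 0), upper = c(1, 1))
  for (alg in c("de", "es", "pso", "hill_climbing",
                "simulated_annealing")) {
    r <- estimate(bad, opt_config(alg, pop_size = 6, max_evals = 60,
                                  seed = 1))
    expect_equal(r$best_fitness, 1e300, info = alg)
  }
})

test_that("estimate dispatches and logs progress", {
  cfg <- opt_config("de", pop_size = 8, max_evals = 80, seed = 9)
  r1 <- estimate(sphere(2), cfg)
  r2 <- differential_evolution(sphere(2), cfg)
  expect_identical(r1$best_par, r2$best_par)
  expect_error(opt_config("banana"), "configuration error")
  cfg$log_every <- 40L
  expect_message(estimate(sphere(2), cfg), "evals=40 best=")
})

test_that("fitness at the generating truth on noise-free data is ~zero", {
  fx <- make_study_fixture(chain_model_spec(2, seed = 21))
  pr <- fixture_problem(fx)
  f0 <- fitness_of(pr, unname(fx$truth[fx$free]))
  expect_lt(f0, 1e-6)
  # deterministic
  expect_identical(f0, fitness_of(pr, unname(fx$truth[fx$free])))
  # and consistent with the generic trajectory/quality path
  tr <- integrate_ode(pr$sys, pr$solver,
                      overrides = setNames(unname(fx$truth[fx$free]) * 1.5,
                                           pr$par_ids),
                      times = pr$data$times)
  expect_equal(fitness_of(pr, unname(fx$truth[fx$free]) * 1.5),
               evaluate_quality(pr$quality, tr, pr$data, pr$mapping),
               tolerance = 1e-12)
})

test_that("a diverging candidate yields the 1e300 sentinel", {
  m <- sbml_model(
    id = "boom",
    compartments = list(sbml_compartment("c", 1)),
    species = list(sbml_species("A", "c", initial_concentration = 1000)),
    parameters = list(sbml_parameter("k", NA_real_)),
    reactions = list(sbml_reaction("auto", reactants = c(A = 1),
                                   products = c(A = 2),
                                   kinetic_law = "k*A*A")))
  d <- dataset(c(0.5, 1), list(A = c(1, 1)))
  pr <- estimation_problem(
    m, d, column_mapping(A = "A"),
    list(parameter_spec("k", 1e-6, 10)),
    solver = solver_settings("rk45", abs_tol = 1e-10, rel_tol = 1e-8,
                             t_start = 0, t_end = 1, output_step = 0.1,
                             max_steps = 5000L))
  expect_identical(fitness_of(pr, 10), 1e300)   # blow-up in finite time
  expect_lt(fitness_of(pr, 1e-6), 1e300)
})
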