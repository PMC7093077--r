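# Data tables, mapping suggestion, parameter-range files.

test_that("CSV data files read with auto-detected separators", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,AS,ASL", "0,1.5,", "1,2.5,0.25"), p)
  d <- read_data_csv(p)
  expect_equal(d$times, c(0, 1))
  expect_equal(d$columns$AS, c(1.5, 2.5))
  expect_equal(d$columns$ASL, c(NA, 0.25))

  ptab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\tAS", "0\t1", "2\t3"), ptab)
  expect_equal(read_data_csv(ptab)$columns$AS, c(1, 3))

  # 2-row single-column file (first column assumed time)
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t0,v", "0,1", "1,2"), p1)
  expect_length(read_data_csv(p1)$times, 2)
})

test_that("bad tables raise format errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,A", "1,1", "1,2"), p)           # duplicated time
  expect_error(read_data_csv(p), "strictly increasing")
  writeLines(c("time,A", "2,1", "1,2"), p)           # decreasing
  expect_error(read_data_csv(p), "strictly increasing")
  writeLines(c("time,A", "x,y", "u,v"), p)           # nothing numeric
  expect_error(read_data_csv(p), "format error")
  expect_error(read_data_csv("/nonexistent/file.csv"), "no such file")
})

test_that("trajectory CSV writing round-trips at full precision", {
  gen <- generate_chain_model(chain_model_spec(1, seed = 2))
  sys <- compile_system(gen$model)
  s <- solver_settings(t_start = 0, t_end = 10, output_step = 1)
  tr <- integrate_ode(sys, s)
  p <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, p)
  d <- read_data_csv(p)
  expect_identical(d$times, tr$times)
  for (id in colnames(tr$values))
    expect_identical(d$columns[[id]], unname(tr$values[, id]), info = id)
  expect_false(anyNA(unlist(d$columns)))

  # 1-point trajectory -> header + one row
  tr1 <- make_trajectory(0, cbind(A = 1))
  write_trajectory_csv(tr1, p)
  expect_length(readLines(p), 2)
})

test_that("mapping suggestion uses exact > name > case-insensitive tiers", {
  model <- sbml_model(
    id = "m",
    compartments = list(sbml_compartment("c", 1)),
    species = list(
      sbml_species("AS", "c", initial_concentration = 1),
      sbml_species("sp1", "c", initial_concentration = 1,
                   name = "atorvastatin lactone"),
      sbml_species("ASL", "c", initial_concentration = 1)))
  d <- dataset(0:1, list(AS = c(1, 1), "atorvastatin lactone" = c(1, 1),
                         asl = c(1, 1), unrelated = c(1, 1)))
  map <- suggest_mapping(d, model)
  expect_equal(map$AS, "AS")                      # exact id
  expect_equal(map$`atorvastatin lactone`, "sp1") # exact name
  expect_equal(map$asl, "ASL")                    # case-insensitive
  expect_null(map$unrelated)
  # deterministic and idempotent
  expect_identical(suggest_mapping(d, model), map)
})

test_that("parameter-range files parse the study table rows", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# transport, fraction, Vmax rows",
               "Import_ASLpOH_k 1e-6 0.1 1e-6 0.1",
               "fu_AS 1e-6 1",
               "CYP3A4_ASoOH_Vmax 1e-6 100 1e-6 100"), p)
  specs <- read_parameter_ranges(p)
  expect_length(specs, 3)
  s1 <- specs[[1]]
  expect_equal(c(s1$init_min, s1$init_max, s1$min, s1$max),
               c(1e-6, 0.1, 1e-6, 0.1))
  # 3-field form: init interval equals the search interval
  s2 <- specs[[2]]
  expect_equal(s2$id, "fu_AS")
  expect_equal(c(s2$init_min, s2$init_max), c(1e-6, 1))
  expect_equal(c(s2$min, s2$max), c(1e-6, 1))
  s3 <- specs[[3]]
  expect_equal(c(s3$min, s3$max), c(1e-6, 100))

  writeLines("k 2 1", p)
  expect_error(read_parameter_ranges(p), "line 1")
  writeLines("k 1 2 3", p)
  expect_error(read_parameter_ranges(p), "expected 3 or 5")

  # write -> read round trip
  write_parameter_ranges(specs, p)
  expect_equal(read_parameter_ranges(p), specs)
})

test_that("parameter_spec enforces the interval invariant", {
  expect_error(parameter_spec("k", 0.5, 0.1), "min <= init_min")
  expect_error(parameter_spec("k", 0, 1, min = 0.5), "min <= init_min")
  expect_error(parameter_spec("k", 0, Inf), "finite")
  s <- parameter_spec("k", 0.2, 0.4, min = 0.1, max = 1, unit = "mL/min")
  expect_equal(s$unit, "mL/min")
})

test_that("subsample restricts to matching rows and rejects others", {
  d <- dataset(c(0, 1, 2, 3.5), list(A = 1:4))
  expect_equal(subsample(d, d$times), d)
  d2 <- subsample(d, c(0, 3.5))
  expect_equal(d2$times, c(0, 3.5))
  expect_equal(d2$columns$A, c(1L, 4L))
  expect_error(subsample(d, 1.7), "1.7")
})

test_that("estimation problems validate their pieces", {
  gen <- generate_chain_model(chain_model_spec(1, seed = 2))
  d <- make_artificial_dataset(gen$model, gen$truth,
                               times = c(10, 50, 100))
  specs <- list(parameter_spec("Import_M1_k", 1e-6, 0.1))
  pr <- estimation_problem(gen$model, d, specs = specs)
  expect_s3_class(pr, "estimation_problem")
  expect_error(estimation_problem(gen$model, d, specs = list()),
               "no parameter specs")
  expect_error(estimation_problem(
    gen$model, d, specs = list(parameter_spec("nope", 0, 1))),
    "not a model quantity")
})
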