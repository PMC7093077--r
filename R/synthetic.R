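# Synthetic compartmental chain models emulating the architecture of the
# atorvastatin biotransformation network: a medium and a cell
# compartment, first-order import/export transport scaled by an unbound
# fraction, and Michaelis-Menten enzymatic conversion of each
# intracellular metabolite into the next.  Used to run the whole
# estimation study without any external model download.
#
# Default magnitudes (chosen once, on physical grounds -- see the
# methods vignette): medium 1 mL, cell 0.01 mL, dose 100 pmol/mL of the
# first metabolite in the medium, a 240-minute observation span with 12
# log-spaced sampling times.  True values are drawn log-uniformly from
# the upper decades of the Table-1-style search boxes so that every
# drawn system shows observable dynamics on the span.

#' Specification of a synthetic chain model
#'
#' @param n_pairs Number of extracellular/intracellular metabolite pairs
#'   (>= 1).
#' @param seed Seed for the true-parameter draw.
#' @param medium_size,cell_size Compartment volumes (mL).
#' @param dose Initial medium concentration of the first metabolite
#'   (pmol/mL).
#' @param k_range,fu_range,vmax_range,km_range Log-uniform draw ranges
#'   for transport rate constants (mL/min), unbound fractions, enzyme
#'   Vmax (pmol/min) and Km (pmol/mL).
#' @param transport Include import/export reactions; `FALSE` leaves the
#'   closed enzymatic conversion chain (useful for conservation checks).
#' @param fu_on_export Whether the unbound fraction also scales the
#'   export reaction (the default); `FALSE` yields the constructed
#'   non-identifiable variant where `fu` appears only as a product with
#'   the import rate constant.
#' @return A `chain_model_spec`.
#' @export
chain_model_spec <- function(n_pairs = 3L, seed = 1L,
                             medium_size = 1, cell_size = 0.01,
                             dose = 100,
                             k_range = c(0.01, 0.1),
                             fu_range = c(0.25, 1),
                             vmax_range = c(5, 100),
                             km_range = c(2, 20),
                             transport = TRUE,
                             fu_on_export = TRUE) {
  stopifnot(n_pairs >= 1)
  structure(list(n_pairs = as.integer(n_pairs), seed = as.integer(seed),
                 medium_size = medium_size, cell_size = cell_size,
                 dose = dose, k_range = k_range, fu_range = fu_range,
                 vmax_range = vmax_range, km_range = km_range,
                 transport = isTRUE(transport),
                 fu_on_export = isTRUE(fu_on_export)),
            class = "chain_model_spec")
}

log_unif <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

#' Generate a compartmental Michaelis-Menten chain model
#'
#' Builds the SBML model described by the spec and draws its true
#' parameter values (log-uniform within the stated ranges, seeded).
#'
#' @param spec A [chain_model_spec].
#' @return `list(model, truth)` where `truth` is the named vector of
#'   drawn parameter values.
#' @export
generate_chain_model <- function(spec) {
  stopifnot(inherits(spec, "chain_model_spec"))
  n <- spec$n_pairs
  truth <- with_seed(spec$seed, {
    v <- c()
    for (i in seq_len(n)) {
      m <- paste0("M", i)
      if (spec$transport) {
        v[paste0("Import_", m, "_k")] <- log_unif(1, spec$k_range)
        v[paste0("Export_", m, "_k")] <- log_unif(1, spec$k_range)
        v[paste0("fu_", m)] <- log_unif(1, spec$fu_range)
      }
      if (i < n) {
        v[paste0("Enz_", m, "_Vmax")] <- log_unif(1, spec$vmax_range)
        v[paste0("Enz_", m, "_Km")] <- log_unif(1, spec$km_range)
      }
    }
    v
  })

  species <- list()
  reactions <- list()
  parameters <- list()
  for (i in seq_len(n)) {
    m <- paste0("M", i)
    species[[length(species) + 1L]] <- sbml_species(
      paste0(m, "_med"), "medium",
      initial_concentration = if (i == 1L) spec$dose else 0)
    species[[length(species) + 1L]] <- sbml_species(
      paste0(m, "_cell"), "cell", initial_concentration = 0)
    if (spec$transport) {
      ik <- paste0("Import_", m, "_k")
      ek <- paste0("Export_", m, "_k")
      fu <- paste0("fu_", m)
      parameters[[ik]] <- sbml_parameter(ik, truth[[ik]])
      parameters[[ek]] <- sbml_parameter(ek, truth[[ek]])
      parameters[[fu]] <- sbml_parameter(fu, truth[[fu]])
      reactions[[length(reactions) + 1L]] <- sbml_reaction(
        paste0("Import_", m),
        reactants = setNames(1, paste0(m, "_med")),
        products = setNames(1, paste0(m, "_cell")),
        kinetic_law = sprintf("%s * %s * %s_med", ik, fu, m))
      reactions[[length(reactions) + 1L]] <- sbml_reaction(
        paste0("Export_", m),
        reactants = setNames(1, paste0(m, "_cell")),
        products = setNames(1, paste0(m, "_med")),
        kinetic_law = if (spec$fu_on_export)
          sprintf("%s * %s * %s_cell", ek, fu, m)
        else sprintf("%s * %s_cell", ek, m))
    }
    if (i < n) {
      vm <- paste0("Enz_", m, "_Vmax")
      km <- paste0("Enz_", m, "_Km")
      parameters[[vm]] <- sbml_parameter(vm, truth[[vm]])
      parameters[[km]] <- sbml_parameter(km, truth[[km]])
      reactions[[length(reactions) + 1L]] <- sbml_reaction(
        paste0("Enz_", m),
        reactants = setNames(1, paste0(m, "_cell")),
        products = setNames(1, paste0("M", i + 1L, "_cell")),
        kinetic_law = sprintf("%s * %s_cell / (%s + %s_cell)",
                              vm, m, km, m))
    }
  }
  model <- sbml_model(
    id = sprintf("chain_%dpair", n),
    compartments = list(sbml_compartment("medium", spec$medium_size),
                        sbml_compartment("cell", spec$cell_size)),
    species = species, parameters = parameters, reactions = reactions)
  list(model = model, truth = truth)
}

#' Default log-spaced sampling times for the study
#' @param n_times Number of points.
#' @param t_end Span end (minutes).
#' @return Numeric vector.
#' @export
study_times <- function(n_times = 12L, t_end = 240) {
  exp(seq(log(t_end / 120), log(t_end), length.out = n_times))
}

study_solver <- function(t_end) {
  solver_settings("rosenbrock", abs_tol = 1e-12, rel_tol = 1e-6,
                  t_start = 0, t_end = t_end, output_step = t_end / 100)
}

#' Simulate artificial data from a model with known parameters
#'
#' Integrates with the study solver settings (Rosenbrock, absolute
#' tolerance 1e-12, relative tolerance 1e-6), samples all species at the
#' requested times and, when `noise_cv > 0`, multiplies every value by
#' `1 + noise_cv * N(0,1)` (seeded).
#'
#' @param model An [sbml_model].
#' @param truth Named vector of parameter values to substitute.
#' @param times Sampling times (within the simulation span).
#' @param noise_cv Multiplicative noise coefficient of variation (>= 0).
#' @param seed Noise seed.
#' @return A [dataset] with one column per species.
#' @export
make_artificial_dataset <- function(model, truth, times = study_times(),
                                    noise_cv = 0, seed = 1L) {
  stopifnot(noise_cv >= 0)
  sys <- compile_system(model)
  settings <- study_solver(max(times))
  traj <- integrate_ode(sys, settings, overrides = truth, times = times)
  if (!identical(traj$status, "success"))
    stop("artificial-data simulation failed: ", traj$reason, call. = FALSE)
  cols <- lapply(names(model$species), function(id) traj$values[, id])
  names(cols) <- names(model$species)
  if (noise_cv > 0) {
    cols <- with_seed(seed, lapply(cols, function(v)
      v * (1 + noise_cv * rnorm(length(v)))))
  }
  dataset(times, cols, source = "artificial")
}

# Table-1-style search box for a parameter id (init interval = search
# interval, as in the study).
study_box <- function(id) {
  if (grepl("_Vmax$", id)) c(1e-6, 100)
  else if (grepl("^fu_", id)) c(1e-6, 1)
  else if (grepl("_Km$", id)) c(1e-6, 100)
  else c(1e-6, 0.1)        # Import_/Export_ transport constants
}

default_free_parameters <- function(truth, n_pairs) {
  cand <- c("Import_M1_k", "Export_M1_k", "Enz_M1_Vmax", "Enz_M2_Vmax",
            "Import_M2_k")
  cand[cand %in% names(truth)]
}

#' Build a complete estimation-study fixture
#'
#' Simulates artificial data from a freshly drawn chain model, deletes
#' the fitted parameters from the model (values set to unknown), and
#' assembles the parameter boxes with Table-1-style scales (transport
#' [1e-6, 0.1], fractions [1e-6, 1], Vmax [1e-6, 100]; initialization
#' interval equal to the search interval).
#'
#' @param spec A [chain_model_spec].
#' @param times Sampling times.
#' @param noise_cv Multiplicative noise level (0 = noise-free).
#' @param free Character vector of parameter ids to estimate; defaults
#'   to five transport/Vmax parameters of the first two metabolites.
#' @return A `study_fixture`: `model` (parameters deleted), `data`,
#'   `specs`, `truth`, `free`, `solver`, and the generating `spec`.
#' @export
make_study_fixture <- function(spec = chain_model_spec(),
                               times = study_times(), noise_cv = 0,
                               free = NULL) {
  gen <- generate_chain_model(spec)
  if (is.null(free)) free <- default_free_parameters(gen$truth,
                                                     spec$n_pairs)
  stopifnot(length(free) > 0, all(free %in% names(gen$truth)))
  data <- make_artificial_dataset(gen$model, gen$truth, times, noise_cv,
                                  seed = spec$seed + 1000L)
  model <- gen$model
  for (id in free) model$parameters[[id]]$value <- NA_real_
  specs <- lapply(free, function(id) {
    box <- study_box(id)
    parameter_spec(id, box[1], box[2])
  })
  for (s in specs) {
    tv <- gen$truth[[s$id]]
    if (!(tv > s$min && tv < s$max))
      stop("true value of ", s$id, " not strictly inside its box",
           call. = FALSE)
  }
  structure(list(model = model, data = data, specs = specs,
                 truth = gen$truth, free = free,
                 solver = study_solver(max(times)), spec = spec),
            class = "study_fixture")
}

#' Estimation problem for a study fixture
#' @param fixture A `study_fixture`.
#' @return An [estimation_problem] (relative squared error, study solver
#'   settings, identity column mapping).
#' @export
fixture_problem <- function(fixture) {
  stopifnot(inherits(fixture, "study_fixture"))
  mapping <- do.call(column_mapping,
                     as.list(setNames(names(fixture$data$columns),
                                      names(fixture$data$columns))))
  estimation_problem(fixture$model, fixture$data, mapping,
                     fixture$specs,
                     quality = quality_spec("relative_squared_error"),
                     solver = fixture$solver)
}

#' Write the four fixture files consumed by the command-line interface
#'
#' `model.xml` (SBML), `data.csv`, `ranges.txt`, `truth.csv`.
#'
#' @param fixture A `study_fixture`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths.
#' @export
write_study_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(model = file.path(dir, "model.xml"),
             data = file.path(dir, "data.csv"),
             ranges = file.path(dir, "ranges.txt"),
             truth = file.path(dir, "truth.csv"))
  write_sbml(fixture$model, paths[["model"]])
  dcols <- c(list(time = fixture$data$times), fixture$data$columns)
  header <- paste(names(dcols), collapse = ",")
  rows <- vapply(seq_along(fixture$data$times), function(i)
    paste(sprintf("%.17g", vapply(dcols, `[`, 0, i)), collapse = ","),
    character(1))
  writeLines(c(header, rows), paths[["data"]])
  write_parameter_ranges(fixture$specs, paths[["ranges"]])
  writeLines(c("parameter,value",
               sprintf("%s,%.17g", names(fixture$truth), fixture$truth)),
             paths[["truth"]])
  invisible(paths)
}
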