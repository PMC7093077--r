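# Experimental-data tables, column-to-quantity mapping, and the plain-text
# parameter-range file format.

#' Construct a dataset
#'
#' @param times Strictly increasing numeric vector.
#' @param columns Named list (or data frame) of numeric series, each the
#'   same length as `times`; `NA` marks missing cells.
#' @param source Provenance string (file name).
#' @return A `dataset`.
#' @export
dataset <- function(times, columns, source = NA_character_) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0))
    stop("format error: time values must be strictly increasing",
         call. = FALSE)
  columns <- lapply(as.list(columns), as.numeric)
  bad <- names(columns)[vapply(columns, length, 0L) != length(times)]
  if (length(bad) > 0L)
    stop("format error: column length mismatch: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(times = times, columns = columns, source = source),
            class = "dataset")
}

#' @export
print.dataset <- function(x, ...) {
  cat(sprintf("<dataset: %d times x %d columns (%s)>\n", length(x$times),
              length(x$columns),
              if (is.na(x$source)) "in memory" else x$source))
  invisible(x)
}

#' Read a time-series data table
#'
#' Plain text, first row headers, comma- or tab-separated (auto-detected
#' from the header line), decimal point.  The time column is the one
#' named "time" (case-insensitive) or, failing that, the first column.
#' Empty cells become missing values.
#'
#' @param path File path.
#' @return A [dataset].
#' @export
read_data_csv <- function(path) {
  if (!file.exists(path))
    stop("format error: no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(df) == 0L || nrow(df) == 0L)
    stop("format error: empty table: ", path, call. = FALSE)
  nums <- vapply(df, is.numeric, logical(1))
  if (!any(nums))
    stop("format error: no numeric columns in ", path, call. = FALSE)
  tcol <- which(tolower(names(df)) == "time")
  tcol <- if (length(tcol) > 0L) tcol[1] else 1L
  times <- as.numeric(df[[tcol]])
  if (anyNA(times))
    stop("format error: missing values in the time column", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("format error: time values must be strictly increasing",
         call. = FALSE)
  cols <- df[-tcol]
  dataset(times, as.list(cols), source = basename(path))
}

#' Column mapping
#'
#' @param ... Named mapping pairs, data column name -> model quantity id,
#'   e.g. `column_mapping(AS = "AS", as_out = "AS_out")`, or a single
#'   named character vector.
#' @return A `column_mapping`.
#' @export
column_mapping <- function(...) {
  pairs <- c(...)
  if (length(pairs) > 0L)
    stopifnot(is.character(pairs), !is.null(names(pairs)),
              all(nzchar(names(pairs))))
  structure(as.list(pairs), class = "column_mapping")
}

mapping_pairs <- function(mapping) {
  if (inherits(mapping, "column_mapping")) return(unclass(mapping))
  if (is.character(mapping)) return(as.list(mapping))
  as.list(mapping)
}

#' Suggest a data-column to model-quantity mapping
#'
#' Deterministic tiered name matching against species, parameters and
#' compartments: exact id match, then exact name match, then
#' case-insensitive id/name match; columns without a match stay
#' unmapped.  No fuzzy matching, so the suggestion is explainable.
#'
#' @param data A [dataset].
#' @param model An [sbml_model].
#' @return A [column_mapping] (possibly empty).
#' @export
suggest_mapping <- function(data, model) {
  quantities <- c(model$species, model$parameters, model$compartments)
  ids <- vapply(quantities, `[[`, "", "id")
  nms <- vapply(quantities, function(q)
    if (is.null(q$name)) NA_character_ else q$name, character(1))
  out <- character(0)
  for (col in names(data$columns)) {
    hit <- ids[match(col, ids)]
    if (is.na(hit)) hit <- ids[match(col, nms)]
    if (is.na(hit)) hit <- ids[match(tolower(col), tolower(ids))]
    if (is.na(hit)) hit <- ids[match(tolower(col), tolower(nms))]
    if (!is.na(hit)) out[[col]] <- unname(hit)
  }
  do.call(column_mapping, list(out))
}

#' Parameter search-range specification
#'
#' `init_min`/`init_max` bound the random initialization of optimizer
#' populations; `min`/`max` bound the whole search.  The invariant
#' `min <= init_min <= init_max <= max` is enforced.
#'
#' @param id Model parameter id.
#' @param init_min,init_max Initialization interval.
#' @param min,max Search interval (defaults to the init interval).
#' @param unit Informational unit string.
#' @return A `parameter_spec`.
#' @export
parameter_spec <- function(id, init_min, init_max, min = init_min,
                           max = init_max, unit = "") {
  vals <- c(min, init_min, init_max, max)
  if (any(!is.finite(vals)))
    stop("parameter spec '", id, "': bounds must be finite",
         call. = FALSE)
  if (!(min <= init_min && init_min <= init_max && init_max <= max))
    stop("parameter spec '", id,
         "': need min <= init_min <= init_max <= max", call. = FALSE)
  structure(list(id = id, init_min = init_min, init_max = init_max,
                 min = min, max = max, unit = unit),
            class = "parameter_spec")
}

#' Read a parameter-range text file
#'
#' One record per line, whitespace- or tab-separated:
#' `id init_min init_max min max` (5 fields) or `id min max` (3 fields,
#' initialization interval equal to the search interval).  `#` starts a
#' comment.  Unknown ids are accepted here and checked at problem
#' assembly.
#'
#' @param path File path.
#' @return List of [parameter_spec].
#' @export
read_parameter_ranges <- function(path) {
  if (!file.exists(path))
    stop("format error: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  specs <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (!length(parts) %in% c(3L, 5L))
      stop("format error in ", path, " line ", i,
           ": expected 3 or 5 fields, got ", length(parts), call. = FALSE)
    nums <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(nums))
      stop("format error in ", path, " line ", i,
           ": non-numeric bound", call. = FALSE)
    spec <- tryCatch({
      if (length(parts) == 3L)
        parameter_spec(parts[1], nums[1], nums[2])
      else
        parameter_spec(parts[1], nums[1], nums[2], nums[3], nums[4])
    }, error = function(e)
      stop(conditionMessage(e), " (", path, " line ", i, ")",
           call. = FALSE))
    specs[[length(specs) + 1L]] <- spec
  }
  specs
}

#' Write parameter ranges in the text format read by
#' [read_parameter_ranges]
#' @param specs List of [parameter_spec].
#' @param path File path.
#' @export
write_parameter_ranges <- function(specs, path) {
  lines <- vapply(specs, function(s)
    sprintf("%s %.17g %.17g %.17g %.17g", s$id, s$init_min, s$init_max,
            s$min, s$max), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' First column `time`, then one column per reported quantity, full
#' double precision so that `read_data_csv` round-trips exactly.
#'
#' @param traj A success `trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  if (!identical(traj$status, "success"))
    stop("refusing to write a failed trajectory (", traj$reason, ")",
         call. = FALSE)
  header <- paste(c("time", colnames(traj$values)), collapse = ",")
  rows <- vapply(seq_along(traj$times), function(i)
    paste(sprintf("%.17g", c(traj$times[i], traj$values[i, ])),
          collapse = ","), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Restrict a dataset to selected time points
#'
#' @param data A [dataset].
#' @param times Times to keep; each must match a dataset time within
#'   `1e-9`.
#' @return The restricted [dataset].
#' @export
subsample <- function(data, times) {
  stopifnot(inherits(data, "dataset"))
  idx <- vapply(times, function(t) {
    j <- which(abs(data$times - t) <= 1e-9)
    if (length(j) == 0L) NA_integer_ else j[1]
  }, integer(1))
  if (anyNA(idx))
    stop("subsample error: times not in dataset: ",
         paste(times[is.na(idx)], collapse = ", "), call. = FALSE)
  dataset(data$times[idx], lapply(data$columns, `[`, idx),
          source = data$source)
}

#' Assemble an estimation problem
#'
#' Bundles everything a fitness evaluation needs; compiles the model
#' once and caches symbol indices of the fitted parameters.
#'
#' @param model An [sbml_model].
#' @param data A [dataset] of observations.
#' @param mapping A [column_mapping]; `NULL` uses [suggest_mapping].
#' @param specs Non-empty list of [parameter_spec]; each id must be a
#'   model parameter or species initial value.
#' @param quality A [quality_spec].
#' @param solver A [solver_settings]; the span must cover the data
#'   times.
#' @return An `estimation_problem`.
#' @export
estimation_problem <- function(model, data, mapping = NULL, specs,
                               quality = quality_spec(),
                               solver = NULL) {
  stopifnot(inherits(model, "sbml_model"), inherits(data, "dataset"))
  if (length(specs) == 0L)
    stop("configuration error: no parameter specs", call. = FALSE)
  if (inherits(specs, "parameter_spec")) specs <- list(specs)
  if (is.null(mapping)) mapping <- suggest_mapping(data, model)
  if (length(mapping_pairs(mapping)) == 0L)
    stop("configuration error: empty column mapping", call. = FALSE)
  if (is.null(solver)) {
    t1 <- max(data$times)
    solver <- solver_settings(t_start = 0, t_end = t1,
                              output_step = t1 / 100)
  }
  if (min(data$times) < solver$t_start - 1e-9 ||
      max(data$times) > solver$t_end + 1e-9)
    stop("configuration error: data times outside the integration span",
         call. = FALSE)
  sys <- compile_system(model)
  ids <- vapply(specs, `[[`, "", "id")
  for (id in ids) {
    if (is.na(sys$sym_index[id]))
      stop("configuration error: spec id '", id,
           "' is not a model quantity", call. = FALSE)
  }
  for (col in names(mapping_pairs(mapping))) {
    tgt <- mapping_pairs(mapping)[[col]]
    if (!tgt %in% sys$out_ids)
      stop("mapping error: '", tgt, "' is not a reported quantity",
           call. = FALSE)
  }
  problem <- structure(
    list(model = model, data = data, mapping = mapping,
         specs = specs, quality = quality, solver = solver,
         sys = sys, par_ids = ids,
         par_sym = as.integer(sys$sym_index[ids]),
         lower = vapply(specs, `[[`, 0, "min"),
         upper = vapply(specs, `[[`, 0, "max"),
         init_lower = vapply(specs, `[[`, 0, "init_min"),
         init_upper = vapply(specs, `[[`, 0, "init_max"),
         cache = new.env(parent = emptyenv())),
    class = "estimation_problem")
  prepare_fitness_cache(problem)
  problem
}

#' @export
print.estimation_problem <- function(x, ...) {
  cat(sprintf("<estimation_problem: %d parameters, %d data columns, %s>\n",
              length(x$specs), length(x$data$columns), x$quality$kind))
  invisible(x)
}
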