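# Quality (distance) functions between a simulated trajectory and an
# experimental dataset.  The estimation fitness is one of these.

#' Quality-function specification
#'
#' @param kind One of `"relative_squared_error"` (the estimation-study
#'   default), `"rmse"`, `"mean_absolute_error"`, `"euclidean"`.
#' @param epsilon Threshold below which an experimental value is treated
#'   as zero in the relative-squared-error denominator.
#' @return A `quality_spec`.
#' @export
quality_spec <- function(kind = c("relative_squared_error", "rmse",
                                  "mean_absolute_error", "euclidean"),
                         epsilon = 1e-10) {
  kind <- tryCatch(match.arg(kind), error = function(e)
    stop("configuration error: unknown quality kind '", kind[1], "'",
         call. = FALSE))
  structure(list(kind = kind, epsilon = epsilon), class = "quality_spec")
}

# Interpolate simulated column `id` at the data times (linear on the
# trajectory output grid).  Returns numeric vector aligned with
# data$times.
sim_at_data_times <- function(sim, id, data_times) {
  if (!id %in% colnames(sim$values))
    stop("mapping error: model quantity '", id,
         "' is not a trajectory column", call. = FALSE)
  y <- sim$values[, id]
  if (length(sim$times) == 1L) return(rep(y[1], length(data_times)))
  approx(sim$times, y, xout = data_times, rule = 2)$y
}

# Iterate over mapped (column, time) cells: calls fun(simval, dataval)
# on every non-missing cell, returns list of residual vectors per column.
mapped_cells <- function(sim, data, mapping) {
  stopifnot(inherits(data, "dataset"))
  map <- mapping_pairs(mapping)
  out <- list()
  for (col in names(map)) {
    if (!col %in% names(data$columns))
      stop("mapping error: data column '", col, "' not present",
           call. = FALSE)
    d <- data$columns[[col]]
    keep <- !is.na(d)
    if (!any(keep)) next
    s <- sim_at_data_times(sim, map[[col]], data$times[keep])
    out[[col]] <- list(sim = s, data = d[keep])
  }
  out
}

#' Relative squared error between simulation and data
#'
#' Sum over mapped columns c and data rows t of
#' `((sim_c(t) - data_c(t)) / d_c(t))^2`, where the denominator
#' `d_c(t)` is the experimental value itself when its magnitude exceeds
#' `epsilon`, otherwise the mean magnitude of the non-zero values of
#' column c; an all-zero column falls back to absolute squared error.
#' This makes columns on very different concentration scales
#' commensurable.  Missing data cells are skipped.
#'
#' @param sim A success `trajectory`.
#' @param data A `dataset`.
#' @param mapping A `column_mapping` (data column -> model quantity).
#' @param epsilon Zero-guard threshold for the denominator.
#' @return Non-negative scalar; 0 iff simulation equals data on every
#'   mapped cell.
#' @export
relative_squared_error <- function(sim, data, mapping, epsilon = 1e-10) {
  cells <- mapped_cells(sim, data, mapping)
  total <- 0
  for (cl in cells) {
    d <- cl$data
    nz <- abs(d) > epsilon
    denom <- abs(d)
    if (any(nz)) denom[!nz] <- mean(abs(d[nz])) else denom[] <- 1
    total <- total + sum(((cl$sim - d) / denom)^2)
  }
  total
}

#' Root-mean-square error over all mapped cells
#' @inheritParams relative_squared_error
#' @return Non-negative scalar.
#' @export
rmse <- function(sim, data, mapping) {
  cells <- mapped_cells(sim, data, mapping)
  sq <- unlist(lapply(cells, function(cl) (cl$sim - cl$data)^2))
  if (length(sq) == 0L) return(0)
  sqrt(mean(sq))
}

#' Mean absolute error over all mapped cells
#' @inheritParams relative_squared_error
#' @return Non-negative scalar.
#' @export
mean_absolute_error <- function(sim, data, mapping) {
  cells <- mapped_cells(sim, data, mapping)
  ab <- unlist(lapply(cells, function(cl) abs(cl$sim - cl$data)))
  if (length(ab) == 0L) return(0)
  mean(ab)
}

#' Euclidean distance over all mapped cells
#' @inheritParams relative_squared_error
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(sim, data, mapping) {
  cells <- mapped_cells(sim, data, mapping)
  sq <- unlist(lapply(cells, function(cl) (cl$sim - cl$data)^2))
  sqrt(sum(sq))
}

#' Evaluate a quality function
#'
#' Dispatches on the `quality_spec`; a failed trajectory maps to `Inf`
#' (the estimation layer converts this to a large finite sentinel so
#' that candidate ordering never meets IEEE infinity edge cases).
#'
#' @param spec A [quality_spec].
#' @inheritParams relative_squared_error
#' @return Non-negative scalar or `Inf` for a failed trajectory.
#' @export
evaluate_quality <- function(spec, sim, data, mapping) {
  stopifnot(inherits(spec, "quality_spec"))
  if (inherits(sim, "trajectory") && !identical(sim$status, "success"))
    return(Inf)
  switch(spec$kind,
         relative_squared_error =
           relative_squared_error(sim, data, mapping, spec$epsilon),
         rmse = rmse(sim, data, mapping),
         mean_absolute_error = mean_absolute_error(sim, data, mapping),
         euclidean = euclidean_distance(sim, data, mapping))
}
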