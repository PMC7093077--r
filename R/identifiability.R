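# Practical identifiability by repeated estimation: run the same
# estimation many times from independent random initializations, keep the
# best-fitting fraction, normalize each parameter estimate by its
# reference ("true" or published) value, and summarize the spread.  A
# small coefficient of variation across the retained runs marks a
# parameter as practically identifiable; a large one means the data do
# not constrain it.

#' Repeat an estimation with consecutive seeds
#'
#' Runs `n` independent estimations with seeds `seed0 ... seed0 + n - 1`.
#'
#' @param problem An [estimation_problem] (or benchmark list).
#' @param config An [opt_config]; its seed field is replaced per run.
#' @param n Number of runs (>= 2).
#' @param seed0 First seed.
#' @param progress Print a line per completed run.
#' @return A `run_ensemble`: list of `estimation_result`, the shared
#'   problem, and the seeds used.
#' @export
run_repeated <- function(problem, config, n, seed0 = 1L,
                         progress = FALSE) {
  if (n < 2L)
    stop("configuration error: need at least 2 runs", call. = FALSE)
  seeds <- seed0 + seq_len(n) - 1L
  results <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    results[[i]] <- estimate(problem, cfg)
    if (progress)
      message(sprintf("run %d/%d (seed %d): best %.6g", i, n, seeds[i],
                      results[[i]]$best_fitness))
  }
  run_ensemble(results, problem)
}

#' Bundle estimation results into an ensemble
#' @param results List of `estimation_result` (all from the same
#'   problem).
#' @param problem The shared problem (may be `NULL` for merged
#'   ensembles).
#' @return A `run_ensemble`.
#' @export
run_ensemble <- function(results, problem = NULL) {
  seeds <- vapply(results, `[[`, 0L, "seed")
  if (anyDuplicated(seeds))
    stop("ensemble seeds must be distinct", call. = FALSE)
  structure(list(results = results, problem = problem, seeds = seeds),
            class = "run_ensemble")
}

#' @export
print.run_ensemble <- function(x, ...) {
  fits <- vapply(x$results, `[[`, 0, "best_fitness")
  cat(sprintf("<run_ensemble: %d runs, best %.6g, worst %.6g>\n",
              length(x$results), min(fits), max(fits)))
  invisible(x)
}

#' Keep the best-fitting fraction of an ensemble
#'
#' Runs are sorted by final fitness (ascending, ties broken by seed for
#' determinism) and the first `ceiling(fraction * n)` are retained.
#'
#' @param ens A `run_ensemble`.
#' @param fraction In (0, 1]; the study default is 0.5.
#' @return The filtered `run_ensemble`.
#' @export
select_best_fraction <- function(ens, fraction = 0.5) {
  stopifnot(inherits(ens, "run_ensemble"))
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0, 1]", call. = FALSE)
  fits <- vapply(ens$results, `[[`, 0, "best_fitness")
  keep <- order(fits, ens$seeds)[seq_len(ceiling(fraction * length(fits)))]
  run_ensemble(ens$results[keep], ens$problem)
}

#' Normalize estimates by reference values and summarize the spread
#'
#' Each retained run's estimate of each parameter is divided by the
#' parameter's reference value; the report gives mean, standard
#' deviation and coefficient of variation of these ratios, plus an
#' identifiability flag `cv <= cv_threshold`.  Optional `products`
#' tracks derived quantities (products of parameters) the same way --
#' useful to show that an unidentifiable pair still has an identifiable
#' product.
#'
#' @param ens A `run_ensemble`.
#' @param reference Named numeric vector of reference (true) values;
#'   all must be non-zero.
#' @param cv_threshold CV at or below which a parameter is flagged
#'   identifiable (reported, never silently applied).
#' @param products Optional list of character vectors; each names
#'   parameters whose product is summarized as a derived row.
#' @return An `identifiability_report` data frame with columns
#'   `parameter`, `mean`, `sd`, `cv`, `identifiable`, plus attributes
#'   `retained` and `cv_threshold`.
#' @export
normalize_and_summarize <- function(ens, reference, cv_threshold = 0.2,
                                    products = NULL) {
  stopifnot(inherits(ens, "run_ensemble"))
  if (any(reference == 0))
    stop("zero reference value for: ",
         paste(names(reference)[reference == 0], collapse = ", "),
         call. = FALSE)
  est <- do.call(rbind, lapply(ens$results, function(r)
    r$best_par[names(reference)]))
  colnames(est) <- names(reference)
  if (anyNA(est))
    stop("ensemble results lack some reference parameters", call. = FALSE)
  rows <- list()
  add_row <- function(name, ratios) {
    m <- mean(ratios)
    s <- if (length(ratios) > 1L) sd(ratios) else 0
    cv <- if (m != 0) abs(s / m) else Inf
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, mean = m, sd = s, cv = cv,
      identifiable = cv <= cv_threshold, stringsAsFactors = FALSE)
  }
  for (p in names(reference))
    add_row(p, est[, p] / reference[[p]])
  for (pr in products) {
    ref <- prod(unlist(reference[pr]))
    vals <- apply(est[, pr, drop = FALSE], 1, prod)
    add_row(paste(pr, collapse = "*"), vals / ref)
  }
  report <- do.call(rbind, rows)
  attr(report, "retained") <- length(ens$results)
  attr(report, "cv_threshold") <- cv_threshold
  class(report) <- c("identifiability_report", "data.frame")
  report
}

#' Write an identifiability report as CSV
#' @param report An `identifiability_report`.
#' @param path File path.
#' @export
write_identifiability_csv <- function(report, path) {
  write.table(report, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Box-plot of normalized parameter estimates
#'
#' One box per parameter of estimate/reference ratios over the retained
#' runs, with a horizontal reference line at 1.
#'
#' @param ens A `run_ensemble` (after [select_best_fraction]).
#' @param reference Named numeric reference values.
#' @param path Output file; format from the extension (`.png` or
#'   `.pdf`; falls back to pdf when the png device is unavailable).
#' @return The path, invisibly.
#' @export
plot_distributions <- function(ens, reference, path) {
  stopifnot(inherits(ens, "run_ensemble"), length(reference) > 0)
  est <- do.call(rbind, lapply(ens$results, function(r)
    r$best_par[names(reference)]))
  ratios <- sweep(est, 2, unlist(reference), "/")
  ext <- if (grepl("\\.", basename(path)))
    tolower(sub(".*\\.", "", basename(path))) else ""
  if (ext == "png" && capabilities("png")) {
    grDevices::png(path, width = 900, height = 600)
  } else {
    if (ext == "png") path <- sub("\\.png$", ".pdf", path)
    grDevices::pdf(path, width = 9, height = 6)
  }
  on.exit(grDevices::dev.off())
  graphics::boxplot(as.data.frame(ratios), las = 2,
                    ylab = "estimated value / reference value",
                    main = sprintf("Normalized estimates over %d retained runs",
                                   nrow(ratios)))
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(path)
}
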