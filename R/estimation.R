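# Nature-inspired optimizers minimizing a quality function over the
# parameter box.  All algorithms are fully reproducible from their seed,
# report a monotone best-so-far trace, and treat integration failure as a
# large finite fitness sentinel (1e300) so ordering never involves IEEE
# infinities.

FITNESS_SENTINEL <- 1e300

#' Optimizer configuration
#'
#' @param algorithm One of `"de"`, `"es"`, `"pso"`, `"hill_climbing"`,
#'   `"simulated_annealing"`.
#' @param pop_size Population size (DE needs >= 4); default
#'   `min(10 * dimension, 100)`, resolved at run time.
#' @param max_evals Fitness-evaluation budget (>= pop_size).
#' @param seed Integer RNG seed; identical seeds give bitwise-identical
#'   results.
#' @param F,CR Differential evolution scale factor and crossover rate.
#' @param mu,lambda Evolution-strategy parent/offspring counts
#'   (comma selection); defaults mu = pop_size/4, lambda = pop_size.
#' @param sigma0 ES/hill-climbing initial step size as a fraction of the
#'   box width.
#' @param w,c1,c2 PSO inertia and acceleration coefficients.
#' @param T0,alpha Simulated-annealing start temperature and geometric
#'   cooling factor (applied per 100 evaluations).
#' @param log_every Progress-log interval in evaluations (0 = silent).
#' @return An `opt_config`.
#' @export
opt_config <- function(algorithm = c("de", "es", "pso", "hill_climbing",
                                     "simulated_annealing"),
                       pop_size = NA_integer_, max_evals = 20000L,
                       seed = 1L, F = 0.7, CR = 0.9,
                       mu = NA_integer_, lambda = NA_integer_,
                       sigma0 = 0.1, w = 0.729, c1 = 1.49445,
                       c2 = 1.49445, T0 = 1, alpha = 0.95,
                       log_every = 0L) {
  algorithm <- tryCatch(match.arg(algorithm), error = function(e)
    stop("configuration error: unknown algorithm '", algorithm[1], "'",
         call. = FALSE))
  structure(list(algorithm = algorithm, pop_size = pop_size,
                 max_evals = as.integer(max_evals), seed = as.integer(seed),
                 F = F, CR = CR, mu = mu, lambda = lambda, sigma0 = sigma0,
                 w = w, c1 = c1, c2 = c2, T0 = T0, alpha = alpha,
                 log_every = as.integer(log_every)),
            class = "opt_config")
}

# Precompute everything the per-candidate fitness evaluation needs:
# data matrix aligned with the mapped trajectory columns, quality
# denominators, solver constants, and (when the model has no assignment
# rules touching fitted initials) the initial state.  Called once at
# problem assembly; results live in problem$cache.
prepare_fitness_cache <- function(problem) {
  cache <- problem$cache
  map <- mapping_pairs(problem$mapping)
  ids <- unlist(map)                      # model quantity per data column
  D <- do.call(cbind, problem$data$columns[names(map)])
  cache$D <- D
  cache$col_idx <- match(ids, problem$sys$out_ids)
  # relative-squared-error denominators (column-wise zero guard)
  eps <- problem$quality$epsilon
  denom <- abs(D)
  for (j in seq_len(ncol(D))) {
    d <- D[, j]
    nz <- !is.na(d) & abs(d) > eps
    if (any(nz)) denom[!nz & !is.na(d), j] <- mean(abs(d[nz]))
    else denom[, j] <- 1
  }
  cache$denom <- denom
  cache$n_cells <- sum(!is.na(D))
  s <- problem$solver
  cache$times <- problem$data$times
  cache$hmax <- (s$t_end - s$t_start) / 10
  cache$h0 <- if (is.na(s$initial_step)) -1 else s$initial_step
  cache$method <- if (s$method == "rosenbrock") 1L else 2L
  cache$ros <- ros_tableau()
  cache$rk <- rk45_tableau()
  # initial state is parameter-independent unless assignment rules exist
  # or a fitted target is itself a species/compartment initial value
  plain_params <- all(problem$par_ids %in%
                        names(problem$model$parameters))
  cache$static_y0 <- if (length(problem$sys$spec$assignments) == 0L &&
                           plain_params)
    as.numeric(initial_state(problem$sys, s$t_start)) else NULL
  invisible(cache)
}

#' Fitness of a parameter vector
#'
#' Substitutes `x` into the model, integrates over the data span with
#' output exactly at the data time points, and evaluates the configured
#' quality function.  Any integration failure yields the finite sentinel
#' `1e300`.  Deterministic: the same `x` always gives the same value.
#'
#' @param problem An [estimation_problem].
#' @param x Numeric vector ordered like `problem$specs`.
#' @return Non-negative scalar fitness.
#' @export
fitness_of <- function(problem, x) {
  stopifnot(inherits(problem, "estimation_problem"))
  cache <- problem$cache
  if (is.null(cache$D)) prepare_fitness_cache(problem)
  s <- problem$solver
  xv <- as.numeric(x)
  y0 <- cache$static_y0
  if (is.null(y0))
    y0 <- as.numeric(initial_state(problem$sys, s$t_start,
                                   setNames(xv, problem$par_ids)))
  dummy <- function(t, y) numeric(0)
  r <- cpp_integrate(sys_ptr(problem$sys), dummy, FALSE, y0,
                     s$t_start, s$t_end, cache$times,
                     s$abs_tol, s$rel_tol, cache$h0, cache$hmax,
                     s$max_steps, cache$ros, cache$rk, cache$method,
                     problem$par_sym, xv)
  if (r$status != 0L) return(FITNESS_SENTINEL)
  S <- r$out[, cache$col_idx, drop = FALSE]
  q <- switch(problem$quality$kind,
    relative_squared_error =
      sum(((S - cache$D) / cache$denom)^2, na.rm = TRUE),
    rmse = sqrt(sum((S - cache$D)^2, na.rm = TRUE) / cache$n_cells),
    mean_absolute_error =
      sum(abs(S - cache$D), na.rm = TRUE) / cache$n_cells,
    euclidean = sqrt(sum((S - cache$D)^2, na.rm = TRUE)))
  if (!is.finite(q)) FITNESS_SENTINEL else q
}

# Resolve problem-or-benchmark into the internal optimization target.
# Benchmarks are lists: list(fn = function(x), lower, upper,
# init_lower = lower, init_upper = upper).
as_opt_target <- function(problem) {
  if (inherits(problem, "estimation_problem")) {
    list(fn = function(x) fitness_of(problem, x),
         lower = problem$lower, upper = problem$upper,
         init_lower = problem$init_lower, init_upper = problem$init_upper,
         par_ids = problem$par_ids)
  } else {
    stopifnot(is.list(problem), is.function(problem$fn))
    lower <- problem$lower; upper <- problem$upper
    list(fn = problem$fn, lower = lower, upper = upper,
         init_lower = if (is.null(problem$init_lower)) lower
                      else problem$init_lower,
         init_upper = if (is.null(problem$init_upper)) upper
                      else problem$init_upper,
         par_ids = if (is.null(problem$par_ids))
           paste0("x", seq_along(lower)) else problem$par_ids)
  }
}

safe_fn <- function(fn) function(x) {
  v <- fn(x)
  if (!is.finite(v) || v > FITNESS_SENTINEL) FITNESS_SENTINEL else v
}

reflect_into <- function(x, lo, hi) {
  for (k in 1:100) {
    below <- x < lo
    above <- x > hi
    if (!any(below) && !any(above)) break
    x[below] <- 2 * lo[below] - x[below]
    x[above] <- 2 * hi[above] - x[above]
  }
  pmin(pmax(x, lo), hi)
}

# shared bookkeeping -------------------------------------------------------

new_tracker <- function(log_every) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$best <- Inf
  env$best_x <- NULL
  env$trace_evals <- integer(0)
  env$trace_best <- numeric(0)
  env$log_every <- log_every
  env
}

track <- function(tr, x, f) {
  tr$n <- tr$n + 1L
  if (f < tr$best) {
    tr$best <- f
    tr$best_x <- x
    tr$trace_evals <- c(tr$trace_evals, tr$n)
    tr$trace_best <- c(tr$trace_best, f)
  }
  if (tr$log_every > 0L && tr$n %% tr$log_every == 0L)
    message(sprintf("evals=%d best=%.8g", tr$n, tr$best))
  f
}

finish_result <- function(tr, target, config, t0) {
  trace <- cbind(evals = c(tr$trace_evals, tr$n),
                 best = c(tr$trace_best, tr$best))
  structure(list(best_par = setNames(tr$best_x, target$par_ids),
                 best_fitness = tr$best,
                 trace = trace, n_evals = tr$n, seed = config$seed,
                 algorithm = config$algorithm,
                 elapsed = as.numeric(proc.time()[3] - t0)),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result [%s, seed %d]: best %.6g after %d evals>\n",
              x$algorithm, x$seed, x$best_fitness, x$n_evals))
  invisible(x)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

resolve_pop <- function(config, d, minimum = 1L) {
  p <- config$pop_size
  if (is.na(p)) p <- min(10L * d, 100L)
  p <- max(as.integer(p), minimum)
  if (config$max_evals < p)
    stop("configuration error: max_evals must be >= population size",
         call. = FALSE)
  p
}

init_population <- function(np, target) {
  d <- length(target$lower)
  matrix(runif(np * d, rep(target$init_lower, each = np),
               rep(target$init_upper, each = np)), nrow = np)
}

#' Differential evolution (DE/rand/1/bin)
#'
#' Initialization uniform in the init box; mutation
#' `v = a + F * (b - c)` over distinct non-target members; binomial
#' crossover with one forced component; greedy selection; out-of-box
#' components are reflected back into the search interval.
#'
#' @param problem An [estimation_problem] or a benchmark list
#'   `list(fn, lower, upper, ...)`.
#' @param config An [opt_config] (population >= 4).
#' @return An `estimation_result`.
#' @export
differential_evolution <- function(problem, config) {
  target <- as_opt_target(problem)
  fn <- safe_fn(target$fn)
  d <- length(target$lower)
  np <- resolve_pop(config, d)
  if (np < 4L)
    stop("configuration error: DE needs a population of at least 4",
         call. = FALSE)
  t0 <- proc.time()[3]
  tr <- new_tracker(config$log_every)
  with_seed(config$seed, {
    X <- init_population(np, target)
    fit <- numeric(np)
    for (i in seq_len(np)) fit[i] <- track(tr, X[i, ], fn(X[i, ]))
    while (tr$n + np <= config$max_evals) {
      for (i in seq_len(np)) {
        idx <- sample.int(np - 1L, 3L)
        idx[idx >= i] <- idx[idx >= i] + 1L
        v <- X[idx[1], ] + config$F * (X[idx[2], ] - X[idx[3], ])
        jr <- sample.int(d, 1L)
        cross <- runif(d) < config$CR
        cross[jr] <- TRUE
        u <- ifelse(cross, v, X[i, ])
        u <- reflect_into(u, target$lower, target$upper)
        fu <- track(tr, u, fn(u))
        if (fu <= fit[i]) {
          X[i, ] <- u
          fit[i] <- fu
        }
      }
    }
  })
  finish_result(tr, target, config, t0)
}

#' (mu, lambda) evolution strategy
#'
#' Comma selection with global log-normal step-size self-adaptation
#' (`tau = 1/sqrt(2 n)`); steps are fractions of the box width;
#' offspring are clipped into the search box.
#'
#' @inheritParams differential_evolution
#' @return An `estimation_result`.
#' @export
evolution_strategy <- function(problem, config) {
  target <- as_opt_target(problem)
  fn <- safe_fn(target$fn)
  d <- length(target$lower)
  lam <- config$lambda
  if (is.na(lam)) lam <- resolve_pop(config, d)
  mu <- config$mu
  if (is.na(mu)) mu <- max(1L, lam %/% 4L)
  if (lam < mu)
    stop("configuration error: lambda must be >= mu", call. = FALSE)
  if (config$max_evals < mu)
    stop("configuration error: max_evals too small", call. = FALSE)
  width <- target$upper - target$lower
  tau <- 1 / sqrt(2 * d)
  t0 <- proc.time()[3]
  tr <- new_tracker(config$log_every)
  with_seed(config$seed, {
    P <- init_population(mu, target)
    sig <- rep(config$sigma0, mu)
    pf <- numeric(mu)
    for (i in seq_len(mu)) pf[i] <- track(tr, P[i, ], fn(P[i, ]))
    while (tr$n + lam <= config$max_evals) {
      O <- matrix(0, lam, d)
      osig <- numeric(lam)
      of <- numeric(lam)
      for (k in seq_len(lam)) {
        p <- sample.int(mu, 1L)
        osig[k] <- sig[p] * exp(tau * rnorm(1))
        x <- P[p, ] + osig[k] * width * rnorm(d)
        x <- pmin(pmax(x, target$lower), target$upper)
        O[k, ] <- x
        of[k] <- track(tr, x, fn(x))
      }
      ord <- order(of)[seq_len(mu)]
      P <- O[ord, , drop = FALSE]
      sig <- osig[ord]
      pf <- of[ord]
    }
  })
  finish_result(tr, target, config, t0)
}

#' Particle swarm optimization
#'
#' Standard inertia-weight PSO (`w = 0.729`, `c1 = c2 = 1.49445`),
#' velocities clamped to 20% of the box width, positions clipped into
#' the box.
#'
#' @inheritParams differential_evolution
#' @return An `estimation_result`.
#' @export
particle_swarm <- function(problem, config) {
  target <- as_opt_target(problem)
  fn <- safe_fn(target$fn)
  d <- length(target$lower)
  np <- resolve_pop(config, d)
  width <- target$upper - target$lower
  vmax <- 0.2 * width
  t0 <- proc.time()[3]
  tr <- new_tracker(config$log_every)
  with_seed(config$seed, {
    X <- init_population(np, target)
    V <- matrix(runif(np * d, rep(-vmax, each = np),
                      rep(vmax, each = np)), nrow = np)
    pbest <- X
    pfit <- numeric(np)
    for (i in seq_len(np)) pfit[i] <- track(tr, X[i, ], fn(X[i, ]))
    g <- which.min(pfit)
    gbest <- pbest[g, ]
    gfit <- pfit[g]
    while (tr$n + np <= config$max_evals) {
      for (i in seq_len(np)) {
        r1 <- runif(d); r2 <- runif(d)
        V[i, ] <- config$w * V[i, ] +
          config$c1 * r1 * (pbest[i, ] - X[i, ]) +
          config$c2 * r2 * (gbest - X[i, ])
        V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
        X[i, ] <- pmin(pmax(X[i, ] + V[i, ], target$lower), target$upper)
        f <- track(tr, X[i, ], fn(X[i, ]))
        if (f < pfit[i]) {
          pfit[i] <- f
          pbest[i, ] <- X[i, ]
          if (f < gfit) {
            gfit <- f
            gbest <- X[i, ]
          }
        }
      }
    }
  })
  finish_result(tr, target, config, t0)
}

#' (1+1) hill climbing with 1/5-success step adaptation
#'
#' Gaussian perturbations with step size starting at `sigma0` (fraction
#' of box width), multiplied by 1.5 or divided by 1.5 every 20 moves
#' depending on whether more or fewer than 1/5 succeeded.
#'
#' @inheritParams differential_evolution
#' @return An `estimation_result`.
#' @export
hill_climbing <- function(problem, config) {
  target <- as_opt_target(problem)
  fn <- safe_fn(target$fn)
  d <- length(target$lower)
  width <- target$upper - target$lower
  t0 <- proc.time()[3]
  tr <- new_tracker(config$log_every)
  with_seed(config$seed, {
    x <- runif(d, target$init_lower, target$init_upper)
    fx <- track(tr, x, fn(x))
    sig <- config$sigma0
    succ <- 0L
    tried <- 0L
    while (tr$n < config$max_evals) {
      y <- pmin(pmax(x + sig * width * rnorm(d), target$lower),
                target$upper)
      fy <- track(tr, y, fn(y))
      tried <- tried + 1L
      if (fy <= fx) {
        x <- y
        fx <- fy
        succ <- succ + 1L
      }
      if (tried == 20L) {
        sig <- if (succ > 4L) sig * 1.5 else sig / 1.5
        sig <- min(max(sig, 1e-12), 1)
        succ <- 0L
        tried <- 0L
      }
    }
  })
  finish_result(tr, target, config, t0)
}

#' Simulated annealing
#'
#' Metropolis acceptance `exp(-delta/T)` with geometric cooling
#' `T = T0 * alpha^(evals/100)`; proposals as in [hill_climbing] with a
#' fixed step.
#'
#' @inheritParams differential_evolution
#' @return An `estimation_result`.
#' @export
simulated_annealing <- function(problem, config) {
  target <- as_opt_target(problem)
  fn <- safe_fn(target$fn)
  d <- length(target$lower)
  width <- target$upper - target$lower
  t0 <- proc.time()[3]
  tr <- new_tracker(config$log_every)
  with_seed(config$seed, {
    x <- runif(d, target$init_lower, target$init_upper)
    fx <- track(tr, x, fn(x))
    while (tr$n < config$max_evals) {
      temp <- config$T0 * config$alpha^(tr$n / 100)
      y <- pmin(pmax(x + config$sigma0 * width * rnorm(d), target$lower),
                target$upper)
      fy <- track(tr, y, fn(y))
      if (fy <= fx || runif(1) < exp(-(fy - fx) / max(temp, 1e-300))) {
        x <- y
        fx <- fy
      }
    }
  })
  finish_result(tr, target, config, t0)
}

#' Run the configured optimizer on an estimation problem
#'
#' Dispatches on `config$algorithm`; progress lines
#' `evals=<n> best=<fitness>` go to the message stream every
#' `log_every` evaluations.
#'
#' @inheritParams differential_evolution
#' @return An `estimation_result`.
#' @export
estimate <- function(problem, config) {
  stopifnot(inherits(config, "opt_config"))
  switch(config$algorithm,
         de = differential_evolution(problem, config),
         es = evolution_strategy(problem, config),
         pso = particle_swarm(problem, config),
         hill_climbing = hill_climbing(problem, config),
         simulated_annealing = simulated_annealing(problem, config))
}
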