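# Independent oracles, written against the document/expression structure
# directly so they share no code path with the compiled evaluators.

# -- recursive expression evaluator (independent of eval_math and of the
#    bytecode VM) -----------------------------------------------------------
oracle_eval <- function(e, env, fundefs = NULL) {
  k <- e$kind
  if (k == "const") return(e$value)
  if (k == "name") {
    v <- env[[e$name]]
    if (is.null(v)) stop("oracle: unbound ", e$name)
    return(v)
  }
  op <- e$op
  if (op == "piecewise") {
    n <- length(e$args)
    i <- 1L
    while (i + 1L <= n) {
      if (oracle_eval(e$args[[i + 1L]], env, fundefs) != 0)
        return(oracle_eval(e$args[[i]], env, fundefs))
      i <- i + 2L
    }
    if (n %% 2L == 1L) return(oracle_eval(e$args[[n]], env, fundefs))
    return(NaN)
  }
  a <- lapply(e$args, oracle_eval, env = env, fundefs = fundefs)
  two <- function(f) Reduce(f, a)
  switch(op,
    add = two(`+`), mul = two(`*`),
    sub = if (length(a) == 1) -a[[1]] else two(`-`),
    div = a[[1]] / a[[2]], pow = a[[1]]^a[[2]], neg = -a[[1]],
    exp = exp(a[[1]]), ln = log(a[[1]]), log10 = log10(a[[1]]),
    sqrt = sqrt(a[[1]]), abs = abs(a[[1]]), floor = floor(a[[1]]),
    ceiling = ceiling(a[[1]]),
    sin = sin(a[[1]]), cos = cos(a[[1]]), tan = tan(a[[1]]),
    arcsin = asin(a[[1]]), arccos = acos(a[[1]]), arctan = atan(a[[1]]),
    sinh = sinh(a[[1]]), cosh = cosh(a[[1]]), tanh = tanh(a[[1]]),
    min = min(unlist(a)), max = max(unlist(a)),
    gt = (a[[1]] > a[[2]]) + 0, geq = (a[[1]] >= a[[2]]) + 0,
    lt = (a[[1]] < a[[2]]) + 0, leq = (a[[1]] <= a[[2]]) + 0,
    eq = (a[[1]] == a[[2]]) + 0, neq = (a[[1]] != a[[2]]) + 0,
    and = as.numeric(all(unlist(a) != 0)),
    or = as.numeric(any(unlist(a) != 0)),
    not = as.numeric(a[[1]] == 0),
    xor = as.numeric(sum(unlist(a) != 0) %% 2 == 1),
    {
      fd <- fundefs[[op]]
      if (is.null(fd)) stop("oracle: unknown op ", op)
      env2 <- as.list(setNames(a, fd$args))
      oracle_eval(fd$body, env2, fundefs)
    })
}

# -- naive document-walking derivative interpreter --------------------------
# Walks the sbml_model directly: no stoichiometry matrix, no symbol table,
# no bytecode.  Assignment rules are applied by fix-point iteration rather
# than topological order.
naive_derivatives <- function(model, t, y, overrides = numeric(0)) {
  env <- list(time = t)
  for (cp in model$compartments) env[[cp$id]] <- cp$size
  sz <- function(id) model$compartments[[id]]$size
  for (sp in model$species) {
    v <- if (!is.na(sp$initial_concentration)) {
      if (sp$has_only_substance_units)
        sp$initial_concentration * sz(sp$compartment)
      else sp$initial_concentration
    } else if (!is.na(sp$initial_amount)) {
      if (sp$has_only_substance_units) sp$initial_amount
      else sp$initial_amount / sz(sp$compartment)
    } else NA_real_
    env[[sp$id]] <- v
  }
  for (p in model$parameters) env[[p$id]] <- p$value
  for (nm in names(overrides)) env[[nm]] <- overrides[[nm]]
  # overwrite dynamic species from the state vector (amounts)
  for (id in names(y)) {
    sp <- model$species[[id]]
    if (!is.null(sp)) {
      env[[id]] <- if (sp$has_only_substance_units) y[[id]]
                   else y[[id]] / sz(sp$compartment)
    } else env[[id]] <- y[[id]]
  }
  fundefs <- lapply(model$functions, function(f)
    list(args = f$args, body = f$body))
  asg <- Filter(function(r) r$kind == "assignment", model$rules)
  for (pass in seq_len(max(1L, length(asg)))) {
    for (ru in asg)
      env[[ru$variable]] <- oracle_eval(ru$math, env, fundefs)
  }
  dy <- setNames(rep(0, length(y)), names(y))
  for (rx in model$reactions) {
    renv <- env
    for (i in seq_along(rx$local_parameters))
      renv[[names(rx$local_parameters)[i]]] <- rx$local_parameters[[i]]
    v <- oracle_eval(rx$kinetic_law, renv, fundefs)
    for (i in seq_along(rx$reactants)) {
      id <- names(rx$reactants)[i]
      sp <- model$species[[id]]
      if (id %in% names(dy) && !sp$boundary_condition && !sp$constant)
        dy[[id]] <- dy[[id]] - rx$reactants[[i]] * v
    }
    for (i in seq_along(rx$products)) {
      id <- names(rx$products)[i]
      sp <- model$species[[id]]
      if (id %in% names(dy) && !sp$boundary_condition && !sp$constant)
        dy[[id]] <- dy[[id]] + rx$products[[i]] * v
    }
  }
  for (ru in model$rules) {
    if (ru$kind != "rate") next
    val <- oracle_eval(ru$math, env, fundefs)
    sp <- model$species[[ru$variable]]
    conv <- if (!is.null(sp) && !sp$has_only_substance_units)
      sz(sp$compartment) else 1
    dy[[ru$variable]] <- dy[[ru$variable]] + conv * val
  }
  dy
}

# -- symbolic differentiation for polynomial expressions --------------------
diff_mexpr <- function(e, var) {
  cst <- function(v) sbmlfit:::mx_const(v)
  if (e$kind == "const") return(cst(0))
  if (e$kind == "name") return(cst(as.numeric(e$name == var)))
  op <- e$op
  a <- e$args
  call2 <- sbmlfit:::mx_call
  switch(op,
    add = call2("add", lapply(a, diff_mexpr, var = var)),
    sub = call2("sub", lapply(a, diff_mexpr, var = var)),
    neg = call2("neg", diff_mexpr(a[[1]], var)),
    mul = {
      stopifnot(length(a) == 2)
      call2("add",
            call2("mul", diff_mexpr(a[[1]], var), a[[2]]),
            call2("mul", a[[1]], diff_mexpr(a[[2]], var)))
    },
    pow = {
      stopifnot(a[[2]]$kind == "const")
      n <- a[[2]]$value
      call2("mul", cst(n),
            call2("mul", call2("pow", a[[1]], cst(n - 1)),
                  diff_mexpr(a[[1]], var)))
    },
    stop("diff_mexpr: unsupported op ", op))
}

# -- random expression generator --------------------------------------------
random_mexpr <- function(depth, vars, polynomial = FALSE) {
  cst <- sbmlfit:::mx_const
  nme <- sbmlfit:::mx_name
  call2 <- sbmlfit:::mx_call
  if (depth <= 0 || runif(1) < 0.3) {
    if (runif(1) < 0.5) return(cst(round(runif(1, -3, 3), 3)))
    return(nme(sample(vars, 1)))
  }
  ops <- if (polynomial) c("add", "sub", "mul", "neg", "pow")
         else c("add", "sub", "mul", "div", "neg", "exp", "sin", "cos",
                "tanh", "abs", "min", "max", "piecewise", "pow")
  op <- sample(ops, 1)
  rec <- function() random_mexpr(depth - 1, vars, polynomial)
  switch(op,
    neg = call2("neg", rec()),
    exp = , sin = , cos = , tanh = , abs = call2(op, rec()),
    pow = call2("pow", rec(), cst(sample(0:3, 1))),
    piecewise = call2("piecewise", rec(),
                      call2("gt", rec(), cst(0)), rec()),
    min = , max = call2(op, rec(), rec()),
    call2(op, rec(), rec()))
}

# -- shared fixtures --------------------------------------------------------
fixture_models <- function() {
  one <- generate_chain_model(chain_model_spec(1, seed = 2))
  three <- generate_chain_model(chain_model_spec(3, seed = 3))
  closed <- generate_chain_model(chain_model_spec(3, seed = 4,
                                                  transport = FALSE))
  # small model exercising rules, locals, functions and an event
  misc <- sbml_model(
    id = "misc",
    compartments = list(sbml_compartment("c", 2)),
    species = list(
      sbml_species("A", "c", initial_concentration = 5),
      sbml_species("B", "c", initial_amount = 1),
      sbml_species("Bnd", "c", initial_concentration = 1,
                   boundary_condition = TRUE)),
    parameters = list(sbml_parameter("k", 0.4),
                      sbml_parameter("scale", 2),
                      sbml_parameter("drv", 0.1, constant = FALSE),
                      sbml_parameter("tot", NA_real_, constant = FALSE)),
    reactions = list(
      sbml_reaction("r1", reactants = c(A = 1), products = c(B = 1),
                    kinetic_law = "kk * A * c * Bnd",
                    local_parameters = c(kk = 0.7)),
      sbml_reaction("r2", reactants = c(B = 1), products = c(A = 1),
                    kinetic_law = "hill(B, k, scale) * c")),
    rules = list(sbml_rule("assignment", "tot", "(A + B) * scale"),
                 sbml_rule("rate", "drv", "0.5 * tot")),
    events = list(sbml_event("e1", "time >= 1000",
                             list(drv = "0"))),
    functions = list(sbml_function("hill", c("x", "K", "n"),
                                   "x^n / (K^n + x^n)")))
  list(one_pair = one$model, three_pair = three$model,
       closed = closed$model, misc = misc)
}

random_state <- function(sys, scale = 10) {
  y <- runif(length(sys$state_ids), 0.01, scale)
  setNames(y, sys$state_ids)
}

# -- double-loop quality reference ------------------------------------------
oracle_rse <- function(sim, data, mapping, epsilon = 1e-10) {
  map <- unclass(mapping)
  total <- 0
  for (col in names(map)) {
    d <- data$columns[[col]]
    id <- map[[col]]
    nzmean <- mean(abs(d[!is.na(d) & abs(d) > epsilon]))
    for (i in seq_along(data$times)) {
      if (is.na(d[i])) next
      sv <- approx(sim$times, sim$values[, id], xout = data$times[i],
                   rule = 2)$y
      den <- if (abs(d[i]) > epsilon) abs(d[i])
             else if (is.finite(nzmean)) nzmean else 1
      total <- total + ((sv - d[i]) / den)^2
    }
  }
  total
}

oracle_rmse <- function(sim, data, mapping) {
  map <- unclass(mapping)
  sq <- c()
  for (col in names(map)) {
    d <- data$columns[[col]]
    for (i in seq_along(data$times)) {
      if (is.na(d[i])) next
      sv <- approx(sim$times, sim$values[, map[[col]]],
                   xout = data$times[i], rule = 2)$y
      sq <- c(sq, (sv - d[i])^2)
    }
  }
  sqrt(mean(sq))
}

make_trajectory <- function(times, values, status = "success") {
  structure(list(times = times, values = values,
                 column_ids = colnames(values), status = status,
                 reason = NA_character_, t_fail = NA_real_, n_steps = 0L),
            class = "trajectory")
}
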