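# Compile a model document into an executable ODE system:
#   dy/dt = N %*% v(y, t)  (+ rate-rule contributions)
# The state vector holds AMOUNTS for species (stoichiometric bookkeeping
# is exact under constant volume); kinetic laws see concentrations unless
# a species hasOnlySubstanceUnits.  Local reaction parameters are
# name-mangled "<reactionId>.<paramId>" into one flat symbol table.

#' Compile a model into an executable ODE system
#'
#' @param model A validated [sbml_model] (error findings abort).
#' @return A `compiled_system` holding the state layout (non-constant,
#'   non-boundary species in document order, then rate-rule variables),
#'   the stoichiometry matrix `N`, compiled rate/rule/event evaluators and
#'   the constant symbol table.
#' @export
compile_system <- function(model) {
  fnd <- validate_model(model)
  err <- fnd[fnd$severity == "error", , drop = FALSE]
  if (nrow(err) > 0L)
    stop("cannot compile invalid model: ",
         paste(sprintf("[%s] %s", err$entity, err$message),
               collapse = "; "), call. = FALSE)

  for (ru in model$rules)
    if (!is.null(model$compartments[[ru$variable]]))
      stop("unsupported construct: rule on compartment '", ru$variable,
           "'", call. = FALSE)

  fundefs <- lapply(model$functions, function(fd)
    list(args = fd$args, body = fd$body))

  # ---- flat symbol table -------------------------------------------------
  sym <- character(0)
  add_sym <- function(id) sym[[length(sym) + 1L]] <<- id
  for (cp in model$compartments) add_sym(cp$id)
  for (sp in model$species) add_sym(sp$id)
  for (p in model$parameters) add_sym(p$id)
  local_names <- list()
  for (rx in model$reactions) {
    if (length(rx$local_parameters) > 0L) {
      mangled <- paste0(rx$id, ".", names(rx$local_parameters))
      local_names[[rx$id]] <- setNames(mangled,
                                       names(rx$local_parameters))
      for (m in mangled) add_sym(m)
    }
  }
  sym_index <- setNames(seq_along(sym), sym)

  comp_size <- function(id) model$compartments[[id]]$size

  template <- rep(NA_real_, length(sym))
  for (cp in model$compartments) template[sym_index[[cp$id]]] <- cp$size
  for (sp in model$species) {
    v <- if (!is.na(sp$initial_concentration)) {
      if (sp$has_only_substance_units)
        sp$initial_concentration * comp_size(sp$compartment)
      else sp$initial_concentration
    } else if (!is.na(sp$initial_amount)) {
      if (sp$has_only_substance_units) sp$initial_amount
      else sp$initial_amount / comp_size(sp$compartment)
    } else NA_real_
    template[sym_index[[sp$id]]] <- v
  }
  for (p in model$parameters) template[sym_index[[p$id]]] <- p$value
  for (rx in model$reactions)
    for (lp in seq_along(rx$local_parameters))
      template[sym_index[[local_names[[rx$id]][lp]]]] <-
        rx$local_parameters[[lp]]

  # ---- state layout ------------------------------------------------------
  rule_vars <- vapply(model$rules, `[[`, "", "variable")
  rate_vars <- rule_vars[vapply(model$rules, function(r)
    r$kind == "rate", logical(1))]
  state_ids <- character(0)
  state_sym <- integer(0)
  state_conv <- numeric(0)     # context value = y / conv
  state_kind <- character(0)
  for (sp in model$species) {
    if (sp$constant || sp$boundary_condition) next
    if (sp$id %in% rule_vars) {
      if (sp$id %in% rate_vars)
        stop("species '", sp$id, "' has a rate rule but is not a ",
             "boundary species", call. = FALSE)
      stop("species '", sp$id, "' has an assignment rule but is not a ",
           "boundary species", call. = FALSE)
    }
    state_ids <- c(state_ids, sp$id)
    state_sym <- c(state_sym, sym_index[[sp$id]])
    state_conv <- c(state_conv,
                    if (sp$has_only_substance_units) 1
                    else comp_size(sp$compartment))
    state_kind <- c(state_kind, "species")
  }
  n_species_state <- length(state_ids)
  for (v in rate_vars) {
    sp <- model$species[[v]]
    conv <- if (!is.null(sp) && !sp$has_only_substance_units)
      comp_size(sp$compartment) else 1
    state_ids <- c(state_ids, v)
    state_sym <- c(state_sym, sym_index[[v]])
    state_conv <- c(state_conv, conv)
    state_kind <- c(state_kind, "rate_rule")
  }
  n_state <- length(state_ids)

  # ---- stoichiometry matrix ---------------------------------------------
  n_rxn <- length(model$reactions)
  N <- matrix(0, nrow = n_state, ncol = n_rxn,
              dimnames = list(state_ids, names(model$reactions)))
  for (j in seq_len(n_rxn)) {
    rx <- model$reactions[[j]]
    for (i in seq_along(rx$reactants)) {
      sid <- names(rx$reactants)[i]
      if (sid %in% state_ids)
        N[sid, j] <- N[sid, j] - rx$reactants[[i]]
    }
    for (i in seq_along(rx$products)) {
      sid <- names(rx$products)[i]
      if (sid %in% state_ids)
        N[sid, j] <- N[sid, j] + rx$products[[i]]
    }
  }

  # ---- compiled programs -------------------------------------------------
  compile1 <- function(e, rxn_id = NULL) {
    e <- inline_functions(e, fundefs)
    if (!is.null(rxn_id) && !is.null(local_names[[rxn_id]])) {
      # rename local parameters to their mangled slots
      ren <- local_names[[rxn_id]]
      rename <- function(x) {
        switch(x$kind,
          const = x,
          name = if (!is.null(ren[x$name]) && !is.na(ren[x$name]))
            mx_name(ren[[x$name]]) else x,
          call = mx_call(x$op, lapply(x$args, rename)))
      }
      e <- rename(e)
    }
    compile_expr(e, sym_index)
  }

  rates <- vector("list", n_rxn)
  for (j in seq_len(n_rxn)) {
    rx <- model$reactions[[j]]
    if (is.null(rx$kinetic_law))
      stop("reaction '", rx$id, "' has no kinetic law", call. = FALSE)
    rates[[j]] <- compile1(rx$kinetic_law, rx$id)
  }

  asg_order <- order_assignments(model$rules)
  assignments <- lapply(asg_order, function(i) {
    ru <- model$rules[[i]]
    list(target = sym_index[[ru$variable]], variable = ru$variable,
         prog = compile1(ru$math))
  })

  rate_rules <- lapply(which(vapply(model$rules, function(r)
    r$kind == "rate", logical(1))), function(i) {
      ru <- model$rules[[i]]
      pos <- match(ru$variable, state_ids)
      list(pos = pos, conv = state_conv[pos], prog = compile1(ru$math))
    })

  events <- lapply(model$events, function(ev) {
    asgs <- lapply(seq_along(ev$assignments), function(k) {
      v <- names(ev$assignments)[k]
      pos <- match(v, state_ids)
      conv <- if (!is.na(pos)) state_conv[pos] else 1
      list(target = sym_index[[v]],
           state_pos = if (is.na(pos)) 0L else pos,
           conv = conv,
           prog = compile1(ev$assignments[[k]]))
    })
    list(trigger = compile1(ev$trigger),
         init_value = ev$initial_trigger_value,
         assignments = asgs)
  })

  out_ids <- c(names(model$species),
               state_ids[state_kind == "rate_rule" &
                         !(state_ids %in% names(model$species))])
  out_sym <- unname(sym_index[out_ids])

  spec <- list(nsym = length(sym), template = template,
               state_sym = state_sym, state_conv = state_conv,
               N = N, rates = rates, assignments = assignments,
               rate_rules = rate_rules, events = unname(events),
               out_sym = out_sym)

  sys <- structure(list(model = model, sym = sym, sym_index = sym_index,
                        template = template, state_ids = state_ids,
                        state_sym = state_sym, state_conv = state_conv,
                        state_kind = state_kind,
                        n_species_state = n_species_state,
                        N = N, out_ids = out_ids, out_sym = out_sym,
                        spec = spec, cache = new.env(parent = emptyenv())),
                   class = "compiled_system")
  sys
}

# Lazily (re)build the C++ evaluator behind an external pointer; the
# pointer does not survive serialization, so rebuild when it is gone.
sys_ptr <- function(sys) {
  p <- sys$cache$ptr
  if (!is.null(p) && !cpp_ptr_valid(p)) p <- NULL
  if (is.null(p)) {
    p <- cpp_build_sys(sys$spec)
    sys$cache$ptr <- p
  }
  p
}

override_idx <- function(sys, overrides) {
  if (length(overrides) == 0L)
    return(list(idx = integer(0), val = numeric(0)))
  idx <- sys$sym_index[names(overrides)]
  if (anyNA(idx))
    stop("unknown override target(s): ",
         paste(names(overrides)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  list(idx = as.integer(idx), val = as.numeric(overrides))
}

#' Evaluate the right-hand side dy/dt of a compiled system
#'
#' Assignment rules are evaluated in dependency order, then all reaction
#' rates; the result is `N %*% v` plus rate-rule contributions.  The call
#' is pure: no state is modified.
#'
#' @param sys A `compiled_system`.
#' @param t Time.
#' @param y State vector (amounts), same length/order as `sys$state_ids`.
#' @param overrides Named numeric vector of symbol values to substitute
#'   (e.g. uncertain parameters).
#' @return Named numeric vector dy/dt.
#' @export
derivatives <- function(sys, t, y, overrides = numeric(0)) {
  stopifnot(inherits(sys, "compiled_system"),
            length(y) == length(sys$state_ids))
  ov <- override_idx(sys, overrides)
  r <- cpp_derivs(sys_ptr(sys), t, as.numeric(y), ov$idx, ov$val)
  if (!r$ok)
    stop("non-finite rate in reaction '",
         names(sys$model$reactions)[r$bad_rxn], "' at t = ", t,
         call. = FALSE)
  setNames(r$dy, sys$state_ids)
}

#' Initial state vector of a compiled system
#'
#' Returns species amounts (initialConcentration times compartment size
#' where needed) and rate-rule variable values at the start time, with
#' assignment rules applied once.  The full symbol context after rule
#' application is attached as attribute `"context"`.
#'
#' @param sys A `compiled_system`.
#' @param t0 Start time used when rules reference `time`.
#' @param overrides Named numeric vector substituted before evaluation.
#' @return Named numeric state vector.
#' @export
initial_state <- function(sys, t0 = 0, overrides = numeric(0)) {
  vals <- sys$template
  ov <- override_idx(sys, overrides)
  if (length(ov$idx) > 0L) vals[ov$idx] <- ov$val
  # apply assignment rules once on the context
  for (a in sys$spec$assignments)
    vals[a$target] <- cpp_eval_prog(a$prog, vals, t0)
  y <- numeric(length(sys$state_ids))
  for (i in seq_along(sys$state_ids)) {
    v <- vals[sys$state_sym[i]]
    if (is.na(v))
      stop("missing initial value for '", sys$state_ids[i], "'",
           call. = FALSE)
    y[i] <- v * sys$state_conv[i]
  }
  names(y) <- sys$state_ids
  attr(y, "context") <- setNames(vals, sys$sym)
  y
}

#' Locate and fire discrete events on one integration interval
#'
#' Checks all event triggers for a false-to-true crossing in `(t0, t1]`
#' assuming linear interpolation of the state between `y0` and `y1`, and
#' returns the earliest crossing (bisection to `1e-9 * (t1 - t0)`) with
#' the post-assignment state.  Simultaneous events fire in document
#' order.  Used by the integrator, which restarts at the returned time.
#'
#' @param sys A `compiled_system`.
#' @param t0,y0 Interval start and state (trigger values known here).
#' @param t1,y1 Interval end and state.
#' @param trigger_state Logical vector of trigger values at `t0`; default
#'   evaluates them at `(t0, y0)`.
#' @param overrides Named numeric substitutions.
#' @return `NULL` when no trigger crosses, otherwise
#'   `list(t_star, y_star, fired, trigger_state)`.
#' @export
locate_and_fire_events <- function(sys, t0, y0, t1, y1,
                                   trigger_state = NULL,
                                   overrides = numeric(0)) {
  evs <- sys$spec$events
  if (length(evs) == 0L) return(NULL)
  vals0 <- sys$template
  ov <- override_idx(sys, overrides)
  if (length(ov$idx) > 0L) vals0[ov$idx] <- ov$val

  ctx_vals <- function(t, y) {
    vals <- vals0
    for (i in seq_along(y)) vals[sys$state_sym[i]] <- y[i] / sys$state_conv[i]
    for (a in sys$spec$assignments)
      vals[a$target] <- cpp_eval_prog(a$prog, vals, t)
    vals
  }
  trig_at <- function(t, y) vapply(evs, function(e)
    cpp_eval_prog(e$trigger, ctx_vals(t, y), t) != 0, logical(1))

  if (is.null(trigger_state)) trigger_state <- trig_at(t0, y0)
  cur <- trig_at(t1, y1)
  flipped <- which(!trigger_state & cur)
  if (length(flipped) == 0L) return(NULL)

  interp <- function(t) y0 + (y1 - y0) * (t - t0) / (t1 - t0)
  lo <- t0; hi <- t1
  btol <- 1e-9 * (t1 - t0)
  while (hi - lo > btol) {
    mid <- (lo + hi) / 2
    tm <- trig_at(mid, interp(mid))
    if (any(tm[flipped] & !trigger_state[flipped])) hi <- mid else lo <- mid
  }
  t_star <- hi
  y_star <- interp(t_star)
  cur <- trig_at(t_star, y_star)
  fired <- character(0)
  for (e in seq_along(evs)) {       # document order
    if (!trigger_state[e] && cur[e]) {
      vals <- ctx_vals(t_star, y_star)
      ev <- evs[[e]]
      newv <- vapply(ev$assignments, function(a)
        cpp_eval_prog(a$prog, vals, t_star), numeric(1))
      for (k in seq_along(ev$assignments)) {
        a <- ev$assignments[[k]]
        if (a$state_pos > 0L)
          y_star[a$state_pos] <- newv[k] * a$conv
        # non-state targets are not persisted by this helper
      }
      fired <- c(fired, names(sys$model$events)[e])
    }
  }
  list(t_star = t_star, y_star = setNames(y_star, sys$state_ids),
       fired = fired, trigger_state = trig_at(t_star, y_star))
}

#' @export
print.compiled_system <- function(x, ...) {
  cat(sprintf("<compiled_system '%s': %d state variables, %d reactions>\n",
              x$model$id, length(x$state_ids), ncol(x$N)))
  invisible(x)
}
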