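# In-memory SBML model document: plain lists of records, mirroring the
# core SBML entity set (compartments, species, parameters, reactions,
# assignment/rate rules, events, function definitions).

#' Construct an SBML model document
#'
#' @param id Model identifier.
#' @param compartments,species,parameters,reactions,rules,events,functions
#'   Lists of records built with the matching constructors.
#' @param level,version SBML level/version metadata (written as L3V2).
#' @param name Optional human-readable name.
#' @return An object of class `sbml_model`.
#' @export
sbml_model <- function(id = "model", compartments = list(),
                       species = list(), parameters = list(),
                       reactions = list(), rules = list(), events = list(),
                       functions = list(), level = 3L, version = 2L,
                       name = NULL) {
  named <- function(x) setNames(x, vapply(x, `[[`, "", "id"))
  structure(list(id = id, name = name,
                 compartments = named(compartments),
                 species = named(species),
                 parameters = named(parameters),
                 reactions = named(reactions),
                 rules = rules,
                 events = named(events),
                 functions = named(functions),
                 level = as.integer(level), version = as.integer(version)),
            class = "sbml_model")
}

#' @rdname sbml_model
#' @param size Compartment size (volume); must be positive when used as a
#'   concentration divisor.
#' @param constant Logical; whether the quantity is fixed.
#' @export
sbml_compartment <- function(id, size = 1, constant = TRUE, name = NULL) {
  structure(list(id = id, size = as.numeric(size),
                 constant = isTRUE(constant), name = name),
            class = "sbml_compartment")
}

#' @rdname sbml_model
#' @param compartment Id of the containing compartment.
#' @param initial_amount,initial_concentration Exactly one must be set.
#' @param boundary_condition Species not changed by reactions.
#' @param has_only_substance_units Kinetic laws see the amount, not the
#'   concentration, of this species.
#' @export
sbml_species <- function(id, compartment, initial_amount = NA_real_,
                         initial_concentration = NA_real_,
                         boundary_condition = FALSE, constant = FALSE,
                         has_only_substance_units = FALSE, name = NULL) {
  structure(list(id = id, compartment = compartment,
                 initial_amount = as.numeric(initial_amount),
                 initial_concentration = as.numeric(initial_concentration),
                 boundary_condition = isTRUE(boundary_condition),
                 constant = isTRUE(constant),
                 has_only_substance_units = isTRUE(has_only_substance_units),
                 name = name),
            class = "sbml_species")
}

#' @rdname sbml_model
#' @param value Parameter value; `NA` marks an uncertain parameter to be
#'   estimated.
#' @export
sbml_parameter <- function(id, value = NA_real_, constant = TRUE,
                           name = NULL) {
  structure(list(id = id, value = as.numeric(value),
                 constant = isTRUE(constant), name = name),
            class = "sbml_parameter")
}

#' @rdname sbml_model
#' @param reactants,products Named numeric vectors: species id ->
#'   stoichiometry (> 0).
#' @param modifiers Character vector of modifier species ids.
#' @param kinetic_law A `mexpr` (or infix string, parsed on the spot).
#' @param reversible Logical flag; a reversible reaction keeps a single
#'   stoichiometry column with a signed net rate.
#' @param local_parameters Named numeric vector of reaction-local
#'   parameter values (shadow globals inside this kinetic law).
#' @export
sbml_reaction <- function(id, reactants = numeric(0), products = numeric(0),
                          modifiers = character(0), kinetic_law = NULL,
                          reversible = FALSE,
                          local_parameters = numeric(0), name = NULL) {
  if (is.character(kinetic_law)) kinetic_law <- parse_math(kinetic_law)
  structure(list(id = id, reactants = reactants, products = products,
                 modifiers = modifiers, kinetic_law = kinetic_law,
                 reversible = isTRUE(reversible),
                 local_parameters = local_parameters, name = name),
            class = "sbml_reaction")
}

#' @rdname sbml_model
#' @param kind `"assignment"` or `"rate"` (algebraic rules are
#'   unsupported).
#' @param variable Target identifier.
#' @param math A `mexpr` or infix string.
#' @export
sbml_rule <- function(kind = c("assignment", "rate"), variable, math) {
  kind <- match.arg(kind)
  if (is.character(math)) math <- parse_math(math)
  structure(list(kind = kind, variable = variable, math = math),
            class = "sbml_rule")
}

#' @rdname sbml_model
#' @param trigger Boolean-valued `mexpr` or infix string.
#' @param assignments Named list: variable id -> `mexpr`/infix string.
#' @param initial_trigger_value Assumed trigger value before the start of
#'   the simulation; `TRUE` suppresses firing when the trigger already
#'   holds at t0.
#' @export
sbml_event <- function(id, trigger, assignments,
                       initial_trigger_value = TRUE, name = NULL) {
  if (is.character(trigger)) trigger <- parse_math(trigger)
  assignments <- lapply(assignments, function(a)
    if (is.character(a)) parse_math(a) else a)
  structure(list(id = id, trigger = trigger, assignments = assignments,
                 initial_trigger_value = isTRUE(initial_trigger_value),
                 name = name),
            class = "sbml_event")
}

#' @rdname sbml_model
#' @param args Character vector of formal argument names.
#' @param body A `mexpr` or infix string referencing only the arguments.
#' @export
sbml_function <- function(id, args, body, name = NULL) {
  if (is.character(body)) body <- parse_math(body)
  structure(list(id = id, args = args, body = body, name = name),
            class = "sbml_function")
}

#' @export
print.sbml_model <- function(x, ...) {
  cat(sprintf("<sbml_model '%s' L%dV%d>\n", x$id, x$level, x$version))
  cat(sprintf("  compartments: %d  species: %d  parameters: %d\n",
              length(x$compartments), length(x$species),
              length(x$parameters)))
  cat(sprintf("  reactions: %d  rules: %d  events: %d  functions: %d\n",
              length(x$reactions), length(x$rules), length(x$events),
              length(x$functions)))
  invisible(x)
}

# ---------------------------------------------------------------------------

finding <- function(severity, entity, message) {
  data.frame(severity = severity, entity = entity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a model document
#'
#' Checks referential integrity and the structural invariants required
#' for ODE compilation.  Returns findings rather than throwing, so that a
#' caller can report all problems at once.
#'
#' @param model An `sbml_model`.
#' @return A data frame with columns `severity` ("error"/"warning"),
#'   `entity` and `message`; zero rows when the model is consistent.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "sbml_model"))
  f <- list()
  add <- function(sev, ent, msg) f[[length(f) + 1L]] <<- finding(sev, ent, msg)

  ids <- c(names(model$compartments), names(model$species),
           names(model$parameters), names(model$reactions),
           names(model$events), names(model$functions))
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add("error", d, "duplicated id")

  for (cp in model$compartments) {
    if (!is.na(cp$size) && cp$size <= 0)
      add("error", cp$id, "compartment size must be > 0")
  }
  for (sp in model$species) {
    if (is.null(model$compartments[[sp$compartment]]))
      add("error", sp$id,
          paste0("unknown compartment '", sp$compartment, "'"))
    has_amt <- !is.na(sp$initial_amount)
    has_conc <- !is.na(sp$initial_concentration)
    if (has_amt && has_conc)
      add("error", sp$id,
          "both initialAmount and initialConcentration set")
  }

  known <- c(names(model$compartments), names(model$species),
             names(model$parameters), "time")
  fundefs <- lapply(model$functions, function(fd)
    list(args = fd$args, body = fd$body))

  for (rx in model$reactions) {
    for (sid in c(names(rx$reactants), names(rx$products), rx$modifiers)) {
      if (is.null(model$species[[sid]]))
        add("error", rx$id, paste0("unknown species '", sid, "'"))
    }
    if (any(c(rx$reactants, rx$products) <= 0))
      add("error", rx$id, "stoichiometry must be > 0")
    if (!is.null(rx$kinetic_law)) {
      refs <- tryCatch(
        math_identifiers(inline_functions(rx$kinetic_law, fundefs)),
        error = function(e) {
          add("error", rx$id, conditionMessage(e))
          character(0)
        })
      locals <- names(rx$local_parameters)
      for (r in setdiff(refs, c(known, locals)))
        add("error", rx$id, paste0("undeclared identifier '", r,
                                   "' in kinetic law"))
    }
  }

  rule_vars <- vapply(model$rules, `[[`, "", "variable")
  for (v in unique(rule_vars[duplicated(rule_vars)]))
    add("error", v, "more than one rule targets this variable")
  for (ru in model$rules) {
    if (!ru$variable %in% known)
      add("error", ru$variable, "rule targets unknown identifier")
    refs <- tryCatch(
      math_identifiers(inline_functions(ru$math, fundefs)),
      error = function(e) character(0))
    for (r in setdiff(refs, known))
      add("error", ru$variable,
          paste0("undeclared identifier '", r, "' in rule"))
    tgt <- c(model$species[[ru$variable]], model$parameters[[ru$variable]],
             model$compartments[[ru$variable]])
    if (!is.null(tgt) && isTRUE(tgt$constant))
      add("error", ru$variable, "rule targets a constant quantity")
  }

  # cyclic assignment rules
  asg <- Filter(function(r) r$kind == "assignment", model$rules)
  if (length(asg) > 1L) {
    avars <- vapply(asg, `[[`, "", "variable")
    deps <- lapply(asg, function(r)
      intersect(math_identifiers(r$math), avars))
    names(deps) <- avars
    cyc <- detect_cycle(deps)
    if (!is.null(cyc))
      add("error", cyc[1],
          paste0("cyclic assignment rules: ",
                 paste(cyc, collapse = " -> ")))
  }

  for (ev in model$events) {
    for (v in names(ev$assignments)) {
      if (!v %in% known) {
        add("error", ev$id,
            paste0("event assigns unknown identifier '", v, "'"))
        next
      }
      tgt <- c(model$species[[v]], model$parameters[[v]],
               model$compartments[[v]])
      if (!is.null(tgt) && isTRUE(tgt$constant))
        add("error", ev$id,
            paste0("event assigns constant quantity '", v, "'"))
    }
    refs <- tryCatch(
      math_identifiers(inline_functions(ev$trigger, fundefs)),
      error = function(e) character(0))
    for (r in setdiff(refs, known))
      add("error", ev$id,
          paste0("undeclared identifier '", r, "' in trigger"))
  }

  for (fd in model$functions) {
    refs <- math_identifiers(fd$body)
    bad <- setdiff(refs, c(fd$args, "time"))
    for (b in bad)
      add("error", fd$id,
          paste0("function body references non-argument '", b, "'"))
  }

  if (length(f) == 0L)
    return(data.frame(severity = character(0), entity = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, f)
}

# deps: named list var -> character vector of vars it depends on.
# Returns NULL or a character vector describing one cycle.
detect_cycle <- function(deps) {
  state <- setNames(rep(0L, length(deps)), names(deps)) # 0 new 1 open 2 done
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return(invisible())
    if (state[[v]] == 1L) {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return(invisible())
    }
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (d in deps[[v]]) if (d %in% names(deps)) visit(d)
    path <<- path[-length(path)]
    state[[v]] <<- 2L
  }
  for (v in names(deps)) visit(v)
  found
}

# Topological order of assignment rules (document order preserved for
# independent rules).  Errors on a cycle.
order_assignments <- function(rules) {
  asg_idx <- which(vapply(rules, function(r) r$kind == "assignment",
                          logical(1)))
  if (length(asg_idx) <= 1L) return(asg_idx)
  avars <- vapply(rules[asg_idx], `[[`, "", "variable")
  deps <- lapply(rules[asg_idx], function(r)
    intersect(math_identifiers(r$math), avars))
  names(deps) <- avars
  cyc <- detect_cycle(deps)
  if (!is.null(cyc))
    stop("cyclic assignment rules: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  ordered <- character(0)
  remaining <- avars
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(v)
      all(deps[[v]] %in% ordered), logical(1))]
    ordered <- c(ordered, ready[1]) # document order among ready ones
    remaining <- setdiff(remaining, ready[1])
  }
  asg_idx[match(ordered, avars)]
}
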