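# SBML XML reader and writer for the supported core subset
# (Level 2 versions 1-5, Level 3 versions 1-2, no packages).

stop_unsupported <- function(what) {
  stop("unsupported construct: ", what, call. = FALSE)
}

attr_or <- function(node, name, default = NA) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

attr_num <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NA_real_ else as.numeric(v)
}

attr_bool <- function(node, name, default = FALSE) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v %in% c("true", "1")
}

find1 <- function(node, xpath) {
  r <- xml2::xml_find_first(node, xpath)
  if (inherits(r, "xml_missing")) NULL else r
}

child_math <- function(node) {
  m <- find1(node, "./math")
  if (is.null(m)) return(NULL)
  kids <- xml2::xml_children(m)
  if (length(kids) != 1L)
    stop("parse error: <math> must contain exactly one expression",
         call. = FALSE)
  mathml_to_mexpr(kids[[1]])
}

#' Parse an SBML document
#'
#' Reads the supported SBML core subset (Level 2 v1-5, Level 3 v1-2) into
#' an [sbml_model].  Constructs outside the subset -- event delays,
#' algebraic rules, constraints, fast reactions, conversion factors --
#' raise an error naming the construct rather than being ignored.
#'
#' @param source File path or a character scalar of XML text.
#' @param validate Run [validate_model] and stop on error findings.
#' @return An `sbml_model`.
#' @export
parse_sbml <- function(source, validate = TRUE) {
  doc <- tryCatch(xml2::read_xml(source), error = function(e)
    stop("SBML parse error: ", conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  root <- doc
  if (xml2::xml_name(root) != "sbml")
    stop("SBML parse error: root element is not <sbml>", call. = FALSE)
  level <- as.integer(attr_or(root, "level", "3"))
  version <- as.integer(attr_or(root, "version", "2"))
  if (!(level == 2L && version %in% 1:5) &&
      !(level == 3L && version %in% 1:2))
    stop_unsupported(sprintf("SBML Level %d Version %d", level, version))
  mnode <- find1(root, "./model")
  if (is.null(mnode))
    stop("SBML parse error: no <model> element", call. = FALSE)

  # explicit rejections of out-of-scope constructs
  if (!is.null(find1(mnode, ".//algebraicRule")))
    stop_unsupported("algebraicRule")
  if (!is.null(find1(mnode, ".//listOfConstraints")))
    stop_unsupported("constraint")
  if (!is.null(find1(mnode, ".//delay")))
    stop_unsupported("delay")
  if (!is.na(xml2::xml_attr(mnode, "conversionFactor")))
    stop_unsupported("conversionFactor")

  functions <- lapply(xml2::xml_find_all(
    mnode, "./listOfFunctionDefinitions/functionDefinition"), function(fn) {
      lam <- find1(fn, "./math/lambda")
      if (is.null(lam))
        stop("SBML parse error: functionDefinition without lambda",
             call. = FALSE)
      kids <- xml2::xml_children(lam)
      nms <- xml2::xml_name(kids)
      args <- vapply(kids[nms == "bvar"], function(b)
        trimws(xml2::xml_text(b)), character(1))
      body <- mathml_to_mexpr(kids[[length(kids)]])
      sbml_function(xml2::xml_attr(fn, "id"), args, body,
                    name = attr_or(fn, "name", NULL))
    })

  compartments <- lapply(xml2::xml_find_all(
    mnode, "./listOfCompartments/compartment"), function(cn) {
      sbml_compartment(xml2::xml_attr(cn, "id"),
                       size = attr_num(cn, "size"),
                       constant = attr_bool(cn, "constant", TRUE),
                       name = attr_or(cn, "name", NULL))
    })

  species <- lapply(xml2::xml_find_all(
    mnode, "./listOfSpecies/species"), function(sn) {
      sbml_species(xml2::xml_attr(sn, "id"),
                   compartment = xml2::xml_attr(sn, "compartment"),
                   initial_amount = attr_num(sn, "initialAmount"),
                   initial_concentration = attr_num(sn,
                                                    "initialConcentration"),
                   boundary_condition = attr_bool(sn, "boundaryCondition"),
                   constant = attr_bool(sn, "constant"),
                   has_only_substance_units =
                     attr_bool(sn, "hasOnlySubstanceUnits"),
                   name = attr_or(sn, "name", NULL))
    })

  parameters <- lapply(xml2::xml_find_all(
    mnode, "./listOfParameters/parameter"), function(pn) {
      sbml_parameter(xml2::xml_attr(pn, "id"),
                     value = attr_num(pn, "value"),
                     constant = attr_bool(pn, "constant", TRUE),
                     name = attr_or(pn, "name", NULL))
    })

  reactions <- lapply(xml2::xml_find_all(
    mnode, "./listOfReactions/reaction"), function(rn) {
      if (attr_bool(rn, "fast")) stop_unsupported("fast reaction")
      refs <- function(xpath) {
        nodes <- xml2::xml_find_all(rn, xpath)
        if (length(nodes) == 0L) return(numeric(0))
        st <- vapply(nodes, function(x) {
          s <- attr_num(x, "stoichiometry")
          if (is.na(s)) 1 else s
        }, numeric(1))
        setNames(st, vapply(nodes, xml2::xml_attr, "", attr = "species"))
      }
      kl <- find1(rn, "./kineticLaw")
      law <- NULL
      locals <- numeric(0)
      if (!is.null(kl)) {
        law <- child_math(kl)
        lp <- xml2::xml_find_all(
          kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter")
        if (length(lp) > 0L)
          locals <- setNames(vapply(lp, attr_num, numeric(1), name = "value"),
                             vapply(lp, xml2::xml_attr, "", attr = "id"))
      }
      sbml_reaction(xml2::xml_attr(rn, "id"),
                    reactants = refs("./listOfReactants/speciesReference"),
                    products = refs("./listOfProducts/speciesReference"),
                    modifiers = vapply(
                      xml2::xml_find_all(
                        rn, "./listOfModifiers/modifierSpeciesReference"),
                      xml2::xml_attr, "", attr = "species"),
                    kinetic_law = law,
                    reversible = attr_bool(rn, "reversible", TRUE),
                    local_parameters = locals,
                    name = attr_or(rn, "name", NULL))
    })

  rules <- lapply(xml2::xml_find_all(
    mnode, "./listOfRules/*"), function(ru) {
      nm <- xml2::xml_name(ru)
      kind <- switch(nm, assignmentRule = "assignment", rateRule = "rate",
                     stop_unsupported(nm))
      sbml_rule(kind, xml2::xml_attr(ru, "variable"), child_math(ru))
    })

  events <- lapply(xml2::xml_find_all(
    mnode, "./listOfEvents/event"), function(en) {
      tn <- find1(en, "./trigger")
      if (is.null(tn))
        stop("SBML parse error: event without trigger", call. = FALSE)
      asg <- xml2::xml_find_all(
        en, "./listOfEventAssignments/eventAssignment")
      assignments <- setNames(
        lapply(asg, child_math),
        vapply(asg, xml2::xml_attr, "", attr = "variable"))
      id <- attr_or(en, "id", paste0("event", xml2::xml_path(en)))
      sbml_event(id, trigger = child_math(tn), assignments = assignments,
                 initial_trigger_value = attr_bool(tn, "initialValue", TRUE),
                 name = attr_or(en, "name", NULL))
    })

  model <- sbml_model(id = attr_or(mnode, "id", "model"),
                      compartments = compartments, species = species,
                      parameters = parameters, reactions = reactions,
                      rules = rules, events = events, functions = functions,
                      level = level, version = version,
                      name = attr_or(mnode, "name", NULL))
  if (validate) {
    fnd <- validate_model(model)
    err <- fnd[fnd$severity == "error", , drop = FALSE]
    if (nrow(err) > 0L)
      stop("SBML validation error: ",
           paste(sprintf("[%s] %s", err$entity, err$message),
                 collapse = "; "), call. = FALSE)
  }
  model
}

# ---------------------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_attr_num <- function(x) sprintf("%.17g", x)

#' Write a model document as SBML Level 3 Version 2
#'
#' The emitted document round-trips: `parse_sbml(write_sbml(m))` compares
#' equal to `m` field by field (numeric attributes are written with 17
#' significant digits).
#'
#' @param model An `sbml_model`.
#' @param path Optional file path; when `NULL` the XML text is returned.
#' @return XML text (invisibly when written to a file).
#' @export
write_sbml <- function(model, path = NULL) {
  stopifnot(inherits(model, "sbml_model"))
  out <- character(0)
  w <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  nm_attr <- function(x)
    if (!is.null(x$name)) paste0(' name="', xml_escape(x$name), '"') else ""

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2">')
  w(sprintf('<model id="%s"%s>', model$id, nm_attr(model)))

  if (length(model$functions) > 0L) {
    w("<listOfFunctionDefinitions>")
    for (fd in model$functions) {
      w(sprintf('<functionDefinition id="%s"%s>', fd$id, nm_attr(fd)))
      bvars <- paste0(vapply(fd$args, function(a)
        sprintf("<bvar><ci>%s</ci></bvar>", a), character(1)),
        collapse = "")
      w('<math xmlns="http://www.w3.org/1998/Math/MathML"><lambda>',
        bvars, mexpr_to_mathml_inner(fd$body), "</lambda></math>")
      w("</functionDefinition>")
    }
    w("</listOfFunctionDefinitions>")
  }

  if (length(model$compartments) > 0L) {
    w("<listOfCompartments>")
    for (cp in model$compartments) {
      sz <- if (is.na(cp$size)) "" else
        sprintf(' size="%s"', fmt_attr_num(cp$size))
      w(sprintf('<compartment id="%s"%s%s constant="%s" spatialDimensions="3"/>',
                cp$id, nm_attr(cp), sz, tolower(cp$constant)))
    }
    w("</listOfCompartments>")
  }

  if (length(model$species) > 0L) {
    w("<listOfSpecies>")
    for (sp in model$species) {
      init <- ""
      if (!is.na(sp$initial_amount))
        init <- sprintf(' initialAmount="%s"',
                        fmt_attr_num(sp$initial_amount))
      if (!is.na(sp$initial_concentration))
        init <- sprintf(' initialConcentration="%s"',
                        fmt_attr_num(sp$initial_concentration))
      w(sprintf(paste0('<species id="%s"%s compartment="%s"%s ',
                       'hasOnlySubstanceUnits="%s" boundaryCondition="%s" ',
                       'constant="%s"/>'),
                sp$id, nm_attr(sp), sp$compartment, init,
                tolower(sp$has_only_substance_units),
                tolower(sp$boundary_condition), tolower(sp$constant)))
    }
    w("</listOfSpecies>")
  }

  if (length(model$parameters) > 0L) {
    w("<listOfParameters>")
    for (p in model$parameters) {
      val <- if (is.na(p$value)) "" else
        sprintf(' value="%s"', fmt_attr_num(p$value))
      w(sprintf('<parameter id="%s"%s%s constant="%s"/>',
                p$id, nm_attr(p), val, tolower(p$constant)))
    }
    w("</listOfParameters>")
  }

  if (length(model$rules) > 0L) {
    w("<listOfRules>")
    for (ru in model$rules) {
      tag <- if (ru$kind == "assignment") "assignmentRule" else "rateRule"
      w(sprintf('<%s variable="%s">', tag, ru$variable))
      w(write_mathml(ru$math))
      w(sprintf("</%s>", tag))
    }
    w("</listOfRules>")
  }

  if (length(model$reactions) > 0L) {
    w("<listOfReactions>")
    for (rx in model$reactions) {
      w(sprintf('<reaction id="%s"%s reversible="%s">',
                rx$id, nm_attr(rx), tolower(rx$reversible)))
      reflist <- function(tag, refs) {
        if (length(refs) == 0L) return()
        w(sprintf("<listOf%s>", tag))
        for (i in seq_along(refs))
          w(sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                    names(refs)[i], fmt_attr_num(refs[[i]])))
        w(sprintf("</listOf%s>", tag))
      }
      reflist("Reactants", rx$reactants)
      reflist("Products", rx$products)
      if (length(rx$modifiers) > 0L) {
        w("<listOfModifiers>")
        for (m in rx$modifiers)
          w(sprintf('<modifierSpeciesReference species="%s"/>', m))
        w("</listOfModifiers>")
      }
      if (!is.null(rx$kinetic_law)) {
        w("<kineticLaw>")
        w(write_mathml(rx$kinetic_law))
        if (length(rx$local_parameters) > 0L) {
          w("<listOfLocalParameters>")
          for (i in seq_along(rx$local_parameters))
            w(sprintf('<localParameter id="%s" value="%s"/>',
                      names(rx$local_parameters)[i],
                      fmt_attr_num(rx$local_parameters[[i]])))
          w("</listOfLocalParameters>")
        }
        w("</kineticLaw>")
      }
      w("</reaction>")
    }
    w("</listOfReactions>")
  }

  if (length(model$events) > 0L) {
    w("<listOfEvents>")
    for (ev in model$events) {
      w(sprintf('<event id="%s"%s useValuesFromTriggerTime="true">',
                ev$id, nm_attr(ev)))
      w(sprintf('<trigger initialValue="%s" persistent="true">',
                tolower(ev$initial_trigger_value)))
      w(write_mathml(ev$trigger))
      w("</trigger>")
      w("<listOfEventAssignments>")
      for (i in seq_along(ev$assignments)) {
        w(sprintf('<eventAssignment variable="%s">',
                  names(ev$assignments)[i]))
        w(write_mathml(ev$assignments[[i]]))
        w("</eventAssignment>")
      }
      w("</listOfEventAssignments>")
      w("</event>")
    }
    w("</listOfEvents>")
  }

  w("</model>")
  w("</sbml>")
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
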