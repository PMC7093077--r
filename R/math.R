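# Expression trees for kinetic-law mathematics.
#
# A `mexpr` node is one of
#   const : list(kind = "const", value = <double>)
#   name  : list(kind = "name",  name = <string>)   ("time" is the csymbol t)
#   call  : list(kind = "call",  op = <string>, args = list(mexpr...))
# Operator vocabulary (op): add sub mul div pow neg, exp ln log10 sqrt abs
# floor ceiling sin cos tan arcsin arccos arctan sinh cosh tanh min max,
# gt geq lt leq eq neq and or not xor, piecewise, or a model function id.

mx_const <- function(value) {
  structure(list(kind = "const", value = as.numeric(value)), class = "mexpr")
}

mx_name <- function(name) {
  stopifnot(is.character(name), nzchar(name))
  structure(list(kind = "name", name = name), class = "mexpr")
}

mx_call <- function(op, ...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !inherits(args[[1]], "mexpr"))
    args <- args[[1]]
  structure(list(kind = "call", op = op, args = args), class = "mexpr")
}

.mx_builtins <- c("add", "sub", "mul", "div", "pow", "neg",
                  "exp", "ln", "log10", "sqrt", "abs", "floor", "ceiling",
                  "sin", "cos", "tan", "arcsin", "arccos", "arctan",
                  "sinh", "cosh", "tanh", "min", "max",
                  "gt", "geq", "lt", "leq", "eq", "neq",
                  "and", "or", "not", "xor", "piecewise")

is_mexpr <- function(x) inherits(x, "mexpr")

#' Parse mathematics into an expression tree
#'
#' Accepts either a MathML content-markup fragment (as text or an
#' `xml2::xml_node`) or an infix string such as `"Vmax*S/(Km+S)"`.
#' The infix dialect is ordinary R arithmetic: `+ - * / ^`, comparisons,
#' `& | !`, calls to `exp, log, log10, sqrt, abs, floor, ceiling,
#' sin..., min, max`, and `piecewise(v1, cond1, ..., otherwise)`.
#' `log(x)` is the natural logarithm; `log(x, b)` is base-`b`.
#'
#' @param x MathML text/node or an infix string.
#' @return A `mexpr` expression tree.
#' @export
#' @examples
#' e <- parse_math("Vmax*S/(Km+S)")
#' eval_math(e, list(Vmax = 100, Km = 1, S = 1))  # 50
parse_math <- function(x) {
  if (inherits(x, "xml_node")) return(mathml_to_mexpr_root(x))
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("^\\s*<", x)) {
    node <- xml2::read_xml(x)
    return(mathml_to_mexpr_root(node))
  }
  lang <- tryCatch(str2lang(x), error = function(e)
    stop("math parse error: ", conditionMessage(e), call. = FALSE))
  rlang_to_mexpr(lang)
}

# ---- infix (R language) -> mexpr ------------------------------------------

.r_op_map <- c("+" = "add", "-" = "sub", "*" = "mul", "/" = "div",
               "^" = "pow", ">" = "gt", ">=" = "geq", "<" = "lt",
               "<=" = "leq", "==" = "eq", "!=" = "neq",
               "&" = "and", "&&" = "and", "|" = "or", "||" = "or")

.r_fun_map <- c(exp = "exp", log10 = "log10", sqrt = "sqrt", abs = "abs",
                floor = "floor", ceiling = "ceiling",
                sin = "sin", cos = "cos", tan = "tan",
                asin = "arcsin", acos = "arccos", atan = "arctan",
                sinh = "sinh", cosh = "cosh", tanh = "tanh",
                min = "min", max = "max", xor = "xor",
                piecewise = "piecewise", ln = "ln")

rlang_to_mexpr <- function(e) {
  if (is.numeric(e)) return(mx_const(e))
  if (is.logical(e)) return(mx_const(as.numeric(e)))
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm == "pi") return(mx_const(pi))
    if (nm == "T" || nm == "TRUE") return(mx_const(1))
    if (nm == "F" || nm == "FALSE") return(mx_const(0))
    return(mx_name(nm))
  }
  if (!is.call(e)) stop("math parse error: unsupported construct ",
                        deparse(e), call. = FALSE)
  op <- as.character(e[[1]])
  args <- as.list(e)[-1]
  if (op == "(") return(rlang_to_mexpr(args[[1]]))
  if (op == "-" && length(args) == 1L)
    return(mx_call("neg", rlang_to_mexpr(args[[1]])))
  if (op == "+" && length(args) == 1L) return(rlang_to_mexpr(args[[1]]))
  if (op == "!") return(mx_call("not", rlang_to_mexpr(args[[1]])))
  if (op %in% names(.r_op_map))
    return(mx_call(.r_op_map[[op]], lapply(args, rlang_to_mexpr)))
  if (op == "log") {
    a <- lapply(args, rlang_to_mexpr)
    if (length(a) == 1L) return(mx_call("ln", a[[1]]))
    return(mx_call("div", mx_call("ln", a[[1]]), mx_call("ln", a[[2]])))
  }
  if (op == "ifelse") {
    a <- lapply(args, rlang_to_mexpr)
    return(mx_call("piecewise", a[[2]], a[[1]], a[[3]]))
  }
  a <- lapply(args, rlang_to_mexpr)
  if (op %in% names(.r_fun_map)) return(mx_call(.r_fun_map[[op]], a))
  # anything else is a model function-definition call
  mx_call(op, a)
}

# ---- MathML -> mexpr ------------------------------------------------------

mathml_to_mexpr_root <- function(node) {
  xml2::xml_ns_strip(node)
  if (xml2::xml_name(node) == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L)
      stop("math parse error: <math> must have exactly one child",
           call. = FALSE)
    node <- kids[[1]]
  }
  mathml_to_mexpr(node)
}

.mathml_ops <- c(plus = "add", minus = "sub", times = "mul", divide = "div",
                 power = "pow", exp = "exp", ln = "ln",
                 abs = "abs", floor = "floor", ceiling = "ceiling",
                 sin = "sin", cos = "cos", tan = "tan",
                 arcsin = "arcsin", arccos = "arccos", arctan = "arctan",
                 sinh = "sinh", cosh = "cosh", tanh = "tanh",
                 min = "min", max = "max",
                 gt = "gt", geq = "geq", lt = "lt", leq = "leq",
                 eq = "eq", neq = "neq",
                 and = "and", or = "or", not = "not", xor = "xor")

mathml_to_mexpr <- function(node) {
  nm <- xml2::xml_name(node)
  switch(nm,
    cn = {
      type <- xml2::xml_attr(node, "type")
      if (!is.na(type) && type == "e-notation") {
        parts <- xml2::xml_contents(node)
        txt <- xml2::xml_text(parts)
        nums <- suppressWarnings(as.numeric(txt[nzchar(trimws(txt))]))
        nums <- nums[!is.na(nums)]
        if (length(nums) != 2L)
          stop("math parse error: malformed e-notation <cn>", call. = FALSE)
        mx_const(nums[1] * 10^nums[2])
      } else if (!is.na(type) && type == "rational") {
        txt <- xml2::xml_text(xml2::xml_contents(node))
        nums <- suppressWarnings(as.numeric(txt[nzchar(trimws(txt))]))
        nums <- nums[!is.na(nums)]
        mx_const(nums[1] / nums[2])
      } else {
        mx_const(as.numeric(xml2::xml_text(node)))
      }
    },
    ci = mx_name(trimws(xml2::xml_text(node))),
    csymbol = {
      url <- xml2::xml_attr(node, "definitionURL")
      if (!is.na(url) && grepl("time$", url)) return(mx_name("time"))
      if (!is.na(url) && grepl("delay$", url))
        stop("unsupported construct: delay", call. = FALSE)
      if (!is.na(url) && grepl("avogadro$", url))
        return(mx_const(6.02214179e23))
      stop("math parse error: unknown csymbol ", url, call. = FALSE)
    },
    "true" = mx_const(1),
    "false" = mx_const(0),
    pi = mx_const(pi),
    exponentiale = mx_const(exp(1)),
    infinity = mx_const(Inf),
    notanumber = mx_const(NaN),
    piecewise = {
      kids <- xml2::xml_children(node)
      args <- list()
      for (k in kids) {
        knm <- xml2::xml_name(k)
        sub <- xml2::xml_children(k)
        if (knm == "piece") {
          args <- c(args, list(mathml_to_mexpr(sub[[1]]),
                               mathml_to_mexpr(sub[[2]])))
        } else if (knm == "otherwise") {
          args <- c(args, list(mathml_to_mexpr(sub[[1]])))
        } else stop("math parse error: unexpected <", knm,
                    "> inside piecewise", call. = FALSE)
      }
      mx_call("piecewise", args)
    },
    apply = {
      kids <- xml2::xml_children(node)
      head <- kids[[1]]
      hnm <- xml2::xml_name(head)
      args <- lapply(kids[-1], mathml_to_mexpr)
      if (hnm == "minus" && length(args) == 1L) return(mx_call("neg", args[[1]]))
      if (hnm == "root") {
        # first arg may be a <degree>
        dkids <- xml2::xml_children(node)[-1]
        if (length(dkids) >= 1L && xml2::xml_name(dkids[[1]]) == "degree") {
          deg <- mathml_to_mexpr(xml2::xml_children(dkids[[1]])[[1]])
          x <- mathml_to_mexpr(dkids[[2]])
          return(mx_call("pow", x, mx_call("div", mx_const(1), deg)))
        }
        return(mx_call("sqrt", args[[1]]))
      }
      if (hnm == "log") {
        dkids <- xml2::xml_children(node)[-1]
        if (length(dkids) >= 1L && xml2::xml_name(dkids[[1]]) == "logbase") {
          base <- mathml_to_mexpr(xml2::xml_children(dkids[[1]])[[1]])
          x <- mathml_to_mexpr(dkids[[2]])
          return(mx_call("div", mx_call("ln", x), mx_call("ln", base)))
        }
        return(mx_call("log10", args[[1]]))
      }
      if (hnm == "ci") {                      # model function call
        return(mx_call(trimws(xml2::xml_text(head)), args))
      }
      if (hnm %in% names(.mathml_ops))
        return(mx_call(.mathml_ops[[hnm]], args))
      stop("math parse error: unknown operator <", hnm, ">", call. = FALSE)
    },
    lambda = stop("math parse error: <lambda> outside functionDefinition",
                  call. = FALSE),
    stop("math parse error: unknown element <", nm, ">", call. = FALSE)
  )
}

# ---- mexpr -> MathML ------------------------------------------------------

.mathml_op_inv <- setNames(names(.mathml_ops), .mathml_ops)

fmt_num <- function(x) {
  if (is.na(x)) return("<notanumber/>")
  s <- sprintf("%.17g", x)
  s
}

cn_xml <- function(value) {
  if (!is.finite(value)) {
    if (is.nan(value)) return("<notanumber/>")
    return(if (value > 0) "<infinity/>"
           else "<apply><minus/><infinity/></apply>")
  }
  s <- sprintf("%.17g", value)
  if (grepl("[eE]", s)) {
    parts <- strsplit(s, "[eE]")[[1]]
    return(sprintf('<cn type="e-notation">%s<sep/>%s</cn>',
                   parts[1], as.numeric(parts[2])))
  }
  sprintf("<cn>%s</cn>", s)
}

mexpr_to_mathml_inner <- function(e) {
  switch(e$kind,
    const = cn_xml(e$value),
    name = if (e$name == "time") {
      paste0('<csymbol encoding="text" definitionURL=',
             '"http://www.sbml.org/sbml/symbols/time">t</csymbol>')
    } else sprintf("<ci>%s</ci>", e$name),
    call = {
      if (e$op == "piecewise") {
        n <- length(e$args)
        npieces <- n %/% 2L
        out <- "<piecewise>"
        for (i in seq_len(npieces)) {
          out <- paste0(out, "<piece>",
                        mexpr_to_mathml_inner(e$args[[2 * i - 1L]]),
                        mexpr_to_mathml_inner(e$args[[2 * i]]), "</piece>")
        }
        if (n %% 2L == 1L)
          out <- paste0(out, "<otherwise>",
                        mexpr_to_mathml_inner(e$args[[n]]), "</otherwise>")
        return(paste0(out, "</piecewise>"))
      }
      args <- vapply(e$args, mexpr_to_mathml_inner, character(1))
      if (e$op == "neg")
        return(paste0("<apply><minus/>", args[1], "</apply>"))
      if (e$op == "pow")
        return(paste0("<apply><power/>", paste(args, collapse = ""),
                      "</apply>"))
      if (e$op == "log10")
        return(paste0("<apply><log/>", args[1], "</apply>"))
      if (e$op == "sqrt")
        return(paste0("<apply><root/>", args[1], "</apply>"))
      if (e$op %in% names(.mathml_op_inv))
        return(paste0("<apply><", .mathml_op_inv[[e$op]], "/>",
                      paste(args, collapse = ""), "</apply>"))
      # model function call
      paste0("<apply><ci>", e$op, "</ci>", paste(args, collapse = ""),
             "</apply>")
    })
}

#' Serialize an expression tree to content MathML
#'
#' @param e A `mexpr`.
#' @param wrap Wrap in a `<math>` element with the MathML namespace.
#' @return A character scalar of XML.
#' @export
write_mathml <- function(e, wrap = TRUE) {
  body <- mexpr_to_mathml_inner(e)
  if (wrap)
    paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', body,
           "</math>")
  else body
}

# ---- evaluation -----------------------------------------------------------

#' Evaluate an expression tree
#'
#' @param e A `mexpr`.
#' @param env Named list or environment mapping identifiers to values;
#'   `time` supplies the time symbol.
#' @param functions Named list of function definitions (each
#'   `list(args = <chr>, body = <mexpr>)`) for model function calls.
#' @return Numeric scalar (booleans are 1/0).
#' @export
eval_math <- function(e, env = list(), functions = NULL) {
  if (is.environment(env)) env <- as.list(env)
  ev <- function(x) {
    switch(x$kind,
      const = x$value,
      name = {
        v <- env[[x$name]]
        if (is.null(v)) stop("unbound identifier: ", x$name, call. = FALSE)
        as.numeric(v)
      },
      call = {
        op <- x$op
        if (op == "piecewise") {
          n <- length(x$args)
          i <- 1L
          while (i + 1L <= n) {
            if (ev(x$args[[i + 1L]]) != 0) return(ev(x$args[[i]]))
            i <- i + 2L
          }
          if (n %% 2L == 1L) return(ev(x$args[[n]]))
          return(NaN)
        }
        a <- lapply(x$args, ev)
        switch(op,
          add = Reduce(`+`, a),
          sub = if (length(a) == 1L) -a[[1]] else Reduce(`-`, a),
          mul = Reduce(`*`, a),
          div = a[[1]] / a[[2]],
          pow = a[[1]]^a[[2]],
          neg = -a[[1]],
          exp = exp(a[[1]]), ln = log(a[[1]]), log10 = log10(a[[1]]),
          sqrt = sqrt(a[[1]]), abs = abs(a[[1]]),
          floor = floor(a[[1]]), ceiling = ceiling(a[[1]]),
          sin = sin(a[[1]]), cos = cos(a[[1]]), tan = tan(a[[1]]),
          arcsin = asin(a[[1]]), arccos = acos(a[[1]]),
          arctan = atan(a[[1]]),
          sinh = sinh(a[[1]]), cosh = cosh(a[[1]]), tanh = tanh(a[[1]]),
          min = do.call(min, a), max = do.call(max, a),
          gt = as.numeric(a[[1]] > a[[2]]),
          geq = as.numeric(a[[1]] >= a[[2]]),
          lt = as.numeric(a[[1]] < a[[2]]),
          leq = as.numeric(a[[1]] <= a[[2]]),
          eq = as.numeric(a[[1]] == a[[2]]),
          neq = as.numeric(a[[1]] != a[[2]]),
          and = as.numeric(all(unlist(a) != 0)),
          or = as.numeric(any(unlist(a) != 0)),
          not = as.numeric(a[[1]] == 0),
          xor = as.numeric(sum(unlist(a) != 0) %% 2 == 1),
          {
            fd <- functions[[op]]
            if (is.null(fd))
              stop("unknown function: ", op, call. = FALSE)
            env2 <- setNames(a, fd$args)
            eval_math(fd$body, env2, functions)
          })
      })
  }
  ev(e)
}

#' Identifiers referenced by an expression
#' @param e A `mexpr`.
#' @return Character vector of identifier names (may include `"time"`).
#' @export
math_identifiers <- function(e) {
  out <- character(0)
  walk <- function(x) {
    if (x$kind == "name") out[[length(out) + 1L]] <<- x$name
    else if (x$kind == "call") for (a in x$args) walk(a)
  }
  walk(e)
  unique(out)
}

# Substitute function-definition calls by their bodies (arguments inlined).
# `defs` is a named list of list(args, body).  Used at compile time so that
# the bytecode VM never sees a user function.
inline_functions <- function(e, defs) {
  if (is.null(defs) || length(defs) == 0L) return(e)
  subst <- function(x, bind) {
    switch(x$kind,
      const = x,
      name = if (!is.null(bind[[x$name]])) bind[[x$name]] else x,
      call = mx_call(x$op, lapply(x$args, subst, bind = bind)))
  }
  walk <- function(x) {
    if (x$kind != "call") return(x)
    args <- lapply(x$args, walk)
    fd <- defs[[x$op]]
    if (!is.null(fd)) {
      if (length(fd$args) != length(args))
        stop("function ", x$op, " called with ", length(args),
             " arguments, expects ", length(fd$args), call. = FALSE)
      bind <- setNames(args, fd$args)
      return(walk(subst(fd$body, bind)))
    }
    mx_call(x$op, args)
  }
  walk(e)
}

# ---- bytecode compilation -------------------------------------------------
# Opcode numbers must match the enum in src/core.cpp.

.OPC <- c(const = 1L, var = 2L, time = 3L,
          add = 4L, sub = 5L, mul = 6L, div = 7L, pow = 8L, neg = 9L,
          exp = 10L, ln = 11L, log10 = 12L, sqrt = 13L, abs = 14L,
          floor = 15L, ceiling = 16L,
          sin = 17L, cos = 18L, tan = 19L, arcsin = 20L, arccos = 21L,
          arctan = 22L, sinh = 23L, cosh = 24L, tanh = 25L,
          min = 26L, max = 27L,
          gt = 28L, geq = 29L, lt = 30L, leq = 31L, eq = 32L, neq = 33L,
          and = 34L, or = 35L, not = 36L, xor = 37L, select = 38L)

# Compile a function-free mexpr to a flat postfix program.
# sym_index: named integer vector, identifier -> 1-based slot in the value
# vector.  Returns list(op, arg, num, depth).
compile_expr <- function(e, sym_index) {
  op <- integer(0); arg <- integer(0); num <- double(0)
  emit <- function(o, a = 0L, n = 0) {
    op[[length(op) + 1L]] <<- o
    arg[[length(arg) + 1L]] <<- a
    num[[length(num) + 1L]] <<- n
  }
  binfold <- function(code, args) {
    cc(args[[1]])
    for (i in seq_along(args)[-1]) { cc(args[[i]]); emit(code) }
  }
  cc <- function(x) {
    switch(x$kind,
      const = emit(.OPC[["const"]], 0L, x$value),
      name = {
        if (x$name == "time") { emit(.OPC[["time"]]); return(invisible()) }
        idx <- sym_index[[x$name]]
        if (is.null(idx) || is.na(idx))
          stop("unbound identifier in expression: ", x$name, call. = FALSE)
        emit(.OPC[["var"]], as.integer(idx))
      },
      call = {
        o <- x$op
        if (o == "piecewise") {
          # compile to nested selects, evaluated right-to-left
          n <- length(x$args)
          other <- if (n %% 2L == 1L) x$args[[n]] else mx_const(NaN)
          npieces <- n %/% 2L
          build <- other
          for (i in rev(seq_len(npieces))) {
            build <- list(val = x$args[[2L * i - 1L]],
                          cond = x$args[[2L * i]], rest = build)
          }
          compile_pw <- function(b) {
            if (is_mexpr(b)) { cc(b); return(invisible()) }
            cc(b$cond); cc(b$val); compile_pw(b$rest)
            emit(.OPC[["select"]])
          }
          compile_pw(build)
          return(invisible())
        }
        if (o == "neg" || o == "not" ||
            (o %in% c("exp", "ln", "log10", "sqrt", "abs", "floor",
                      "ceiling", "sin", "cos", "tan", "arcsin", "arccos",
                      "arctan", "sinh", "cosh", "tanh"))) {
          cc(x$args[[1]]); emit(.OPC[[o]])
          return(invisible())
        }
        if (o == "sub" && length(x$args) == 1L) {
          cc(x$args[[1]]); emit(.OPC[["neg"]])
          return(invisible())
        }
        if (o %in% c("add", "mul", "min", "max", "and", "or", "xor",
                     "sub")) {
          binfold(.OPC[[o]], x$args)
          return(invisible())
        }
        if (o %in% c("div", "pow", "gt", "geq", "lt", "leq", "eq",
                     "neq")) {
          cc(x$args[[1]]); cc(x$args[[2]]); emit(.OPC[[o]])
          return(invisible())
        }
        stop("cannot compile operator: ", o,
             " (function calls must be inlined first)", call. = FALSE)
      })
  }
  cc(e)
  # stack depth by simulation
  depth <- 0L; d <- 0L
  for (i in seq_along(op)) {
    o <- op[i]
    d <- d + if (o <= 3L) 1L
      else if (o %in% c(.OPC[["neg"]], .OPC[["not"]]) ||
               (o >= 10L && o <= 25L)) 0L
      else if (o == .OPC[["select"]]) -2L
      else -1L
    depth <- max(depth, d)
  }
  list(op = op, arg = arg, num = num, depth = max(depth, 1L))
}

#' @export
print.mexpr <- function(x, ...) {
  cat(deparse_mexpr(x), "\n")
  invisible(x)
}

#' Render an expression tree as infix text
#' @param e A `mexpr`.
#' @return Character scalar.
#' @export
deparse_mexpr <- function(e) {
  inv <- c(add = "+", sub = "-", mul = "*", div = "/", pow = "^",
           gt = ">", geq = ">=", lt = "<", leq = "<=", eq = "==",
           neq = "!=", and = "&", or = "|")
  dp <- function(x) {
    switch(x$kind,
      const = format(x$value, digits = 15),
      name = x$name,
      call = {
        if (x$op %in% names(inv)) {
          paste0("(", paste(vapply(x$args, dp, character(1)),
                            collapse = paste0(" ", inv[[x$op]], " ")), ")")
        } else if (x$op == "neg") {
          paste0("(-", dp(x$args[[1]]), ")")
        } else if (x$op == "not") {
          paste0("!(", dp(x$args[[1]]), ")")
        } else {
          fn <- switch(x$op, ln = "log", arcsin = "asin",
                       arccos = "acos", arctan = "atan", x$op)
          paste0(fn, "(", paste(vapply(x$args, dp, character(1)),
                                collapse = ", "), ")")
        }
      })
  }
  dp(e)
}
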