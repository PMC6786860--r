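# Parsing and validation of model-description strings. A model is a
# multi-line string in which each non-empty line declares one entry:
#
#   dX/dt = rhs : unit (flags)     a differential equation
#   X = rhs : unit (flags)         a subexpression, re-evaluated on demand
#   X : unit (flags)               a parameter (per-instance state, no rhs)
#
# The unit annotation declares the dimension of the variable itself; for a
# differential entry the right-hand side must therefore have dimension
# unit/second. Numeric literals are dimensionless -- every dimensioned
# constant enters through the namespace.

KNOWN_FLAGS <- c("summed", "linked", "constant", "unless_refractory", "integer")

RESERVED_DIMS <- function() list(
  t = dimension(s = 1), dt = dimension(s = 1),
  i = DIMLESS, j = DIMLESS, N = DIMLESS,
  xi = dimension(s = -0.5)
)

BUILTIN_FUNCTIONS <- c("exp", "log", "log10", "sqrt", "abs", "sin", "cos",
                       "tan", "tanh", "sinh", "cosh", "sign", "floor",
                       "ceiling", "clip", "int", "rand", "randn", "exprel")

#' Parse model equations
#'
#' Parses a multi-line model description into an equation set with one
#' entry per line. Lines may carry trailing comments introduced by `#`.
#' Flags are given as a parenthesized, comma-separated list after the unit,
#' e.g. `x : 1 (linked)`.
#'
#' @param text multi-line model string.
#' @return an object of class `"equation_set"`: a list with `entries`
#'   (named list of entries, in source order) and `identifiers` (free names
#'   referenced by any right-hand side).
#' @examples
#' eqs <- parse_equations("dv/dt = -v/tau : volt")
#' names(eqs$entries)
#' @export
parse_equations <- function(text) {
  raw <- strsplit(text, "\n", fixed = TRUE)[[1]]
  raw <- trimws(vapply(raw, function(l) sub("#.*$", "", l), character(1), USE.NAMES = FALSE))
  # join continuation lines while parentheses are unbalanced
  lines <- character(); lnos <- integer(); open <- 0L
  for (li in seq_along(raw)) {
    if (!nzchar(raw[[li]]) && open == 0L) next
    if (open == 0L) { lines <- c(lines, raw[[li]]); lnos <- c(lnos, li) }
    else lines[[length(lines)]] <- paste(lines[[length(lines)]], raw[[li]])
    bal <- function(s, ch) lengths(regmatches(s, gregexpr(ch, s, fixed = TRUE)))
    open <- bal(lines[[length(lines)]], "(") - bal(lines[[length(lines)]], ")")
  }
  entries <- list()
  for (k in seq_along(lines)) {
    line <- lines[[k]]
    li <- lnos[[k]]
    if (!nzchar(line)) next
    entry <- parse_equation_line(line, li)
    if (entry$name %in% names(entries))
      duplicate_definition(sprintf("line %d: '%s' is defined twice", li, entry$name))
    if (unit_in_expressions(entry$name) ||
        entry$name %in% c(BUILTIN_FUNCTIONS, names(RESERVED_DIMS())))
      name_collision(sprintf("line %d: '%s' shadows a reserved name, unit or function",
                             li, entry$name))
    check_flags(entry, li)
    entries[[entry$name]] <- entry
  }
  free <- character()
  for (entry in entries) {
    if (!is.null(entry$rhs))
      free <- union(free, expr_names(entry$rhs)$vars)
  }
  structure(list(entries = entries,
                 identifiers = setdiff(free, names(entries))),
            class = "equation_set")
}

parse_equation_line <- function(line, li) {
  where <- sprintf(" (line %d)", li)
  # split off the unit annotation at the first ':'
  colon <- regexpr(":", line, fixed = TRUE)
  if (colon < 0)
    eq_abort("eqspike_error", sprintf("syntax error%s: missing ': unit' in '%s'", where, line))
  lhs_rhs <- trimws(substr(line, 1, colon - 1))
  unit_part <- trimws(substr(line, colon + 1, nchar(line)))
  m <- regmatches(unit_part, regexec("^([^()]*?)\\s*(\\(([^)]*)\\))?$", unit_part))[[1]]
  if (!length(m))
    eq_abort("eqspike_error", sprintf("syntax error%s: bad unit/flags in '%s'", where, line))
  unit_text <- trimws(m[2])
  flags <- if (nzchar(m[4])) trimws(strsplit(m[4], ",", fixed = TRUE)[[1]]) else character()
  if (!nzchar(unit_text))
    eq_abort("eqspike_error", sprintf("syntax error%s: empty unit in '%s'", where, line))
  dim <- if (identical(unit_text, "1") || identical(unit_text, "integer") ||
             identical(unit_text, "boolean")) DIMLESS
         else quantity_dim(parse_unit_expression(unit_text))
  if (identical(unit_text, "integer")) flags <- union(flags, "integer")

  dm <- regmatches(lhs_rhs, regexec(
    "^d\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*/\\s*dt\\s*=\\s*(.+)$", lhs_rhs))[[1]]
  if (length(dm)) {
    return(list(name = dm[2], kind = "differential",
                rhs = parse_rhs(dm[3], where), rhs_text = trimws(dm[3]),
                dim = dim, unit_text = unit_text, flags = flags))
  }
  sm <- regmatches(lhs_rhs, regexec(
    "^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", lhs_rhs))[[1]]
  if (length(sm)) {
    return(list(name = sm[2], kind = "subexpression",
                rhs = parse_rhs(sm[3], where), rhs_text = trimws(sm[3]),
                dim = dim, unit_text = unit_text, flags = flags))
  }
  pm <- regmatches(lhs_rhs, regexec("^([A-Za-z_][A-Za-z0-9_]*)$", lhs_rhs))[[1]]
  if (length(pm)) {
    return(list(name = pm[2], kind = "parameter", rhs = NULL, rhs_text = NULL,
                dim = dim, unit_text = unit_text, flags = flags))
  }
  eq_abort("eqspike_error", sprintf("syntax error%s: cannot parse '%s'", where, line))
}

check_flags <- function(entry, li) {
  bad <- setdiff(entry$flags, KNOWN_FLAGS)
  if (length(bad))
    illegal_flag(sprintf("line %d: unknown flag '%s'", li, bad[1]))
  if ("summed" %in% entry$flags && entry$kind != "subexpression")
    illegal_flag(sprintf("line %d: 'summed' is only legal on subexpressions", li))
  if ("linked" %in% entry$flags && entry$kind != "parameter")
    illegal_flag(sprintf("line %d: 'linked' is only legal on parameters", li))
  if ("constant" %in% entry$flags && entry$kind != "parameter")
    illegal_flag(sprintf("line %d: 'constant' is only legal on parameters", li))
  if ("unless_refractory" %in% entry$flags && entry$kind != "differential")
    illegal_flag(sprintf("line %d: 'unless_refractory' is only legal on differential equations", li))
}

#' Format an equation set back to model text
#'
#' Inverse of [parse_equations()]: re-parsing the returned text yields an
#' equivalent equation set.
#' @param eqs an equation set.
#' @export
format_equations <- function(eqs) {
  paste(vapply(eqs$entries, function(e) {
    flags <- if (length(e$flags)) paste0(" (", paste(e$flags, collapse = ", "), ")") else ""
    head <- switch(e$kind,
      differential = sprintf("d%s/dt = %s", e$name, deparse1(e$rhs)),
      subexpression = sprintf("%s = %s", e$name, deparse1(e$rhs)),
      parameter = e$name)
    paste0(head, " : ", e$unit_text, flags)
  }, character(1)), collapse = "\n")
}

# namespace entries may be Quantities, bare numerics (dimensionless), or
# dimensions; normalize to dimensions for checking
namespace_dims <- function(namespace) {
  out <- list()
  for (nm in names(namespace)) {
    v <- namespace[[nm]]
    out[[nm]] <- if (inherits(v, "eq_dimension")) v else quantity_dim(v)
  }
  out
}

#' Validate the dimensional consistency of an equation set
#'
#' Infers the dimension of every right-hand side and checks it against the
#' declared dimension (for differential entries, declared dimension per
#' second). Boolean expressions must be dimensionless.
#'
#' @param eqs an equation set from [parse_equations()].
#' @param namespace named list supplying a [quantity()] or [dimension()]
#'   for every free identifier (external constants, other groups'
#'   variables), and signatures for registered functions.
#' @param functions named list of registered function signatures (see
#'   [register_function()]); built-ins are always available.
#' @return the equation set, with inferred dimensions attached.
#' @export
validate_dimensions <- function(eqs, namespace = list(), functions = list()) {
  dimenv <- c(RESERVED_DIMS(), namespace_dims(namespace))
  for (e in eqs$entries) dimenv[[e$name]] <- e$dim
  unknown <- setdiff(eqs$identifiers, c(names(dimenv), BUILTIN_FUNCTIONS, names(functions)))
  unknown <- unknown[!vapply(unknown, unit_in_expressions, logical(1))]
  if (length(unknown))
    unresolved_identifier(sprintf("unknown identifier(s): %s",
                                  paste(unknown, collapse = ", ")))
  second <- dimension(s = 1)
  for (e in eqs$entries) {
    if (is.null(e$rhs)) next
    inferred <- infer_dim(e$rhs, dimenv, functions)
    expected <- if (e$kind == "differential") dim_div(e$dim, second) else e$dim
    if (!dim_eq(inferred, expected))
      dimension_mismatch(sprintf(
        "entry '%s': right-hand side has dimension [%s], expected [%s]",
        e$name, format(inferred), format(expected)))
    if (is_boolean_expr(e$rhs) && !is_dimless(e$dim))
      dimension_mismatch(sprintf("entry '%s': boolean expressions must be dimensionless",
                                 e$name))
    eqs$entries[[e$name]]$inferred_dim <- inferred
  }
  eqs$validated <- TRUE
  eqs$dims <- dimenv
  eqs
}

# recursive dimension inference over an expression tree
infer_dim <- function(e, dimenv, functions = list()) {
  if (is.numeric(e) || is.logical(e)) return(DIMLESS)
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names(dimenv)) return(dimenv[[nm]])
    if (unit_in_expressions(nm)) return(quantity_dim(get_unit(nm)))
    unresolved_identifier(sprintf("unknown identifier '%s'", nm))
  }
  stopifnot(is.call(e))
  op <- as.character(e[[1]])
  if (op == "(") return(infer_dim(e[[2]], dimenv, functions))
  if (op %in% c("+", "-") && length(e) == 2) return(infer_dim(e[[2]], dimenv, functions))
  if (op %in% c("+", "-")) {
    a <- infer_dim(e[[2]], dimenv, functions); b <- infer_dim(e[[3]], dimenv, functions)
    if (!dim_eq(a, b))
      dimension_mismatch(sprintf("cannot %s [%s] and [%s] in '%s'",
                                 if (op == "+") "add" else "subtract",
                                 format(a), format(b), deparse1(e)))
    return(a)
  }
  if (op == "*") return(dim_mul(infer_dim(e[[2]], dimenv, functions),
                                infer_dim(e[[3]], dimenv, functions)))
  if (op == "/") return(dim_div(infer_dim(e[[2]], dimenv, functions),
                                infer_dim(e[[3]], dimenv, functions)))
  if (op == "^") {
    base <- infer_dim(e[[2]], dimenv, functions)
    ex <- e[[3]]
    exd <- infer_dim(ex, dimenv, functions)
    if (!is_dimless(exd)) dimension_mismatch("exponent must be dimensionless")
    if (is_dimless(base)) return(DIMLESS)
    if (!is.numeric(ex)) {
      if (is.call(ex) && as.character(ex[[1]]) %in% c("+", "-") && length(ex) == 2 &&
          is.numeric(ex[[2]]))
        ex <- if (as.character(ex[[1]]) == "-") -ex[[2]] else ex[[2]]
      else
        dimension_mismatch(sprintf(
          "cannot raise dimension [%s] to a non-literal power in '%s'",
          format(base), deparse1(e)))
    }
    return(dim_pow(base, ex))
  }
  if (op %in% c("==", "!=", "<", ">", "<=", ">=")) {
    a <- infer_dim(e[[2]], dimenv, functions); b <- infer_dim(e[[3]], dimenv, functions)
    if (!dim_eq(a, b))
      dimension_mismatch(sprintf("cannot compare [%s] and [%s] in '%s'",
                                 format(a), format(b), deparse1(e)))
    return(DIMLESS)
  }
  if (op %in% c("&", "|")) {
    for (i in 2:3) {
      d <- infer_dim(e[[i]], dimenv, functions)
      if (!is_dimless(d))
        dimension_mismatch(sprintf("boolean operands must be dimensionless in '%s'",
                                   deparse1(e)))
    }
    return(DIMLESS)
  }
  if (op == "!") {
    if (!is_dimless(infer_dim(e[[2]], dimenv, functions)))
      dimension_mismatch("operand of 'not' must be dimensionless")
    return(DIMLESS)
  }
  # function call
  args <- lapply(seq_along(e)[-1], function(i) infer_dim(e[[i]], dimenv, functions))
  if (op %in% names(functions)) {
    sig <- functions[[op]]
    if (length(args) != length(sig$arg_dims))
      eq_abort("eqspike_error", sprintf("'%s' called with %d argument(s), expects %d",
                                        op, length(args), length(sig$arg_dims)))
    for (k in seq_along(args))
      if (!dim_eq(args[[k]], sig$arg_dims[[k]]))
        dimension_mismatch(sprintf("argument %d of '%s' has dimension [%s], expected [%s]",
                                   k, op, format(args[[k]]), format(sig$arg_dims[[k]])))
    return(sig$return_dim)
  }
  switch(op,
    exp = , log = , log10 = , sin = , cos = , tan = , tanh = , sinh = , cosh = ,
    exprel = {
      if (!is_dimless(args[[1]]))
        dimension_mismatch(sprintf("%s() requires a dimensionless argument", op))
      DIMLESS
    },
    sqrt = dim_pow(args[[1]], 0.5),
    abs = , floor = , ceiling = args[[1]],
    sign = DIMLESS,
    int = {
      if (!is_dimless(args[[1]]))
        dimension_mismatch("int() requires a dimensionless argument")
      DIMLESS
    },
    clip = {
      if (!dim_eq(args[[1]], args[[2]]) || !dim_eq(args[[1]], args[[3]]))
        dimension_mismatch("clip() requires all arguments of equal dimension")
      args[[1]]
    },
    rand = , randn = DIMLESS,
    unresolved_identifier(sprintf("unknown function '%s'", op))
  )
}

#' Order subexpressions topologically
#'
#' Returns entry names such that every subexpression precedes all entries
#' that reference it; differential entries come last.
#'
#' @param eqs an equation set.
#' @return character vector of entry names.
#' @export
order_subexpressions <- function(eqs) {
  subs <- names(Filter(function(e) e$kind == "subexpression", eqs$entries))
  deps <- lapply(eqs$entries[subs], function(e) intersect(expr_names(e$rhs)$vars, subs))
  names(deps) <- subs
  ordered <- character()
  visiting <- character()
  visit <- function(nm) {
    if (nm %in% ordered) return(invisible())
    if (nm %in% visiting)
      cyclic_dependency(sprintf("cyclic subexpression dependency involving: %s",
                                paste(c(visiting, nm), collapse = " -> ")))
    visiting <<- c(visiting, nm)
    for (d in deps[[nm]]) visit(d)
    visiting <<- setdiff(visiting, nm)
    ordered <<- c(ordered, nm)
  }
  for (nm in subs) visit(nm)
  c(ordered, names(Filter(function(e) e$kind == "differential", eqs$entries)))
}

#' Detect stochastic differential entries
#'
#' Finds every differential entry whose right-hand side references the
#' reserved white-noise symbol `xi` (dimension second^(-1/2)). `xi` may
#' appear only linearly and only inside differential equations.
#'
#' @param eqs an equation set.
#' @return character vector of stochastic entry names (possibly empty).
#' @export
detect_stochastic <- function(eqs) {
  stoch <- character()
  for (e in eqs$entries) {
    if (is.null(e$rhs) || !expr_uses(e$rhs, "xi")) next
    if (e$kind != "differential")
      illegal_noise(sprintf("entry '%s': xi may only appear in differential equations",
                            e$name))
    g <- eq_deriv(e$rhs, "xi")
    if (is.null(g) || expr_uses(g, "xi"))
      illegal_noise(sprintf("entry '%s': xi must appear linearly", e$name))
    stoch <- c(stoch, e$name)
  }
  stoch
}

# split an rhs f(x, xi) = drift + g*xi into drift and noise coefficient g
split_noise <- function(rhs) {
  g <- eq_deriv(rhs, "xi")
  if (is.null(g)) illegal_noise("xi must appear linearly")
  drift <- subst_expr(rhs, list(xi = 0))
  list(drift = drift, g = g)
}

# --- statement strings (reset, on_pre, state initialization) ---------------

#' Parse a statement string
#'
#' Statements (used for reset code and synaptic event code) are assignments
#' `X = expr` or augmented assignments `X += expr` / `X -= expr`, separated
#' by newlines or semicolons and executed top to bottom.
#'
#' @param text statement string.
#' @return list of parsed statements (target, op, rhs).
#' @export
parse_statements <- function(text) {
  pieces <- unlist(strsplit(text, "[;\n]"))
  out <- list()
  for (s in pieces) {
    s <- trimws(sub("#.*$", "", s))
    if (!nzchar(s)) next
    m <- regmatches(s, regexec(
      "^([A-Za-z_][A-Za-z0-9_]*)\\s*(\\+=|-=|=)\\s*(.+)$", s))[[1]]
    if (!length(m) || (m[3] == "=" && grepl("^=", m[4])))
      eq_abort("eqspike_error", sprintf("cannot parse statement '%s'", s))
    out[[length(out) + 1L]] <- list(target = m[2], op = m[3],
                                    rhs = parse_rhs(m[4]), rhs_text = m[4])
  }
  out
}
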