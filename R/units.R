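# Physical quantities: numeric values (scalar or vector) tagged with a
# 7-exponent SI dimension. All stored values are in SI base scale; display
# units (mV, ms, mS/cm2 ...) exist only at parse/format time.

#' Construct a physical dimension
#'
#' A dimension is a vector of seven exponents over the SI base dimensions
#' (metre, kilogram, second, ampere, kelvin, mole, candela). Exponents may
#' be fractional so that e.g. the white-noise symbol of stochastic
#' differential equations, of dimension second^(-1/2), is representable.
#'
#' @param m,kg,s,A,K,mol,cd exponents of the respective base dimensions.
#' @return a named numeric vector of length 7 with class `"eq_dimension"`.
#' @examples
#' dimension(m = 2, kg = 1, s = -3, A = -1)  # volt
#' @export
dimension <- function(m = 0, kg = 0, s = 0, A = 0, K = 0, mol = 0, cd = 0) {
  structure(c(m = m, kg = kg, s = s, A = A, K = K, mol = mol, cd = cd),
            class = "eq_dimension")
}

DIMLESS <- dimension()

dim_eq <- function(a, b) isTRUE(all(abs(unclass(a) - unclass(b)) < 1e-9))
dim_mul <- function(a, b) structure(unclass(a) + unclass(b), class = "eq_dimension")
dim_div <- function(a, b) structure(unclass(a) - unclass(b), class = "eq_dimension")
dim_pow <- function(a, p) structure(unclass(a) * p, class = "eq_dimension")
is_dimless <- function(d) dim_eq(d, DIMLESS)

#' @export
format.eq_dimension <- function(x, ...) {
  e <- unclass(x)
  nz <- which(abs(e) > 1e-12)
  if (!length(nz)) return("1")
  paste(vapply(nz, function(i) {
    if (abs(e[i] - 1) < 1e-12) names(e)[i]
    else paste0(names(e)[i], "**", format(e[i], digits = 10))
  }, character(1)), collapse = " * ")
}

#' @export
print.eq_dimension <- function(x, ...) { cat("<dimension> ", format(x), "\n", sep = ""); invisible(x) }

#' Construct a Quantity
#'
#' A quantity is a numeric scalar or vector together with one physical
#' dimension shared by all its elements. Values are stored in SI base
#' scale (volts, seconds, siemens per square metre, ...).
#'
#' @param value numeric scalar or vector, SI base-scaled.
#' @param dim an [dimension()] object (default dimensionless).
#' @return an object of class `"quantity"`.
#' @examples
#' quantity(0.02, dimension(s = 1))   # 20 ms
#' @export
quantity <- function(value, dim = DIMLESS) {
  stopifnot(is.numeric(value) || is.logical(value))
  if (is.logical(value)) value <- as.numeric(value)
  structure(value, dim_exp = dim, class = "quantity")  # keeps array shape
}

#' @export
is_quantity <- function(x) inherits(x, "quantity")

#' Extract the dimension of a quantity
#' @param x a quantity (bare numerics are dimensionless).
#' @return an `eq_dimension`.
#' @export
quantity_dim <- function(x) {
  if (is_quantity(x)) attr(x, "dim_exp") else DIMLESS
}

#' Strip a quantity to its SI-scaled numeric value
#' @param x quantity or numeric.
#' @export
si_value <- function(x) {
  if (is_quantity(x)) {
    x <- unclass(x)
    attr(x, "dim_exp") <- NULL
    x
  } else if (is.logical(x)) as.numeric(x) else x
}

as_qty <- function(x) if (is_quantity(x)) x else quantity(x)

#' @export
Ops.quantity <- function(e1, e2) {
  op <- .Generic
  if (missing(e2)) {  # unary + / -
    return(quantity(get(op)(si_value(e1)), quantity_dim(e1)))
  }
  d1 <- quantity_dim(e1); d2 <- quantity_dim(e2)
  v1 <- si_value(e1); v2 <- si_value(e2)
  switch(op,
    "+" = , "-" = {
      if (!dim_eq(d1, d2))
        dimension_mismatch(sprintf("cannot %s quantities of dimension [%s] and [%s]",
                                   if (op == "+") "add" else "subtract",
                                   format(d1), format(d2)))
      quantity(get(op)(v1, v2), d1)
    },
    "*" = quantity(v1 * v2, dim_mul(d1, d2)),
    "/" = quantity(v1 / v2, dim_div(d1, d2)),
    "^" = {
      if (!is_dimless(d2))
        dimension_mismatch("exponent must be dimensionless")
      if (length(v2) != 1)
        dimension_mismatch("exponent must be a scalar")
      if (!is_dimless(d1) && !is_small_rational(v2))
        dimension_mismatch(sprintf(
          "cannot raise a quantity of dimension [%s] to the non-rational power %g",
          format(d1), v2))
      quantity(v1^v2, dim_pow(d1, v2))
    },
    "==" = , "!=" = , "<" = , ">" = , "<=" = , ">=" = {
      if (!dim_eq(d1, d2))
        dimension_mismatch(sprintf("cannot compare quantities of dimension [%s] and [%s]",
                                   format(d1), format(d2)))
      get(op)(v1, v2)
    },
    eq_abort("eqspike_error", sprintf("operation '%s' not defined for quantities", op))
  )
}

# rational with small denominator (covers 1/2 used by noise dimensions)
is_small_rational <- function(p) {
  any(abs(p * (1:48) - round(p * (1:48))) < 1e-9)
}

#' @export
Math.quantity <- function(x, ...) {
  d <- quantity_dim(x); v <- si_value(x)
  g <- .Generic
  if (g %in% c("abs", "floor", "ceiling", "trunc", "round", "signif", "cummax", "cummin"))
    return(quantity(get(g)(v, ...), d))
  if (g == "sqrt") return(quantity(sqrt(v), dim_pow(d, 0.5)))
  if (!is_dimless(d))
    dimension_mismatch(sprintf("%s() requires a dimensionless argument, got [%s]", g, format(d)))
  quantity(get(g)(v, ...), DIMLESS)
}

#' @export
format.quantity <- function(x, ...) {
  d <- quantity_dim(x)
  v <- si_value(x)
  vs <- paste(format(v, digits = 15, trim = TRUE), collapse = ", ")
  if (length(v) > 1) vs <- paste0("c(", vs, ")")
  if (is_dimless(d)) vs else paste(vs, "*", format(d))
}

#' @export
print.quantity <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
length.quantity <- function(x) length(si_value(x))

#' @export
`[.quantity` <- function(x, ...) quantity(si_value(x)[...], quantity_dim(x))

# ---------------------------------------------------------------------------
# unit registry

the_units <- new.env(parent = emptyenv())

register_unit <- function(name, q, powers = TRUE) {
  assign(name, q, envir = the_units)
  if (powers) {
    assign(paste0(name, "2"), q^2, envir = the_units)
    assign(paste0(name, "3"), q^3, envir = the_units)
  }
}

init_units <- function() {
  base <- list(
    metre   = quantity(1, dimension(m = 1)),
    second  = quantity(1, dimension(s = 1)),
    kilogram = quantity(1, dimension(kg = 1)),
    ampere  = quantity(1, dimension(A = 1)),
    kelvin  = quantity(1, dimension(K = 1)),
    mole    = quantity(1, dimension(mol = 1)),
    candela = quantity(1, dimension(cd = 1)),
    # coherent derived units
    hertz   = quantity(1, dimension(s = -1)),
    newton  = quantity(1, dimension(kg = 1, m = 1, s = -2)),
    pascal  = quantity(1, dimension(kg = 1, m = -1, s = -2)),
    joule   = quantity(1, dimension(kg = 1, m = 2, s = -2)),
    watt    = quantity(1, dimension(kg = 1, m = 2, s = -3)),
    coulomb = quantity(1, dimension(A = 1, s = 1)),
    volt    = quantity(1, dimension(kg = 1, m = 2, s = -3, A = -1)),
    farad   = quantity(1, dimension(kg = -1, m = -2, s = 4, A = 2)),
    ohm     = quantity(1, dimension(kg = 1, m = 2, s = -3, A = -2)),
    siemens = quantity(1, dimension(kg = -1, m = -2, s = 3, A = 2)),
    gram    = quantity(1e-3, dimension(kg = 1)),
    litre   = quantity(1e-3, dimension(m = 3))
  )
  short <- c(metre = "m", second = "s", ampere = "A", kelvin = "K",
             gram = "g", mole = "mol", candela = "cd", hertz = "Hz",
             newton = "N", pascal = "Pa", joule = "J", watt = "W",
             coulomb = "C", volt = "V", farad = "F", ohm = "ohm",
             siemens = "S", litre = "l")
  prefixes <- c(Y = 1e24, Z = 1e21, E = 1e18, P = 1e15, T = 1e12, G = 1e9,
                M = 1e6, k = 1e3, h = 1e2, d = 1e-1, c = 1e-2, m = 1e-3,
                u = 1e-6, n = 1e-9, p = 1e-12, f = 1e-15, a = 1e-18,
                z = 1e-21, y = 1e-24)
  for (nm in names(base)) {
    q <- base[[nm]]
    register_unit(nm, q)
    for (pf in names(prefixes)) register_unit(paste0(pf, nm), quantity(prefixes[[pf]]) * q)
    if (nm %in% names(short)) {
      s <- short[[nm]]
      register_unit(s, q)
      if (!nm %in% c("gram", "kilogram"))  # SI prefixes attach to gram, not kg
        for (pf in names(prefixes)) register_unit(paste0(pf, s), quantity(prefixes[[pf]]) * q)
    }
  }
  for (pf in names(prefixes)) register_unit(paste0(pf, "g"), quantity(prefixes[[pf]] * 1e-3, dimension(kg = 1)))
  register_unit("kg", base$kilogram)
  register_unit("meter", base$metre)
  register_unit("amp", base$ampere)
  for (pf in names(prefixes)) {
    register_unit(paste0(pf, "meter"), quantity(prefixes[[pf]]) * base$metre)
    register_unit(paste0(pf, "amp"), quantity(prefixes[[pf]]) * base$ampere)
  }
  invisible(NULL)
}

unit_is_registered <- function(name) exists(name, envir = the_units, inherits = FALSE)

# Unit names usable directly inside model/statement expressions ("-50*mV").
# Single-character names (s, m, g, A, ...) are excluded so that common
# model variable names never shadow a unit.
unit_in_expressions <- function(name) nchar(name) > 1 && unit_is_registered(name)

the_unit_value_env <- new.env(parent = emptyenv())

# environment binding every expression-layer unit name to its SI value;
# sits below the builtin functions in every kernel's lookup chain
unit_value_env <- function() {
  if (is.null(the_unit_value_env$env)) {
    e <- new.env(parent = baseenv())
    for (nm in ls(the_units)) {
      if (nchar(nm) > 1) {
        v <- get(nm, envir = the_units)
        if (length(si_value(v)) == 1) assign(nm, si_value(v), envir = e)
      }
    }
    the_unit_value_env$env <- e
  }
  the_unit_value_env$env
}

get_unit <- function(name) {
  if (!unit_is_registered(name))
    unknown_unit(sprintf("unknown unit '%s'", name))
  get(name, envir = the_units, inherits = FALSE)
}

#' Parse a unit expression into an SI-scaled Quantity
#'
#' Accepts products, quotients and powers of registered unit names with an
#' optional numeric factor, e.g. `"10*mV"`, `"mS/cm2"`, `"ms**-1"`, `"1"`.
#' The result is the equivalent quantity on the SI base scale, so
#' `parse_unit_expression("mS/cm2")` is 10 siemens per square metre.
#'
#' @param text a unit expression string.
#' @return a [quantity()].
#' @examples
#' parse_unit_expression("20*ms")    # 0.02 s
#' parse_unit_expression("mS/cm2")   # 10 S/m^2
#' @export
parse_unit_expression <- function(text) {
  expr <- tryCatch(str2lang(translate_operators(text)),
                   error = function(e) eq_abort("eqspike_error",
                     sprintf("malformed unit expression '%s': %s", text, conditionMessage(e))))
  eval_unit_expr(expr)
}

eval_unit_expr <- function(e) {
  if (is.numeric(e)) return(quantity(e))
  if (is.name(e)) return(get_unit(as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(eval_unit_expr(e[[2]]))
    if (op %in% c("+", "-") && length(e) == 2) return(get(op)(eval_unit_expr(e[[2]])))
    if (op %in% c("*", "/", "^") && length(e) == 3)
      return(get(op)(eval_unit_expr(e[[2]]), eval_unit_expr(e[[3]])))
  }
  eq_abort("eqspike_error", sprintf("unsupported construct in unit expression: %s", deparse(e)))
}

#' Format a quantity as a canonical, re-parseable unit string
#'
#' The output is `"<value> * <base-unit product>"` using SI base unit
#' names, such that [parse_unit_expression()] applied to it yields an
#' equal quantity.
#'
#' @param x a quantity.
#' @export
format_unit_expression <- function(x) {
  d <- quantity_dim(x)
  v <- si_value(x)
  stopifnot(length(v) == 1)
  if (is_dimless(d)) return(format(v, digits = 17))
  paste(format(v, digits = 17), "*", format(d))
}
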