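# Expression-tree utilities shared by the equation parser, the dimension
# checker, the linearity detector and the kernel compiler. Model text uses
# Python-flavoured operators (`**`, `and`, `or`, `not`); they are rewritten
# to their host-language equivalents before parsing, after which expression
# trees are ordinary R calls.

translate_operators <- function(text) {
  text <- gsub("**", "^", text, fixed = TRUE)
  text <- gsub("\\band\\b", "&", text, perl = TRUE)
  text <- gsub("\\bor\\b", "|", text, perl = TRUE)
  text <- gsub("\\bnot\\b", "!", text, perl = TRUE)
  text
}

parse_rhs <- function(text, where = "") {
  tryCatch(str2lang(translate_operators(text)),
           error = function(e) eq_abort("eqspike_error",
             sprintf("syntax error%s in '%s': %s", where, text, conditionMessage(e))))
}

# all identifiers referenced by an expression (function names excluded from
# `vars`, collected separately under `funs`)
expr_names <- function(e, vars = character(), funs = character()) {
  walk <- function(e) {
    if (is.name(e)) {
      vars[[length(vars) + 1L]] <<- as.character(e)
    } else if (is.call(e)) {
      head <- e[[1]]
      if (is.name(head)) {
        op <- as.character(head)
        if (!op %in% c("+", "-", "*", "/", "^", "(", "==", "!=", "<", ">",
                       "<=", ">=", "&", "|", "!"))
          funs[[length(funs) + 1L]] <<- op
      }
      for (i in seq_along(e)[-1]) walk(e[[i]])
    }
  }
  walk(e)
  list(vars = unique(vars), funs = unique(funs))
}

expr_uses <- function(e, name) name %in% expr_names(e)$vars

# substitute names by expressions (used to inline subexpressions)
subst_expr <- function(e, map) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names(map)) return(map[[nm]])
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) e[[i]] <- subst_expr(e[[i]], map)
    return(e)
  }
  e
}

# --- small constant-folding helpers keep derived expressions readable ------

is_zero <- function(e) is.numeric(e) && length(e) == 1 && e == 0
is_one <- function(e) is.numeric(e) && length(e) == 1 && e == 1

mk_add <- function(a, b) {
  if (is_zero(a)) return(b)
  if (is_zero(b)) return(a)
  call("+", a, b)
}
mk_sub <- function(a, b) {
  if (is_zero(b)) return(a)
  if (is_zero(a)) return(call("-", b))
  call("-", a, b)
}
mk_mul <- function(a, b) {
  if (is_zero(a) || is_zero(b)) return(0)
  if (is_one(a)) return(b)
  if (is_one(b)) return(a)
  call("*", a, b)
}
mk_div <- function(a, b) {
  if (is_zero(a)) return(0)
  if (is_one(b)) return(a)
  call("/", a, b)
}

# Symbolic derivative over the model grammar. Returns NULL when the
# expression is not differentiable in closed form w.r.t. `var` (e.g. `var`
# appears inside an unknown function) -- callers treat NULL as "nonlinear".
eq_deriv <- function(e, var) {
  if (is.numeric(e) || is.logical(e)) return(0)
  if (is.name(e)) return(if (as.character(e) == var) 1 else 0)
  if (!is.call(e)) return(NULL)
  op <- as.character(e[[1]])
  if (op == "(") return(eq_deriv(e[[2]], var))
  if (op %in% c("+", "-") && length(e) == 2) {
    d <- eq_deriv(e[[2]], var)
    if (is.null(d)) return(NULL)
    return(if (op == "-") mk_sub(0, d) else d)
  }
  if (op %in% c("+", "-")) {
    da <- eq_deriv(e[[2]], var); db <- eq_deriv(e[[3]], var)
    if (is.null(da) || is.null(db)) return(NULL)
    return(if (op == "+") mk_add(da, db) else mk_sub(da, db))
  }
  if (op == "*") {
    a <- e[[2]]; b <- e[[3]]
    da <- eq_deriv(a, var); db <- eq_deriv(b, var)
    if (is.null(da) || is.null(db)) return(NULL)
    return(mk_add(mk_mul(da, b), mk_mul(a, db)))
  }
  if (op == "/") {
    a <- e[[2]]; b <- e[[3]]
    da <- eq_deriv(a, var); db <- eq_deriv(b, var)
    if (is.null(da) || is.null(db)) return(NULL)
    if (is_zero(db)) return(mk_div(da, b))
    return(mk_sub(mk_div(da, b), mk_div(mk_mul(a, db), call("^", b, 2))))
  }
  if (op == "^") {
    base <- e[[2]]; ex <- e[[3]]
    if (expr_uses(ex, var)) return(NULL)  # var in the exponent: give up
    db <- eq_deriv(base, var)
    if (is.null(db)) return(NULL)
    if (is_zero(db)) return(0)
    return(mk_mul(mk_mul(ex, call("^", base, mk_sub(ex, 1))), db))
  }
  if (op %in% c("==", "!=", "<", ">", "<=", ">=", "&", "|", "!")) {
    # boolean expressions are piecewise constant; derivative 0 unless the
    # variable appears inside, in which case we refuse
    if (any(vapply(seq_along(e)[-1], function(i) expr_uses(e[[i]], var), logical(1))))
      return(NULL)
    return(0)
  }
  # function call
  if (length(e) == 2) {
    u <- e[[2]]
    du <- eq_deriv(u, var)
    if (is.null(du)) return(NULL)
    if (is_zero(du)) return(0)
    inner <- switch(op,
      exp = call("exp", u),
      log = mk_div(1, u),
      sqrt = mk_div(1, mk_mul(2, call("sqrt", u))),
      sin = call("cos", u),
      cos = mk_sub(0, call("sin", u)),
      tanh = mk_div(1, call("^", call("cosh", u), 2)),
      sinh = call("cosh", u),
      cosh = call("sinh", u),
      NULL)
    if (is.null(inner)) return(NULL)
    return(mk_mul(inner, du))
  }
  # unknown multi-argument call: constant in var or give up
  if (any(vapply(seq_along(e)[-1], function(i) expr_uses(e[[i]], var), logical(1))))
    return(NULL)
  0
}

# does the expression tree contain a boolean operator at its root (looking
# through parentheses and and/or/not)?
is_boolean_expr <- function(e) {
  if (is.logical(e)) return(TRUE)
  if (!is.call(e)) return(FALSE)
  op <- as.character(e[[1]])
  if (op == "(") return(is_boolean_expr(e[[2]]))
  op %in% c("==", "!=", "<", ">", "<=", ">=", "&", "|", "!")
}
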