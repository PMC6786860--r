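# shared helpers for the test suite

u <- function(s) parse_unit_expression(s)
sec <- function(x) quantity(x, dimension(s = 1))

# scalar tree-walking interpreter over the model grammar: the independent
# oracle for vectorized kernel evaluation (one instance at a time)
scalar_eval <- function(e, env) {
  if (is.numeric(e) || is.logical(e)) return(as.numeric(e))
  if (is.name(e)) return(as.numeric(env[[as.character(e)]]))
  op <- as.character(e[[1]])
  if (op == "(") return(scalar_eval(e[[2]], env))
  a <- function(k) scalar_eval(e[[k]], env)
  switch(op,
    "+" = if (length(e) == 2) a(2) else a(2) + a(3),
    "-" = if (length(e) == 2) -a(2) else a(2) - a(3),
    "*" = a(2) * a(3), "/" = a(2) / a(3), "^" = a(2)^a(3),
    "==" = as.numeric(a(2) == a(3)), "!=" = as.numeric(a(2) != a(3)),
    "<" = as.numeric(a(2) < a(3)), ">" = as.numeric(a(2) > a(3)),
    "<=" = as.numeric(a(2) <= a(3)), ">=" = as.numeric(a(2) >= a(3)),
    "&" = as.numeric(a(2) != 0 && a(3) != 0),
    "|" = as.numeric(a(2) != 0 || a(3) != 0),
    "!" = as.numeric(a(2) == 0),
    "exp" = exp(a(2)), "log" = log(a(2)), "sqrt" = sqrt(a(2)),
    "abs" = abs(a(2)), "tanh" = tanh(a(2)), "sin" = sin(a(2)),
    "cos" = cos(a(2)), "sinh" = sinh(a(2)), "cosh" = cosh(a(2)),
    "floor" = floor(a(2)), "ceiling" = ceiling(a(2)),
    "sign" = sign(a(2)), "int" = trunc(a(2)),
    "clip" = min(max(a(2), a(3)), a(4)),
    "exprel" = if (abs(a(2)) < 1e-9) 1 + a(2) / 2 else expm1(a(2)) / a(2),
    stop("scalar_eval: unknown op ", op)
  )
}

# double-loop enumeration oracle for expression-based connectivity
enumerate_pairs <- function(Ns, Nt, cond_text, pre_vars = list(),
                            post_vars = list(), consts = list()) {
  expr <- str2lang(eqspike:::translate_operators(cond_text))
  out_i <- integer(); out_j <- integer()
  for (i in 0:(Ns - 1)) for (j in 0:(Nt - 1)) {
    env <- c(list(i = i, j = j), consts)
    for (nm in names(pre_vars)) env[[paste0(nm, "_pre")]] <- pre_vars[[nm]][i + 1]
    for (nm in names(post_vars)) env[[paste0(nm, "_post")]] <- post_vars[[nm]][j + 1]
    if (scalar_eval(expr, env) != 0) { out_i <- c(out_i, i); out_j <- c(out_j, j) }
  }
  list(i = out_i, j = out_j)
}

# a minimal leaky integrate-and-fire group with constant per-instance drive
make_lif <- function(N = 1, tau = u("10*ms"), refractory = NULL) {
  create_group(N, "dv/dt = (v0 - v)/tau : volt\nv0 : volt (constant)",
               threshold = "v > -50*mV", reset = "v = -60*mV",
               refractory = refractory, namespace = list(tau = tau),
               name = "lif")
}
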