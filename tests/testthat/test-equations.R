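# model-string parsing, dimensional validation, ordering, noise detection

test_that("equation lines parse into the three entry kinds with flags", {
  eqs <- parse_equations("dv/dt = -v/tau : volt")
  expect_named(eqs$entries, "v")
  expect_equal(eqs$entries$v$kind, "differential")
  expect_true(eqspike:::dim_eq(eqs$entries$v$dim, quantity_dim(u("volt"))))
  expect_setequal(eqs$identifiers, "tau")

  # a graded-synapse model: a differential equation driven by the
  # presynaptic potential plus a summed entry targeting the postsynaptic cell
  syn <- parse_equations("
    I_slow_post = g_slow*m_slow*(E_syn - v_post) : amp (summed)
    dm_slow/dt = (1/(1 + exp((v_th - v_pre)/dv_sig)) - m_slow)/tau_m : 1")
  expect_equal(length(syn$entries), 2)
  expect_true("summed" %in% syn$entries$I_slow_post$flags)
  expect_equal(syn$entries$m_slow$kind, "differential")

  lp <- parse_equations("x : 1 (linked)")
  expect_equal(lp$entries$x$kind, "parameter")
  expect_true("linked" %in% lp$entries$x$flags)

  expect_error(parse_equations("dv/dt = -v/tau : volt\nv : volt"),
               class = "DuplicateDefinition")
  expect_error(parse_equations("dv/dt = -v/tau : volt (summed)"),
               class = "IllegalFlag")
  expect_error(parse_equations("v = 3*x : 1 (linked)"), class = "IllegalFlag")
  expect_error(parse_equations("mV : volt"), class = "NameCollision")
  expect_error(parse_equations("dv/dt = -v/ : volt"), class = "eqspike_error")
})

test_that("dimensional validation accepts consistent and rejects inconsistent models", {
  ns <- list(tau = u("10*ms"), I = u("1*nA"))
  eqs <- parse_equations("dv/dt = -v/tau : volt")
  expect_silent(validate_dimensions(eqs, ns))

  bad <- parse_equations("dw/dt = (v + I)/second : volt\nv : volt")
  expect_error(validate_dimensions(bad, ns), class = "DimensionMismatch")

  # missing /time on a differential right-hand side
  bad2 <- parse_equations("dv/dt = -v : volt")
  expect_error(validate_dimensions(bad2, ns), class = "DimensionMismatch")

  expect_error(validate_dimensions(parse_equations("dv/dt = -v/tau_x : volt"), ns),
               class = "UnresolvedIdentifier")

  # conductance density times voltage validates as a current density
  cd <- parse_equations("j_na = gna*(v - ENa) : amp/metre**2\ngna : siemens/metre**2\nv : volt")
  expect_silent(validate_dimensions(cd, list(ENa = u("50*mV"))))

  # boolean subexpressions must be dimensionless
  bb <- parse_equations("above = v > th : volt\nv : volt")
  expect_error(validate_dimensions(bb, list(th = u("-50*mV"))),
               class = "DimensionMismatch")
})

test_that("subexpressions order topologically and cycles are reported", {
  eqs <- parse_equations("b = a*2 : 1\na : 1")
  expect_equal(order_subexpressions(eqs), "b")
  eqs2 <- parse_equations("b = a*2 : 1\na = 3 + c : 1\nc : 1")
  expect_equal(order_subexpressions(eqs2), c("a", "b"))
  cyc <- parse_equations("a = b : 1\nb = a : 1")
  expect_error(order_subexpressions(cyc), class = "CyclicDependency")

  # evaluating in the returned order never reads an unset name (the
  # pyloric-style chain: activity trace -> regulator -> conductances)
  chain <- parse_equations("
    g = g_max/(1 + exp(2*z)) : 1
    s = s_max/(1 + exp(-2*z)) : 1
    z = (Ca - target) : 1
    Ca : 1")
  ord <- order_subexpressions(chain)
  seen <- c("Ca", "g_max", "s_max", "target")
  for (nm in ord) {
    needs <- eqspike:::expr_names(chain$entries[[nm]]$rhs)$vars
    expect_true(all(needs %in% seen), info = nm)
    seen <- c(seen, nm)
  }
})

test_that("stochastic entries are detected and xi misuse rejected", {
  s <- parse_equations("dx/dt = -x/tau + sigma*xi : metre")
  expect_equal(detect_stochastic(s), "x")
  d <- parse_equations("dx/dt = -x/tau : metre")
  expect_equal(detect_stochastic(d), character(0))
  expect_error(detect_stochastic(parse_equations("y = xi : 1")),
               class = "IllegalNoise")
  expect_error(detect_stochastic(parse_equations("dx/dt = xi*xi : 1/second")),
               class = "IllegalNoise")
})

test_that("format/parse is an identity on equation sets", {
  txt <- "dv/dt = (v0 - v)/tau : volt
    v0 : volt (constant)
    above = v > v0 : 1
    dCa/dt = -Ca/tau_ca : 1"
  eqs <- parse_equations(txt)
  eqs2 <- parse_equations(format_equations(eqs))
  expect_equal(names(eqs2$entries), names(eqs$entries))
  for (nm in names(eqs$entries)) {
    expect_equal(eqs2$entries[[nm]]$kind, eqs$entries[[nm]]$kind)
    expect_equal(eqs2$entries[[nm]]$flags, eqs$entries[[nm]]$flags)
    expect_true(eqspike:::dim_eq(eqs2$entries[[nm]]$dim, eqs$entries[[nm]]$dim))
    expect_identical(deparse(eqs2$entries[[nm]]$rhs), deparse(eqs$entries[[nm]]$rhs))
  }
})

test_that("statement strings parse assignments and augmented assignments", {
  st <- parse_statements("Ca += 0.1; v = -60*mV")
  expect_equal(length(st), 2)
  expect_equal(st[[1]]$op, "+=")
  expect_equal(st[[2]]$target, "v")
  expect_error(parse_statements("2 + 2"), class = "eqspike_error")
})

test_that("validation result does not depend on entry order", {
  ns <- list(tau = u("10*ms"))
  a <- parse_equations("w = v*2 : volt\ndv/dt = -v/tau : volt")
  b <- parse_equations("dv/dt = -v/tau : volt\nw = v*2 : volt")
  va <- validate_dimensions(a, ns); vb <- validate_dimensions(b, ns)
  expect_true(eqspike:::dim_eq(va$entries$w$inferred_dim, vb$entries$w$inferred_dim))
})
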