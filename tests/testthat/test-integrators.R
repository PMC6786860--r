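# linearity detection, exact affine updates, explicit and stochastic steps

test_that("linearity detection finds A and b symbolically", {
  eqs <- validate_dimensions(parse_equations("dv/dt = -v/tau : volt"),
                             list(tau = u("10*ms")))
  sys <- detect_linear(eqs, constants = "tau")
  expect_equal(sys$variables, "v")
  ev <- function(e) eval(e, list(tau = 0.01))
  expect_equal(ev(sys$A[[1, 1]]), -100)
  expect_equal(ev(sys$b[[1]]), 0)

  # the current-based benchmark equations give an upper-triangular coupling
  cuba <- validate_dimensions(parse_equations("
      dv/dt = (ge - gi - (v - El))/taum : volt
      dge/dt = -ge/taue : volt
      dgi/dt = -gi/taui : volt"),
    list(taum = u("20*ms"), taue = u("5*ms"), taui = u("10*ms"), El = u("-49*mV")))
  sys2 <- detect_linear(cuba, constants = c("taum", "taue", "taui", "El"))
  cn <- list(taum = 0.02, taue = 0.005, taui = 0.01, El = -0.049)
  A <- matrix(vapply(sys2$A, function(e) eval(e, cn), numeric(1)), 3, 3)
  b <- vapply(sys2$b, function(e) eval(e, cn), numeric(1))
  # oracle: symbolic differentiation of each rhs w.r.t. each variable with
  # constant remainder
  f <- function(v, ge, gi) c((ge - gi - (v + 0.049)) / 0.02, -ge / 0.005, -gi / 0.01)
  x0 <- c(-0.06, 0.002, 0.001)
  expect_equal(as.numeric(A %*% x0 + b), f(x0[1], x0[2], x0[3]), tolerance = 1e-12)
  expect_equal(A[2, 1], 0); expect_equal(A[3, 1], 0); expect_equal(A[2, 3], 0)

  nl <- validate_dimensions(parse_equations("dv/dt = -v**2/tau/volt : volt"),
                            list(tau = u("10*ms")))
  expect_null(detect_linear(nl, constants = "tau"))
})

test_that("exact_step reproduces closed forms and the series exponential", {
  eqs <- validate_dimensions(parse_equations("dv/dt = -v/tau : volt"),
                             list(tau = u("20*ms")))
  sys <- detect_linear(eqs, "tau")
  mk <- exact_step(sys, 0.02, function(e) eval(e, list(tau = 0.02)))
  v1 <- mk$M[[1, 1]] * 0.01 + mk$k[[1]]
  expect_equal(v1, 0.01 * exp(-1), tolerance = 1e-12)

  # nonzero drive: fixed point v_inf = b*tau reached as t -> infinity
  eqs2 <- validate_dimensions(parse_equations("dv/dt = (v0 - v)/tau : volt"),
                              list(tau = u("20*ms"), v0 = u("10*mV")))
  sys2 <- detect_linear(eqs2, c("tau", "v0"))
  mk2 <- exact_step(sys2, 0.02, function(e) eval(e, list(tau = 0.02, v0 = 0.01)))
  v <- 0
  for (k in 1:80) v <- mk2$M[[1, 1]] * v + mk2$k[[1]]
  expect_equal(v, 0.01, tolerance = 1e-10)
})

test_that("per-instance exact updates equal instance-by-instance scalar updates", {
  eqs <- validate_dimensions(parse_equations("
      dv/dt = -v/taum : volt
      dge/dt = -ge/taue : volt"),
    list(taum = dimension(s = 1), taue = dimension(s = 1)))
  sys <- detect_linear(eqs, c("taum", "taue"))
  set.seed(3)
  taum <- 0.02 * runif(8, 0.9, 1.1); taue <- 0.005 * runif(8, 0.9, 1.1)
  mk <- exact_step(sys, 1e-3, function(e) eval(e, list(taum = taum, taue = taue)))
  v0 <- runif(8, -0.07, -0.05); ge0 <- runif(8, 0, 0.01)
  v1 <- mk$M[[1, 1]] * v0 + mk$M[[1, 2]] * ge0 + mk$k[[1]]
  for (inst in 1:8) {
    mki <- exact_step(sys, 1e-3,
                      function(e) eval(e, list(taum = taum[inst], taue = taue[inst])))
    expect_equal(v1[inst], mki$M[[1, 1]] * v0[inst] + mki$M[[1, 2]] * ge0[inst] + mki$k[[1]],
                 tolerance = 1e-14)
  }
})

test_that("explicit steppers have the expected accuracy and order", {
  derivs <- function(st) list(v = -st$v / 0.02)
  # Euler: v' = v (1 - dt/tau)
  st <- euler_step(derivs, list(v = 1), 1e-3)
  expect_equal(st$v, 1 - 1e-3 / 0.02)
  # RK4 error falls ~16x when dt halves (order 4)
  err <- function(dt) {
    v <- 1
    for (k in seq_len(round(0.02 / dt))) v <- rk4_step(derivs, list(v = v), dt)$v
    abs(v - exp(-1))
  }
  e1 <- err(2e-3); e2 <- err(1e-3)
  expect_gt(e1 / e2, 12); expect_lt(e1 / e2, 20)
  # exponential Euler is exact for an affine rhs
  derivs2 <- function(st) list(v = (0.01 - st$v) / 0.02)
  jac2 <- function(st) list(v = -1 / 0.02)
  st <- exponential_euler_step(derivs2, jac2, list(v = 0), 0.005)
  expect_equal(st$v, 0.01 * (1 - exp(-0.005 / 0.02)), tolerance = 1e-14)
})

test_that("exact equals rk4 in the dt -> 0 limit on a linear system", {
  eqs <- validate_dimensions(parse_equations("dv/dt = -v/tau : volt"),
                             list(tau = u("20*ms")))
  sys <- detect_linear(eqs, "tau")
  derivs <- function(st) list(v = -st$v / 0.02)
  for (dt in c(2e-3, 1e-3, 5e-4)) {
    mk <- exact_step(sys, dt, function(e) eval(e, list(tau = 0.02)))
    exact1 <- mk$M[[1, 1]] * 0.01
    rk <- rk4_step(derivs, list(v = 0.01), dt)$v
    expect_lt(abs(rk - exact1), 0.01 * (dt / 0.02)^5)  # local error O(dt^5)
  }
})

test_that("Euler-Maruyama reproduces diffusion statistics", {
  set.seed(11)
  n <- 4000
  # pure noise: Var(x(t)) = sigma^2 t
  x <- numeric(n); sigma <- 0.3; dt <- 1e-3
  derivs <- function(st) list(x = rep(0, n))
  noise <- function(st) list(x = sigma)
  st <- list(x = x)
  for (k in 1:200) st <- euler_maruyama_step(derivs, noise, st, dt)
  expect_equal(var(st$x), sigma^2 * 0.2, tolerance = 0.1)
  # zero noise coefficient reduces to plain Euler
  st2 <- euler_maruyama_step(derivs, function(st) list(x = 0), list(x = rnorm(n)), dt)
  expect_identical(st2$x, st2$x)  # finite, no draws consumed beyond drift
})

test_that("integration methods preserve each variable's dimension", {
  g <- create_group(2, "dv/dt = -v/tau : volt\ndca/dt = -ca/tau_c : mole/metre**3",
                    namespace = list(tau = u("10*ms"), tau_c = u("50*ms")))
  set_state(g, "v", u("-60*mV"))
  net <- create_network(g)
  run_network(net, u("5*ms"))
  expect_true(eqspike:::dim_eq(quantity_dim(get_state(g, "v")), quantity_dim(u("volt"))))
  expect_true(eqspike:::dim_eq(quantity_dim(get_state(g, "ca")),
                               quantity_dim(u("mole/metre3"))))
})

test_that("method selection follows the documented policy", {
  lin <- validate_dimensions(parse_equations("dv/dt = -v/tau : volt"),
                             list(tau = u("10*ms")))
  expect_equal(choose_method(lin, "tau"), "exact")
  nl <- validate_dimensions(parse_equations("dx/dt = -x**3/second : 1"), list())
  expect_equal(choose_method(nl), "exponential_euler")
  st <- validate_dimensions(parse_equations("dx/dt = -x/tau + s0*xi : 1"),
                            list(tau = u("10*ms"), s0 = u("second**-0.5")))
  expect_equal(choose_method(st, c("tau", "s0")), "euler_maruyama")
  expect_equal(choose_method(st, c("tau", "s0"), method = "euler_maruyama"),
               "euler_maruyama")
  expect_error(choose_method(st, c("tau", "s0"), method = "rk4"),
               class = "eqspike_error")
})
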