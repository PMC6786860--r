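# State-update methods. Linear constant-coefficient systems are detected
# symbolically and advanced exactly via the matrix exponential of the
# augmented system; everything else uses explicit schemes (forward Euler,
# classical RK4, exponential Euler) or Euler-Maruyama when the white-noise
# symbol xi is present.

#' Detect whether an equation set is linear with constant coefficients
#'
#' Inlines subexpressions and checks symbolically that every differential
#' right-hand side is affine in the state variables: d/dt x = A x + b with
#' A and b free of state variables, time and randomness. Coefficients may
#' reference per-instance parameters (heterogeneous time constants), in
#' which case the system is flagged `per_instance`.
#'
#' @param eqs a validated equation set.
#' @param constants character vector of identifier names that are fixed
#'   during integration (namespace constants and parameter entries).
#' @return a list describing the linear system (`variables`, expression
#'   matrices `A` and `b`, `per_instance` candidate names), or `NULL` if
#'   any right-hand side is not linear.
#' @export
detect_linear <- function(eqs, constants = character()) {
  vars <- names(Filter(function(e) e$kind == "differential", eqs$entries))
  if (!length(vars)) return(NULL)
  sub_map <- inline_map(eqs)
  d <- length(vars)
  A <- vector("list", d * d); dim(A) <- c(d, d)
  b <- vector("list", d)
  coef_names <- character()
  for (r in seq_len(d)) {
    rhs <- subst_expr(eqs$entries[[vars[r]]]$rhs, sub_map)
    free <- expr_names(rhs)
    if (any(c("xi", "t") %in% free$vars) || any(c("rand", "randn") %in% free$funs))
      return(NULL)
    if (length(setdiff(free$vars, c(vars, constants, "i", "N", "dt"))))
      return(NULL)
    for (cc in seq_len(d)) {
      dexpr <- eq_deriv(rhs, vars[cc])
      if (is.null(dexpr)) return(NULL)
      if (length(intersect(expr_names(dexpr)$vars, vars))) return(NULL)
      A[[r, cc]] <- dexpr
      coef_names <- union(coef_names, expr_names(dexpr)$vars)
    }
    zero_map <- stats::setNames(rep(list(0), d), vars)
    b[[r]] <- subst_expr(rhs, zero_map)
    coef_names <- union(coef_names, setdiff(expr_names(b[[r]])$vars, vars))
  }
  list(variables = vars, A = A, b = b, coef_names = coef_names)
}

inline_map <- function(eqs) {
  ord <- order_subexpressions(eqs)
  subs <- ord[vapply(ord, function(nm) eqs$entries[[nm]]$kind == "subexpression", logical(1))]
  map <- list()
  for (nm in subs) map[[nm]] <- subst_expr(eqs$entries[[nm]]$rhs, map)
  map
}

#' Exact affine update for a linear system
#'
#' For d/dt x = A x + b and a fixed step dt, computes M = exp(A dt) and
#' k such that x(t + dt) = M x(t) + k, via the matrix exponential of the
#' augmented matrix \eqn{[[A, b], [0, 0]] \cdot dt} (which handles singular
#' A without special-casing). When coefficients vary across instances, one
#' (M, k) is computed per distinct coefficient tuple.
#'
#' @param sys result of [detect_linear()].
#' @param dt_s timestep in seconds (bare numeric).
#' @param eval_coef function mapping a coefficient expression to its
#'   numeric value (length 1, or length N for per-instance coefficients).
#' @return list with `M` (d x d list of numeric vectors) and `k` (length-d
#'   list), each entry of length 1 or N.
#' @export
exact_step <- function(sys, dt_s, eval_coef) {
  d <- length(sys$variables)
  Av <- lapply(sys$A, eval_coef)
  bv <- lapply(sys$b, eval_coef)
  lens <- vapply(c(Av, bv), length, integer(1))
  n <- max(lens)
  if (any(!lens %in% c(1L, n)))
    integration_error("coefficient arrays of inconsistent length")
  if (n == 1L) {
    Mk <- affine_update(matrix(unlist(Av), d, d), unlist(bv), dt_s)
    M <- lapply(seq_len(d * d), function(q) Mk$M[q])
    dim(M) <- c(d, d)
    return(list(M = M, k = lapply(seq_len(d), function(r) Mk$k[r]), n = 1L))
  }
  coef <- vapply(c(Av, bv), function(v) rep_len(v, n), numeric(n))  # n x (d^2+d)
  key <- apply(coef, 1, paste, collapse = "\r")
  uniq <- which(!duplicated(key))
  grp <- match(key, key[uniq])
  Mu <- array(NA_real_, c(length(uniq), d, d))
  ku <- matrix(NA_real_, length(uniq), d)
  for (u in seq_along(uniq)) {
    row <- coef[uniq[u], ]
    Mk <- affine_update(matrix(row[seq_len(d * d)], d, d), row[d * d + seq_len(d)], dt_s)
    Mu[u, , ] <- Mk$M
    ku[u, ] <- Mk$k
  }
  M <- vector("list", d * d); dim(M) <- c(d, d)
  for (r in seq_len(d)) for (cc in seq_len(d)) M[[r, cc]] <- Mu[grp, r, cc]
  k <- lapply(seq_len(d), function(r) ku[grp, r])
  list(M = M, k = k, n = n)
}

# single affine update via the augmented matrix exponential
affine_update <- function(A, b, dt_s) {
  d <- nrow(A)
  aug <- rbind(cbind(A, b), 0) * dt_s
  E <- tryCatch(as.matrix(Matrix::expm(Matrix::Matrix(aug))),
                error = function(e) integration_error(
                  sprintf("matrix exponential failed: %s", conditionMessage(e))))
  if (any(!is.finite(E)))
    integration_error("matrix exponential produced non-finite values")
  dimnames(E) <- NULL
  list(M = E[seq_len(d), seq_len(d), drop = FALSE],
       k = unname(E[seq_len(d), d + 1]))
}

#' Matrix exponential by scaled Taylor series
#'
#' Independent high-order series evaluation (scaling and squaring around a
#' plain Taylor sum), intended as a cross-check for the exact integrator.
#'
#' @param A square matrix.
#' @param order series order (default 30).
#' @export
expm_series <- function(A, order = 30L) {
  d <- nrow(A)
  s <- max(0L, ceiling(log2(max(1e-300, norm(A, "1")))))
  As <- A / 2^s
  E <- diag(d)
  term <- diag(d)
  for (k in seq_len(order)) {
    term <- term %*% As / k
    E <- E + term
  }
  for (q in seq_len(s)) E <- E %*% E
  E
}

# --- explicit steppers ------------------------------------------------------
# Each stepper receives:
#   derivs(state)  -> named list of d/dt values given a named list of
#                     state vectors (subexpressions already inlined)
#   state          -> named list of current state vectors
# and returns the named list of updated state vectors.

#' One forward-Euler step
#' @param derivs function(state list) -> named list of derivatives.
#' @param state named list of state vectors.
#' @param dt_s timestep in seconds.
#' @export
euler_step <- function(derivs, state, dt_s) {
  f <- derivs(state)
  for (nm in names(f)) state[[nm]] <- state[[nm]] + dt_s * f[[nm]]
  state
}

#' One classical Runge-Kutta (RK4) step
#' @inheritParams euler_step
#' @export
rk4_step <- function(derivs, state, dt_s) {
  k1 <- derivs(state)
  k2 <- derivs(state_plus(state, k1, dt_s / 2))
  k3 <- derivs(state_plus(state, k2, dt_s / 2))
  k4 <- derivs(state_plus(state, k3, dt_s))
  for (nm in names(k1))
    state[[nm]] <- state[[nm]] + dt_s / 6 *
      (k1[[nm]] + 2 * k2[[nm]] + 2 * k3[[nm]] + k4[[nm]])
  state
}

state_plus <- function(state, k, h) {
  for (nm in names(k)) state[[nm]] <- state[[nm]] + h * k[[nm]]
  state
}

#' One exponential-Euler step
#'
#' Treats each right-hand side as locally affine in its own variable,
#' f = a - b x with b = -df/dx evaluated at the current state, updates that
#' variable exactly over dt while freezing the others. Exact for
#' conditionally linear systems (e.g. Hodgkin-Huxley gating variables).
#'
#' @param derivs as in [euler_step()].
#' @param jac function(state) -> named list of df/dx (own-variable partial
#'   derivatives); entries may be NULL, in which case that variable falls
#'   back to forward Euler.
#' @param state named list of state vectors.
#' @param dt_s timestep in seconds.
#' @export
exponential_euler_step <- function(derivs, jac, state, dt_s) {
  f <- derivs(state)
  J <- jac(state)
  for (nm in names(f)) {
    if (is.null(J[[nm]])) {
      state[[nm]] <- state[[nm]] + dt_s * f[[nm]]
    } else {
      b <- -J[[nm]]
      bdt <- b * dt_s
      if (all(abs(bdt) >= 1e-12)) {
        phi <- -expm1(-bdt) / b
      } else {
        phi <- rep_len(dt_s, length(state[[nm]]))
        ok <- abs(bdt) >= 1e-12
        phi[ok] <- -expm1(-bdt[ok]) / (if (length(b) > 1) b[ok] else b)
      }
      state[[nm]] <- state[[nm]] + f[[nm]] * phi
    }
  }
  state
}

#' One Euler-Maruyama step
#'
#' x' = x + f dt + g sqrt(dt) eta, with eta standard normal per instance
#' per step drawn from the simulation RNG stream.
#'
#' @param derivs drift evaluator, as in [euler_step()].
#' @param noise function(state) -> named list of noise coefficients g
#'   (the coefficient of xi; zero or absent entries get no noise).
#' @param state named list of state vectors.
#' @param dt_s timestep in seconds.
#' @export
euler_maruyama_step <- function(derivs, noise, state, dt_s) {
  f <- derivs(state)
  g <- noise(state)
  sq <- sqrt(dt_s)
  for (nm in names(f)) {
    x <- state[[nm]] + dt_s * f[[nm]]
    gn <- g[[nm]]
    if (!is.null(gn) && !(is.numeric(gn) && length(gn) == 1 && gn == 0))
      x <- x + gn * sq * stats::rnorm(length(state[[nm]]))
    state[[nm]] <- x
  }
  state
}

#' Choose an integration method for an equation set
#'
#' Default policy: `exact` when the system is linear with constant
#' coefficients and deterministic, `exponential_euler` for other
#' deterministic systems, `euler_maruyama` when the noise symbol xi is
#' present. `euler_maruyama` is forced for stochastic systems regardless
#' of the requested method.
#'
#' @param eqs validated equation set.
#' @param constants names of fixed coefficients.
#' @param method `"auto"` or one of `"exact"`, `"euler"`, `"rk4"`,
#'   `"exponential_euler"`, `"euler_maruyama"`.
#' @return the method name chosen.
#' @export
choose_method <- function(eqs, constants = character(), method = "auto") {
  stochastic <- length(detect_stochastic(eqs)) > 0
  if (stochastic) {
    if (!method %in% c("auto", "euler_maruyama"))
      eq_abort("eqspike_error", "stochastic equations require euler_maruyama")
    return("euler_maruyama")
  }
  if (method != "auto") return(method)
  if (!is.null(detect_linear(eqs, constants))) "exact" else "exponential_euler"
}
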