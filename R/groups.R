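# Populations of model instances. A NeuronGroup holds N instances sharing
# one equation set, per-variable state arrays (SI-scaled bare numerics),
# an optional threshold condition, reset statements and refractory period.
#
# Environment layout per group (lookup order during kernel evaluation):
#   state_env (state arrays, linked variables as active bindings)
#     -> rt (reserved names: t, dt, N, i, .n)
#       -> ns_env (namespace constants, registered + builtin functions)
#         -> baseenv
# Inside the model grammar the instance index `i` is 0-based (as in the
# equation DSL); R-level API arguments (`subset`, `record`) are 1-based.

#' @import R6
NULL

NeuronGroup <- R6::R6Class("NeuronGroup",
  public = list(
    name = NULL, N = NULL, eqs = NULL,
    diff_vars = NULL, params = NULL, subexprs = NULL,
    state_env = NULL, rt = NULL, ns_env = NULL,
    namespace = NULL, functions = NULL,
    threshold_text = NULL, reset_text = NULL, refractory_s = 0,
    last_spike = NULL, spikes = integer(), not_ref = NULL,
    method_req = "auto", method = NULL,
    linked = list(),

    initialize = function(N, model, threshold = NULL, reset = NULL,
                          refractory = NULL, namespace = list(),
                          method = "auto", name = "group") {
      stopifnot(N >= 1)
      self$name <- name
      self$N <- as.integer(N)
      self$method_req <- method
      # split namespace into constants and registered functions
      is_fun <- vapply(namespace, inherits, logical(1), what = "registered_function")
      self$namespace <- namespace[!is_fun]
      self$functions <- namespace[is_fun]
      names(self$functions) <- vapply(self$functions, function(f) f$name, character(1))

      eqs <- if (inherits(model, "equation_set")) model else parse_equations(model)
      eqs <- validate_dimensions(eqs, self$namespace,
                                 functions = lapply(self$functions, function(f)
                                   list(arg_dims = f$arg_dims, return_dim = f$return_dim)))
      for (e in eqs$entries)
        if ("summed" %in% e$flags)
          illegal_flag(sprintf("entry '%s': summed variables belong to synapse models", e$name))
      self$eqs <- eqs
      self$diff_vars <- names(Filter(function(e) e$kind == "differential", eqs$entries))
      self$params <- names(Filter(function(e) e$kind == "parameter", eqs$entries))
      self$subexprs <- names(Filter(function(e) e$kind == "subexpression", eqs$entries))

      # environment chain
      self$ns_env <- new.env(parent = builtin_funs_env())
      for (nm in names(self$namespace))
        assign(nm, si_value(self$namespace[[nm]]), envir = self$ns_env)
      for (f in self$functions) assign(f$name, f$impl, envir = self$ns_env)
      self$rt <- new.env(parent = self$ns_env)
      assign("N", as.numeric(N), envir = self$rt)
      assign("i", as.numeric(seq_len(N) - 1), envir = self$rt)
      assign(".n", as.integer(N), envir = self$rt)
      assign("t", 0, envir = self$rt)
      assign("dt", NA_real_, envir = self$rt)
      self$state_env <- new.env(parent = self$rt)
      for (v in c(self$diff_vars, self$params))
        assign(v, numeric(N), envir = self$state_env)

      self$last_spike <- rep(-Inf, N)
      if (!is.null(refractory)) {
        if (!dim_eq(quantity_dim(refractory), dimension(s = 1)))
          dimension_mismatch("refractory period must be a time")
        self$refractory_s <- si_value(refractory)
      }
      if (!is.null(threshold)) {
        cond <- self$inline_subexpressions(parse_rhs(threshold))
        self$check_resolvable(cond)
        d <- infer_dim(cond, self$dim_env(), self$function_sigs())
        if (!is_dimless(d))
          dimension_mismatch(sprintf(
            "threshold '%s' has dimension [%s]; must be a dimensionless boolean",
            threshold, format(d)))
        if (!is_boolean_expr(cond))
          eq_abort("eqspike_error", sprintf("threshold '%s' is not a boolean expression", threshold))
        private$threshold_cond <- cond
        self$threshold_text <- threshold
      }
      if (!is.null(reset)) {
        private$reset_block <- compile_statements(reset, self, kind = "reset")
        self$reset_text <- reset
      }
      invisible(self)
    },

    # ---- context interface used by the kernel compiler --------------------
    resolvable_names = function() c(self$diff_vars, self$params, names(self$linked)),
    dim_env = function() {
      d <- c(RESERVED_DIMS(), namespace_dims(self$namespace))
      for (e in self$eqs$entries) d[[e$name]] <- e$dim
      d
    },
    function_sigs = function() lapply(self$functions, function(f)
      list(arg_dims = f$arg_dims, return_dim = f$return_dim)),
    dim_of = function(name) {
      e <- self$eqs$entries[[name]]
      if (is.null(e)) unresolved_identifier(sprintf("unknown variable '%s'", name))
      e$dim
    },
    inline_subexpressions = function(tree) {
      if (is.null(private$im_cache)) private$im_cache <- inline_map(self$eqs)
      if (!length(private$im_cache)) return(tree)
      subst_expr(tree, private$im_cache)
    },
    check_resolvable = function(tree) {
      nm <- expr_names(tree)
      known <- c(self$diff_vars, self$params, self$subexprs,
                 names(self$namespace), names(RESERVED_DIMS()))
      bad <- setdiff(nm$vars, known)
      bad <- bad[!vapply(bad, unit_in_expressions, logical(1))]
      if (length(bad))
        unresolved_identifier(sprintf("group '%s': unknown identifier(s) %s",
                                      self$name, paste(bad, collapse = ", ")))
      badf <- setdiff(nm$funs, c(BUILTIN_FUNCTIONS, names(self$functions)))
      if (length(badf))
        unresolved_identifier(sprintf("group '%s': unknown function(s) %s",
                                      self$name, paste(badf, collapse = ", ")))
    },
    # setup = TRUE allows assigning constant-flagged parameters (state
    # initialization); inside statement blocks constants are read-only
    check_writable = function(name, setup = FALSE) {
      e <- self$eqs$entries[[name]]
      if (is.null(e))
        unresolved_identifier(sprintf("group '%s': unknown variable '%s'", self$name, name))
      if (name %in% names(self$linked))
        write_to_linked(sprintf("variable '%s' is linked and read-only", name))
      if (e$kind == "subexpression")
        eq_abort("eqspike_error", sprintf("cannot assign to subexpression '%s'", name))
      if (!setup && "constant" %in% e$flags)
        assignment_to_constant(sprintf("variable '%s' is declared constant", name))
    },
    eval_expr = function(tree, idx = NULL, reads = NULL) {
      if (is.null(idx)) return(eval(tree, self$state_env))
      eval(tree, self$subset_env(idx, reads))
    },
    subset_env = function(idx, names) {
      e <- new.env(parent = self$rt)
      vars <- intersect(names, self$resolvable_names())
      if (is.null(idx)) {
        for (v in vars) assign(v, get(v, envir = self$state_env), envir = e)
      } else {
        for (v in vars) assign(v, get(v, envir = self$state_env)[idx], envir = e)
        assign("i", as.numeric(idx - 1), envir = e)
        assign(".n", length(idx), envir = e)
      }
      e
    },
    write_back = function(target, idx, new, op, delta) {
      if (is.null(idx)) {
        assign(target, rep_len(new, self$N), envir = self$state_env)
      } else {
        cur <- get(target, envir = self$state_env)
        cur[idx] <- new
        assign(target, cur, envir = self$state_env)
      }
    },

    # ---- schedule blocks ---------------------------------------------------
    blocks = function() {
      b <- list(list(kind = "state_update", slot = 2L))
      if (!is.null(private$threshold_cond)) b <- c(b, list(list(kind = "threshold", slot = 3L)))
      if (!is.null(private$reset_block)) b <- c(b, list(list(kind = "reset", slot = 5L)))
      b
    },

    prepare = function(dt_s) {
      assign("dt", dt_s, envir = self$rt)
      if (!length(self$diff_vars)) {
        private$step_fn <- function() NULL
        return(invisible(self))
      }
      # only true constants may enter exact-update coefficients: namespace
      # values and constant-flagged parameters (linked or synapse-driven
      # parameters vary between steps, so systems involving them fall back
      # to a per-step method)
      consts <- c(names(self$namespace),
                  self$params[vapply(self$params, function(p)
                    "constant" %in% self$eqs$entries[[p]]$flags, logical(1))])
      self$method <- choose_method(self$eqs, consts, self$method_req)
      m <- inline_map(self$eqs)
      rhs <- lapply(self$eqs$entries[self$diff_vars], function(e) subst_expr(e$rhs, m))
      names(rhs) <- self$diff_vars
      group <- self
      if (self$method == "exact") {
        sys <- detect_linear(self$eqs, consts)
        if (is.null(sys))
          eq_abort("eqspike_error", sprintf(
            "group '%s': exact integration requested but equations are not linear", self$name))
        mk <- exact_step(sys, dt_s, function(e) eval(e, self$state_env))
        vars <- sys$variables
        d <- length(vars)
        private$step_fn <- function() {
          st <- mget(vars, envir = group$state_env)
          frozen <- private$frozen_vars
          refrac <- if (length(frozen)) which(!group$not_ref) else integer()
          for (r in seq_len(d)) {
            acc <- mk$k[[r]]
            for (cc in seq_len(d)) {
              mrc <- mk$M[[r, cc]]
              if (length(mrc) == 1 && mrc == 0) next
              acc <- acc + mrc * st[[cc]]
            }
            acc <- rep_len(acc, group$N)
            if (vars[r] %in% frozen && length(refrac))
              acc[refrac] <- st[[r]][refrac]
            assign(vars[r], acc, envir = group$state_env)
          }
        }
      } else {
        drift <- rhs
        gexpr <- NULL
        if (self$method == "euler_maruyama") {
          parts <- lapply(rhs, split_noise)
          drift <- lapply(parts, `[[`, "drift")
          gexpr <- lapply(parts, `[[`, "g")
        }
        derivs <- function(st) {
          e <- list2env(st, parent = group$state_env)
          lapply(drift, eval, envir = e)
        }
        stepper <- switch(self$method,
          euler = function(st, dt_s) euler_step(derivs, st, dt_s),
          rk4 = function(st, dt_s) rk4_step(derivs, st, dt_s),
          exponential_euler = {
            jac_exprs <- lapply(self$diff_vars, function(v) eq_deriv(drift[[v]], v))
            names(jac_exprs) <- self$diff_vars
            jac <- function(st) {
              e <- list2env(st, parent = group$state_env)
              lapply(jac_exprs, function(j) if (is.null(j)) NULL else eval(j, e))
            }
            function(st, dt_s) exponential_euler_step(derivs, jac, st, dt_s)
          },
          euler_maruyama = {
            noise <- function(st) {
              e <- list2env(st, parent = group$state_env)
              lapply(gexpr, function(g) eval(g, e))
            }
            function(st, dt_s) euler_maruyama_step(derivs, noise, st, dt_s)
          },
          eq_abort("eqspike_error", sprintf("unknown method '%s'", self$method)))
        private$step_fn <- function() {
          st <- mget(group$diff_vars, envir = group$state_env)
          new <- stepper(st, dt_s)
          frozen <- private$frozen_vars
          if (length(frozen)) {
            refrac <- which(!group$not_ref)
            for (v in frozen) new[[v]][refrac] <- st[[v]][refrac]
          }
          for (v in group$diff_vars) {
            if (!all(is.finite(new[[v]])))
              integration_error(sprintf(
                "group '%s': variable '%s' became non-finite at t = %g s",
                group$name, v, get("t", envir = group$rt)))
            assign(v, new[[v]], envir = group$state_env)
          }
        }
      }
      private$frozen_vars <- names(Filter(function(e)
        "unless_refractory" %in% e$flags, self$eqs$entries))
      invisible(self)
    },

    set_time = function(t_s, dt_s) {
      assign("t", t_s, envir = self$rt)
      assign("dt", dt_s, envir = self$rt)
    },

    state_update = function(t_s) {
      self$not_ref <- if (self$refractory_s > 0)
        (t_s - self$last_spike) >= self$refractory_s else rep(TRUE, self$N)
      private$step_fn()
    },

    apply_threshold = function(t_s) {
      if (is.null(private$threshold_cond)) {
        self$spikes <- integer()
        return(integer())
      }
      self$not_ref <- if (self$refractory_s > 0)
        (t_s - self$last_spike) >= self$refractory_s else rep(TRUE, self$N)
      cond <- rep_len(eval(private$threshold_cond, self$state_env), self$N)
      spk <- which(cond & self$not_ref)
      self$last_spike[spk] <- t_s
      self$spikes <- spk
      spk
    },

    do_reset = function() {
      if (!is.null(private$reset_block) && length(self$spikes))
        private$reset_block$fn(self$spikes)
    },

    # ---- state access ------------------------------------------------------
    set_state = function(variable, value, subset = NULL) {
      self$check_writable(variable, setup = TRUE)
      idx <- private$resolve_subset(subset)
      vd <- self$dim_of(variable)
      if (is.character(value)) {
        expr <- self$inline_subexpressions(parse_rhs(value))
        self$check_resolvable(expr)
        d <- infer_dim(expr, self$dim_env(), self$function_sigs())
        if (!dim_eq(d, vd))
          dimension_mismatch(sprintf(
            "cannot set '%s' [%s] from expression of dimension [%s]",
            variable, format(vd), format(d)))
        reads <- intersect(expr_names(expr)$vars, self$resolvable_names())
        val <- eval(expr, self$subset_env(idx, reads))
      } else {
        if (!dim_eq(quantity_dim(value), vd))
          dimension_mismatch(sprintf(
            "cannot set '%s' [%s] to a value of dimension [%s]",
            variable, format(vd), format(quantity_dim(value))))
        val <- si_value(value)
      }
      cur <- get(variable, envir = self$state_env)
      if (is.null(idx)) cur <- rep_len(val, self$N) else cur[idx] <- val
      assign(variable, cur, envir = self$state_env)
      invisible(self)
    },

    get_state = function(variable, idx = NULL, as_quantity = TRUE) {
      e <- self$eqs$entries[[variable]]
      if (is.null(e))
        unresolved_identifier(sprintf("unknown variable '%s'", variable))
      v <- if (e$kind == "subexpression")
        eval(self$inline_subexpressions(e$rhs), self$state_env)
      else get(variable, envir = self$state_env)
      v <- rep_len(v, self$N)
      if (!is.null(idx)) v <- v[idx]
      if (as_quantity) quantity(v, e$dim) else v
    },

    # ---- snapshots ---------------------------------------------------------
    snapshot = function() {
      vars <- setdiff(ls(self$state_env), names(self$linked))
      list(state = mget(vars, envir = self$state_env),
           last_spike = self$last_spike, spikes = self$spikes)
    },
    restore_snapshot = function(snap) {
      for (v in names(snap$state)) assign(v, snap$state[[v]], envir = self$state_env)
      self$last_spike <- snap$last_spike
      self$spikes <- snap$spikes
      invisible(self)
    }
  ),
  private = list(
    threshold_cond = NULL,
    reset_block = NULL,
    step_fn = NULL,
    frozen_vars = character(),
    im_cache = NULL,
    resolve_subset = function(subset) {
      if (is.null(subset)) return(NULL)
      if (is.character(subset)) {
        expr <- self$inline_subexpressions(parse_rhs(subset))
        self$check_resolvable(expr)
        d <- infer_dim(expr, self$dim_env(), self$function_sigs())
        if (!is_dimless(d) || !is_boolean_expr(expr))
          dimension_mismatch("subset condition must be a dimensionless boolean")
        return(which(rep_len(eval(expr, self$state_env), self$N)))
      }
      idx <- as.integer(subset)
      if (any(idx < 1 | idx > self$N))
        eq_abort("eqspike_error", sprintf("subset index out of range 1..%d", self$N))
      idx
    }
  )
)

#' Create a population of model instances
#'
#' @param N number of instances.
#' @param model multi-line model string (see [parse_equations()]).
#' @param threshold dimensionless boolean condition string, or NULL.
#' @param reset statement string executed for spiking instances, or NULL.
#' @param refractory a time [quantity()]: after a spike the threshold is
#'   suppressed for this long (and `unless_refractory` variables frozen).
#' @param namespace named list of constants ([quantity()] or bare
#'   dimensionless numerics) and [register_function()] objects referenced
#'   by the model.
#' @param method integration method: `"auto"` (exact if linear and
#'   deterministic, else exponential Euler; Euler-Maruyama if stochastic),
#'   or one of `"exact"`, `"euler"`, `"rk4"`, `"exponential_euler"`,
#'   `"euler_maruyama"`.
#' @param name label used in error messages and output files.
#' @return a `NeuronGroup`.
#' @examples
#' g <- create_group(1, "dv/dt = -v/tau : volt",
#'                   threshold = "v > -50*mV", reset = "v = -60*mV",
#'                   namespace = list(tau = parse_unit_expression("10*ms")))
#' @export
create_group <- function(N, model, threshold = NULL, reset = NULL,
                         refractory = NULL, namespace = list(),
                         method = "auto", name = "group") {
  NeuronGroup$new(N, model, threshold, reset, refractory, namespace, method, name)
}

#' Set a state variable
#'
#' @param group a neuron group.
#' @param variable variable name.
#' @param value a [quantity()] (dimension must match), a bare numeric
#'   (dimensionless variables only), or an expression string which may use
#'   `i` (0-based instance index), `N`, `rand()`, `randn()` and other group
#'   variables.
#' @param subset NULL (all instances), a 1-based integer index vector, or a
#'   boolean condition string such as `"label == LP"`.
#' @export
set_state <- function(group, variable, value, subset = NULL) {
  group$set_state(variable, value, subset)
}

#' Read a state variable (or subexpression) as a Quantity
#' @param group a neuron group.
#' @param variable variable name.
#' @param idx optional 1-based index subset.
#' @export
get_state <- function(group, variable, idx = NULL) group$get_state(variable, idx)

#' Apply the threshold condition
#'
#' Returns the 1-based indices of instances whose threshold condition holds
#' and that are not refractory; their `last_spike` is updated.
#' @param group a neuron group.
#' @param t current time (a [quantity()] in seconds, or bare seconds).
#' @export
apply_threshold <- function(group, t) group$apply_threshold(si_value(t))

#' Link a read-only variable to another group's variable
#'
#' Reads of `target_var` in the target group always reflect the current
#' value of `source_var` in the source group, through `index_map`. Writes
#' to the target variable raise `WriteToLinked`.
#'
#' @param target,source neuron groups.
#' @param target_var,source_var variable names; dimensions must match and
#'   the target variable must be a parameter with the `linked` flag.
#' @param index_map 1-based integer vector of length `target$N` mapping
#'   each target instance to a source instance; defaults to `rep(1, N)`
#'   when the source has a single instance, identity when sizes match.
#' @export
link_variable <- function(target, target_var, source, source_var,
                          index_map = NULL) {
  te <- target$eqs$entries[[target_var]]
  se <- source$eqs$entries[[source_var]]
  if (is.null(te) || is.null(se))
    unresolved_identifier("unknown variable in link_variable()")
  if (!"linked" %in% te$flags)
    eq_abort("eqspike_error", sprintf(
      "target variable '%s' must be a parameter with the (linked) flag", target_var))
  if (!dim_eq(te$dim, se$dim))
    dimension_mismatch(sprintf("cannot link [%s] to [%s]",
                               format(te$dim), format(se$dim)))
  if (is.null(index_map)) {
    index_map <- if (source$N == 1) rep(1L, target$N)
    else if (source$N == target$N) seq_len(target$N)
    else eq_abort("eqspike_error", "index_map required when group sizes differ")
  }
  index_map <- as.integer(index_map)
  if (length(index_map) != target$N || any(index_map < 1 | index_map > source$N))
    eq_abort("eqspike_error", "index_map must map every target instance to a source instance")
  if (exists(target_var, envir = target$state_env, inherits = FALSE))
    rm(list = target_var, envir = target$state_env)
  makeActiveBinding(target_var, local({
    src <- source; sv <- source_var; im <- index_map; tv <- target_var
    function(value) {
      if (!missing(value)) write_to_linked(sprintf("variable '%s' is linked and read-only", tv))
      get(sv, envir = src$state_env)[im]
    }
  }), target$state_env)
  target$linked[[target_var]] <- list(source = source, source_var = source_var,
                                      index_map = index_map)
  invisible(list(target = c(target$name, target_var),
                 source = c(source$name, source_var), index_map = index_map))
}

#' Register a user-defined function for use in model expressions
#'
#' The implementation operates on SI-scaled bare numeric vectors and must
#' be deterministic given its inputs. Dimension checking of calls uses the
#' declared signature.
#'
#' @param name function name (must not collide with a unit or builtin).
#' @param implementation vectorized function of bare numerics.
#' @param arg_dims list of argument [dimension()]s.
#' @param return_dim the [dimension()] of the result.
#' @return a `registered_function` to be passed in a group's namespace.
#' @examples
#' # a stored waveform sampled at time t
#' wave <- sin(2 * pi * 440 * seq(0, 1, by = 1/8000))
#' snd <- register_function("sound",
#'   function(t) wave[pmin(length(wave), floor(t * 8000) + 1)],
#'   arg_dims = list(dimension(s = 1)), return_dim = dimension())
#' @export
register_function <- function(name, implementation, arg_dims, return_dim) {
  if (unit_is_registered(name) || name %in% c(BUILTIN_FUNCTIONS, names(RESERVED_DIMS())))
    name_collision(sprintf("'%s' is already a unit, builtin or reserved name", name))
  structure(list(name = name, impl = implementation,
                 arg_dims = arg_dims, return_dim = return_dim),
            class = "registered_function")
}

#' Extract spike times from a recorded membrane-potential trace
#'
#' One spike per strict upward crossing: sample k spikes iff
#' `trace[k] >= threshold` and `trace[k-1] < threshold`. The first sample
#' never spikes.
#'
#' @param trace [quantity()] vector (e.g. volts).
#' @param times time vector (quantity in seconds or bare seconds), same length.
#' @param threshold scalar [quantity()] with the dimension of `trace`.
#' @return numeric vector of spike times in seconds.
#' @export
extract_spikes_from_trace <- function(trace, times, threshold) {
  if (!dim_eq(quantity_dim(trace), quantity_dim(threshold)))
    dimension_mismatch("trace and threshold dimensions differ")
  v <- si_value(trace); tt <- si_value(times); th <- si_value(threshold)
  stopifnot(length(v) == length(tt))
  if (length(v) < 2) return(numeric())
  up <- which(v[-1] >= th & v[-length(v)] < th) + 1L
  tt[up]
}
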