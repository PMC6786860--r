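# Synapse populations: expression-based connectivity over the full
# source x target cross product, per-synapse state and dynamics,
# spike-triggered statements delivered through per-pathway delay queues,
# and continuous graded interactions via summed variables.
#
# Inside synaptic expressions, `i` and `j` are the 0-based pre- and
# post-synaptic neuron indices of each synapse; `X_pre` / `X_post` resolve
# to variable X of the source / target group, and `N` is the number of
# synapses.

SynapsePopulation <- R6::R6Class("SynapsePopulation",
  public = list(
    name = NULL, source = NULL, target = NULL,
    eqs = NULL, diff_vars = character(), params = character(),
    subexprs = character(), summed = list(),
    i = integer(), j = integer(), n_syn = 0L,
    syn_env = NULL, rt = NULL, ns_env = NULL,
    namespace = NULL, functions = NULL,
    pathways = list(), method_req = "auto", method = NULL,
    connected = FALSE,

    initialize = function(source, target, model = NULL, on_pre = NULL,
                          on_post = NULL, namespace = list(),
                          method = "auto", name = "synapses") {
      self$name <- name
      self$source <- source
      self$target <- target
      self$method_req <- method
      is_fun <- vapply(namespace, inherits, logical(1), what = "registered_function")
      self$namespace <- namespace[!is_fun]
      self$functions <- namespace[is_fun]
      names(self$functions) <- vapply(self$functions, function(f) f$name, character(1))

      if (!is.null(model)) {
        eqs <- if (inherits(model, "equation_set")) model else parse_equations(model)
        eqs <- validate_dimensions(eqs, c(self$namespace, private$suffixed_dims()),
                                   functions = self$function_sigs())
        self$eqs <- eqs
        for (e in eqs$entries) {
          if ("summed" %in% e$flags) {
            side <- if (grepl("_post$", e$name)) "post"
                    else if (grepl("_pre$", e$name)) "pre"
                    else illegal_flag(sprintf(
                      "summed entry '%s' must target a group variable via the _pre/_post suffix",
                      e$name))
            base <- sub("_(pre|post)$", "", e$name)
            grp <- if (side == "post") target else source
            be <- grp$eqs$entries[[base]]
            if (is.null(be))
              unresolved_identifier(sprintf(
                "summed entry '%s': no variable '%s' in the %s group", e$name, base, side))
            if (!dim_eq(be$dim, e$dim))
              dimension_mismatch(sprintf(
                "summed entry '%s' has dimension [%s] but targets [%s]",
                e$name, format(e$dim), format(be$dim)))
            self$summed[[e$name]] <- list(side = side, var = base, rhs = e$rhs)
          } else if (e$kind == "differential") {
            self$diff_vars <- c(self$diff_vars, e$name)
          } else if (e$kind == "parameter") {
            self$params <- c(self$params, e$name)
          } else {
            self$subexprs <- c(self$subexprs, e$name)
          }
        }
      }

      self$ns_env <- new.env(parent = builtin_funs_env())
      for (nm in names(self$namespace))
        assign(nm, si_value(self$namespace[[nm]]), envir = self$ns_env)
      for (f in self$functions) assign(f$name, f$impl, envir = self$ns_env)
      self$rt <- new.env(parent = self$ns_env)
      assign("t", 0, envir = self$rt)
      assign("dt", NA_real_, envir = self$rt)
      assign("N_pre", as.numeric(source$N), envir = self$rt)
      assign("N_post", as.numeric(target$N), envir = self$rt)
      self$syn_env <- new.env(parent = self$rt)

      mk_pathway <- function(spec, onto) {
        if (is.null(spec)) return(list())
        if (is.character(spec)) spec <- list(pre = spec)
        lapply(spec, function(stmts) list(statements = stmts, onto = onto,
                                          block = NULL, delay_s = numeric(),
                                          delay_steps = NULL, ring = NULL, pos = 1L))
      }
      self$pathways <- c(mk_pathway(on_pre, "pre"), mk_pathway(on_post, "post"))
      invisible(self)
    },

    # ---- connectivity ------------------------------------------------------
    connect = function(condition = NULL, p = NULL, pairs = NULL) {
      if (self$connected)
        eq_abort("eqspike_error", "synapse population is already connected")
      given <- c(!is.null(condition), !is.null(pairs))
      if (sum(given) > 1 || (is.null(condition) && is.null(p) && is.null(pairs)))
        eq_abort("eqspike_error",
                 "supply exactly one of: condition (with optional p), p alone, or explicit pairs")
      if (!is.null(p) && (p < 0 || p > 1))
        eq_abort("eqspike_error", "connection probability must be in [0, 1]")
      Ns <- self$source$N; Nt <- self$target$N
      if (!is.null(pairs)) {
        ii <- as.integer(pairs$i); jj <- as.integer(pairs$j)
        if (length(ii) != length(jj) || any(ii < 0 | ii >= Ns) || any(jj < 0 | jj >= Nt))
          eq_abort("eqspike_error", "explicit pairs out of range (0-based indices)")
      } else {
        cond_expr <- NULL
        if (!is.null(condition)) {
          cond_expr <- self$inline_subexpressions(parse_rhs(condition))
          self$check_resolvable(cond_expr)
          d <- infer_dim(cond_expr, self$dim_env(), self$function_sigs())
          if (!is_dimless(d) || !is_boolean_expr(cond_expr))
            dimension_mismatch("connection condition must be a dimensionless boolean")
        }
        reads <- if (is.null(cond_expr)) character()
                 else intersect(expr_names(cond_expr)$vars, private$pair_names())
        ii <- integer(); jj <- integer()
        chunk <- max(1L, as.integer(4e6 %/% max(1, Nt)))
        for (lo in seq(0L, Ns - 1L, by = chunk)) {
          hi <- min(Ns - 1L, lo + chunk - 1L)
          ci <- rep(lo:hi, each = Nt)
          cj <- rep.int(0:(Nt - 1L), hi - lo + 1L)
          keep <- if (is.null(cond_expr)) rep(TRUE, length(ci))
                  else rep_len(eval(cond_expr, private$pair_env(ci, cj, reads)), length(ci))
          if (!is.null(p)) {
            keep[keep] <- stats::runif(sum(keep)) < p
          }
          ii <- c(ii, ci[keep]); jj <- c(jj, cj[keep])
        }
      }
      self$i <- as.integer(ii); self$j <- as.integer(jj)
      self$n_syn <- length(ii)
      assign("N", as.numeric(self$n_syn), envir = self$rt)
      assign(".n", self$n_syn, envir = self$rt)
      assign("i", as.numeric(self$i), envir = self$rt)
      assign("j", as.numeric(self$j), envir = self$rt)
      for (v in c(self$diff_vars, self$params))
        assign(v, numeric(self$n_syn), envir = self$syn_env)
      for (pw in names(self$pathways))
        self$pathways[[pw]]$delay_s <- numeric(self$n_syn)
      # synapse lists per source / target neuron (1-based neuron index)
      private$adj_pre <- split(seq_len(self$n_syn), factor(self$i + 1L, levels = seq_len(Ns)))
      private$adj_post <- split(seq_len(self$n_syn), factor(self$j + 1L, levels = seq_len(Nt)))
      self$connected <- TRUE
      invisible(self)
    },

    # ---- context interface -------------------------------------------------
    resolvable_names = function() {
      c(self$diff_vars, self$params,
        paste0(c(self$source$diff_vars, self$source$params, names(self$source$linked)), "_pre"),
        paste0(c(self$target$diff_vars, self$target$params, names(self$target$linked)), "_post"))
    },
    dim_env = function() {
      d <- c(RESERVED_DIMS(), namespace_dims(self$namespace), private$suffixed_dims())
      if (!is.null(self$eqs)) for (e in self$eqs$entries) d[[e$name]] <- e$dim
      d$delay <- dimension(s = 1)
      d
    },
    function_sigs = function() {
      sigs <- lapply(self$functions, function(f)
        list(arg_dims = f$arg_dims, return_dim = f$return_dim))
      c(sigs, self$source$function_sigs(), self$target$function_sigs())
    },
    dim_of = function(name) {
      if (name == "delay") return(dimension(s = 1))
      d <- self$dim_env()
      if (is.null(d[[name]])) unresolved_identifier(sprintf("unknown variable '%s'", name))
      d[[name]]
    },
    inline_subexpressions = function(tree) {
      if (is.null(private$im_own)) private$im_own <- private$own_inline_map()
      if (is.null(private$im_grp)) private$im_grp <- private$group_inline_map()
      if (length(private$im_own)) tree <- subst_expr(tree, private$im_own)
      if (length(private$im_grp)) tree <- subst_expr(tree, private$im_grp)
      tree
    },
    check_resolvable = function(tree) {
      nm <- expr_names(tree)
      known <- c(self$resolvable_names(), self$subexprs, "delay",
                 names(self$namespace), names(RESERVED_DIMS()), "N_pre", "N_post",
                 names(private$suffixed_dims()))
      bad <- setdiff(nm$vars, known)
      bad <- bad[!vapply(bad, unit_in_expressions, logical(1))]
      if (length(bad))
        unresolved_identifier(sprintf("synapses '%s': unknown identifier(s) %s",
                                      self$name, paste(bad, collapse = ", ")))
      badf <- setdiff(nm$funs, c(BUILTIN_FUNCTIONS, names(self$function_sigs())))
      if (length(badf))
        unresolved_identifier(sprintf("synapses '%s': unknown function(s) %s",
                                      self$name, paste(badf, collapse = ", ")))
    },
    check_writable = function(name, setup = FALSE) {
      if (name == "delay") return(invisible())
      if (name %in% self$params) {
        if (!setup && "constant" %in% self$eqs$entries[[name]]$flags)
          assignment_to_constant(sprintf("synaptic variable '%s' is declared constant", name))
        return(invisible())
      }
      if (name %in% self$diff_vars) return(invisible())
      if (grepl("_(pre|post)$", name)) {
        base <- sub("_(pre|post)$", "", name)
        grp <- if (grepl("_post$", name)) self$target else self$source
        return(grp$check_writable(base, setup))
      }
      unresolved_identifier(sprintf("synapses '%s': cannot write unknown variable '%s'",
                                    self$name, name))
    },
    subset_env = function(idx, names) {
      e <- new.env(parent = self$rt)
      si <- if (is.null(idx)) self$i else self$i[idx]
      sj <- if (is.null(idx)) self$j else self$j[idx]
      for (v in intersect(names, c(self$diff_vars, self$params))) {
        x <- get(v, envir = self$syn_env)
        assign(v, if (is.null(idx)) x else x[idx], envir = e)
      }
      for (v in names[grepl("_pre$", names)]) {
        base <- sub("_pre$", "", v)
        if (base %in% c(self$source$diff_vars, self$source$params, names(self$source$linked)))
          assign(v, get(base, envir = self$source$state_env)[si + 1L], envir = e)
      }
      for (v in names[grepl("_post$", names)]) {
        base <- sub("_post$", "", v)
        if (base %in% c(self$target$diff_vars, self$target$params, names(self$target$linked)))
          assign(v, get(base, envir = self$target$state_env)[sj + 1L], envir = e)
      }
      if (!is.null(idx)) {
        assign("i", as.numeric(si), envir = e)
        assign("j", as.numeric(sj), envir = e)
        assign(".n", length(idx), envir = e)
      }
      e
    },
    write_back = function(target, idx, new, op, delta) {
      if (target %in% c(self$diff_vars, self$params)) {
        cur <- get(target, envir = self$syn_env)
        if (is.null(idx)) cur <- rep_len(new, self$n_syn) else cur[idx] <- new
        assign(target, cur, envir = self$syn_env)
        return(invisible())
      }
      side <- if (grepl("_post$", target)) "post" else "pre"
      base <- sub("_(pre|post)$", "", target)
      grp <- if (side == "post") self$target else self$source
      nidx <- (if (side == "post") self$j else self$i)
      nidx <- (if (is.null(idx)) nidx else nidx[idx]) + 1L
      arr <- get(base, envir = grp$state_env)
      if (op == "=") {
        arr[nidx] <- new
      } else {
        d <- rep_len(delta, length(nidx))
        if (op == "-=") d <- -d
        agg <- rowsum(d, nidx, reorder = FALSE)
        at <- as.integer(rownames(agg))
        arr[at] <- arr[at] + agg[, 1]
      }
      assign(base, arr, envir = grp$state_env)
    },

    # ---- per-synapse state -------------------------------------------------
    set_synapse_state = function(variable, value, subset = NULL, pathway = NULL) {
      if (!self$connected) eq_abort("eqspike_error", "connect() the population first")
      self$check_writable(variable, setup = TRUE)
      idx <- private$resolve_subset(subset)
      vd <- self$dim_of(variable)
      if (is.character(value)) {
        expr <- self$inline_subexpressions(parse_rhs(value))
        self$check_resolvable(expr)
        d <- infer_dim(expr, self$dim_env(), self$function_sigs())
        if (!dim_eq(d, vd))
          dimension_mismatch(sprintf("cannot set '%s' [%s] from expression of dimension [%s]",
                                     variable, format(vd), format(d)))
        reads <- intersect(expr_names(expr)$vars,
                           c(self$resolvable_names(), self$diff_vars, self$params))
        val <- eval(expr, self$subset_env(idx, reads))
      } else {
        if (!dim_eq(quantity_dim(value), vd))
          dimension_mismatch(sprintf("cannot set '%s' [%s] to a value of dimension [%s]",
                                     variable, format(vd), format(quantity_dim(value))))
        val <- si_value(value)
      }
      if (variable == "delay") {
        pw <- private$pick_pathway(pathway)
        cur <- self$pathways[[pw]]$delay_s
        if (is.null(idx)) cur <- rep_len(val, self$n_syn) else cur[idx] <- val
        self$pathways[[pw]]$delay_s <- cur
      } else {
        cur <- get(variable, envir = self$syn_env)
        if (is.null(idx)) cur <- rep_len(val, self$n_syn) else cur[idx] <- val
        assign(variable, cur, envir = self$syn_env)
      }
      invisible(self)
    },

    get_synapse_state = function(variable, idx = NULL, pathway = NULL) {
      if (variable == "delay") {
        v <- self$pathways[[private$pick_pathway(pathway)]]$delay_s
        if (!is.null(idx)) v <- v[idx]
        return(quantity(v, dimension(s = 1)))
      }
      if (variable %in% self$subexprs || variable %in% names(self$summed)) {
        e <- self$eqs$entries[[variable]]
        expr <- self$inline_subexpressions(e$rhs)
        reads <- intersect(expr_names(expr)$vars, self$resolvable_names())
        v <- rep_len(eval(expr, self$subset_env(NULL, reads)), self$n_syn)
        if (!is.null(idx)) v <- v[idx]
        return(quantity(v, e$dim))
      }
      v <- get(variable, envir = self$syn_env)
      if (!is.null(idx)) v <- v[idx]
      quantity(v, self$dim_of(variable))
    },

    # ---- schedule ----------------------------------------------------------
    blocks = function() {
      b <- list()
      if (length(self$diff_vars) || length(self$summed))
        b <- c(b, list(list(kind = "summed_update", slot = 1L)))
      if (length(self$pathways))
        b <- c(b, list(list(kind = "synapse_event", slot = 4L)))
      b
    },

    prepare = function(dt_s) {
      if (!self$connected) eq_abort("eqspike_error", sprintf(
        "synapses '%s' were never connected", self$name))
      assign("dt", dt_s, envir = self$rt)
      for (pw in names(self$pathways)) {
        p <- self$pathways[[pw]]
        if (is.null(p$block))
          self$pathways[[pw]]$block <- compile_statements(p$statements, self,
                                                          kind = "synapse_event")
        steps <- as.integer(floor(p$delay_s / dt_s + 0.5))  # ties round up
        self$pathways[[pw]]$delay_steps <- steps
        horizon <- max(steps, 0L) + 1L
        self$pathways[[pw]]$ring <- vector("list", horizon)
        self$pathways[[pw]]$ring[] <- list(integer())
        self$pathways[[pw]]$pos <- 1L
      }
      if (length(self$diff_vars)) private$build_updater(dt_s)
      invisible(self)
    },

    integrate_and_sum = function() {
      # per-synapse dynamics advance only once a timestep is known
      if (length(self$diff_vars) && !is.null(private$ode_step)) private$ode_step()
      if (is.null(private$summed_c)) {
        private$summed_c <- lapply(self$summed, function(s) {
          expr <- self$inline_subexpressions(s$rhs)
          list(side = s$side, var = s$var, expr = expr,
               reads = intersect(expr_names(expr)$vars,
                                 c(self$resolvable_names(), self$diff_vars, self$params)))
        })
      }
      for (s in private$summed_c) {
        grp <- if (s$side == "post") self$target else self$source
        acc <- numeric(grp$N)
        if (self$n_syn > 0) {
          vals <- rep_len(eval(s$expr, self$subset_env(NULL, s$reads)), self$n_syn)
          nidx <- (if (s$side == "post") self$j else self$i) + 1L
          agg <- rowsum(vals, nidx, reorder = FALSE)
          acc[as.integer(rownames(agg))] <- agg[, 1]
        }
        assign(s$var, acc, envir = grp$state_env)
      }
      invisible(self)
    },

    deliver = function() {
      for (pw in names(self$pathways)) {
        p <- self$pathways[[pw]]
        spikes <- if (p$onto == "pre") self$source$spikes else self$target$spikes
        adj <- if (p$onto == "pre") private$adj_pre else private$adj_post
        ring <- p$ring; pos <- p$pos; L <- length(ring)
        if (length(spikes)) {
          syn <- unlist(adj[spikes], use.names = FALSE)
          if (length(syn)) {
            ds <- p$delay_steps[syn]
            maxd <- max(ds)
            if (maxd + 1L > L) {  # regrow, preserving slot semantics
              ring2 <- vector("list", maxd + 1L)
              ring2[] <- list(integer())
              for (off in 0:(L - 1L))
                ring2[[off + 1L]] <- ring[[(pos - 1L + off) %% L + 1L]]
              ring <- ring2; pos <- 1L; L <- maxd + 1L
            }
            for (grpd in split(syn, ds)) {
              d <- p$delay_steps[grpd[1]]
              slot <- (pos - 1L + d) %% L + 1L
              ring[[slot]] <- c(ring[[slot]], grpd)
            }
          }
        }
        due <- ring[[pos]]
        ring[[pos]] <- integer()
        self$pathways[[pw]]$ring <- ring
        self$pathways[[pw]]$pos <- pos %% L + 1L
        if (length(due)) p$block$fn(due)
      }
      invisible(self)
    },

    set_time = function(t_s, dt_s) {
      assign("t", t_s, envir = self$rt)
      assign("dt", dt_s, envir = self$rt)
    },

    # ---- snapshots ---------------------------------------------------------
    snapshot = function() {
      list(state = mget(ls(self$syn_env), envir = self$syn_env),
           pathways = lapply(self$pathways, function(p)
             list(ring = p$ring, pos = p$pos, delay_s = p$delay_s)))
    },
    restore_snapshot = function(snap) {
      for (v in names(snap$state)) assign(v, snap$state[[v]], envir = self$syn_env)
      for (pw in names(snap$pathways)) {
        self$pathways[[pw]]$ring <- snap$pathways[[pw]]$ring
        self$pathways[[pw]]$pos <- snap$pathways[[pw]]$pos
        self$pathways[[pw]]$delay_s <- snap$pathways[[pw]]$delay_s
      }
      invisible(self)
    }
  ),

  private = list(
    adj_pre = NULL, adj_post = NULL, ode_step = NULL,
    im_own = NULL, im_grp = NULL, summed_c = NULL,

    suffixed_dims = function() {
      d <- list()
      for (e in self$source$eqs$entries) d[[paste0(e$name, "_pre")]] <- e$dim
      for (e in self$target$eqs$entries) d[[paste0(e$name, "_post")]] <- e$dim
      d
    },
    pair_names = function() {
      c(paste0(c(self$source$diff_vars, self$source$params, names(self$source$linked)), "_pre"),
        paste0(c(self$target$diff_vars, self$target$params, names(self$target$linked)), "_post"))
    },
    pair_env = function(ci, cj, reads) {
      e <- new.env(parent = self$rt)
      assign("i", as.numeric(ci), envir = e)
      assign("j", as.numeric(cj), envir = e)
      assign(".n", length(ci), envir = e)
      for (v in reads) {
        base <- sub("_(pre|post)$", "", v)
        if (grepl("_pre$", v))
          assign(v, get(base, envir = self$source$state_env)[ci + 1L], envir = e)
        else
          assign(v, get(base, envir = self$target$state_env)[cj + 1L], envir = e)
      }
      e
    },
    # inline this population's own (non-summed) subexpressions
    own_inline_map = function() {
      if (is.null(self$eqs)) return(list())
      map <- list()
      ord <- order_subexpressions(self$eqs)
      for (nm in ord) {
        e <- self$eqs$entries[[nm]]
        if (e$kind == "subexpression" && !"summed" %in% e$flags)
          map[[nm]] <- subst_expr(e$rhs, map)
      }
      map
    },
    # inline X_pre / X_post where X is a subexpression of the source/target
    group_inline_map = function() {
      map <- list()
      for (side in c("pre", "post")) {
        grp <- if (side == "pre") self$source else self$target
        gm <- inline_map(grp$eqs)
        statey <- c(grp$diff_vars, grp$params, names(grp$linked))
        for (nm in names(gm))
          map[[paste0(nm, "_", side)]] <-
            suffix_expr(gm[[nm]], paste0("_", side), statey)
      }
      map
    },
    pick_pathway = function(pathway) {
      if (!length(self$pathways))
        eq_abort("eqspike_error", "population has no event pathway (no on_pre/on_post)")
      if (is.null(pathway)) {
        if (length(self$pathways) > 1)
          eq_abort("eqspike_error", sprintf(
            "multiple pathways (%s); name one explicitly",
            paste(names(self$pathways), collapse = ", ")))
        return(names(self$pathways)[1])
      }
      if (!pathway %in% names(self$pathways))
        eq_abort("eqspike_error", sprintf("no pathway named '%s'", pathway))
      pathway
    },
    resolve_subset = function(subset) {
      if (is.null(subset)) return(NULL)
      if (is.character(subset)) {
        expr <- self$inline_subexpressions(parse_rhs(subset))
        self$check_resolvable(expr)
        d <- infer_dim(expr, self$dim_env(), self$function_sigs())
        if (!is_dimless(d) || !is_boolean_expr(expr))
          dimension_mismatch("subset condition must be a dimensionless boolean")
        reads <- intersect(expr_names(expr)$vars,
                           c(self$resolvable_names(), self$diff_vars, self$params))
        return(which(rep_len(eval(expr, self$subset_env(NULL, reads)), self$n_syn)))
      }
      idx <- as.integer(subset)
      if (any(idx < 1 | idx > self$n_syn))
        eq_abort("eqspike_error", "synapse subset index out of range")
      idx
    },
    build_updater = function(dt_s) {
      pop <- self
      m <- private$own_inline_map()
      fexprs <- lapply(self$eqs$entries[self$diff_vars], function(e)
        self$inline_subexpressions(e$rhs))
      names(fexprs) <- self$diff_vars
      stoch <- detect_stochastic(self$eqs)
      self$method <- if (length(stoch)) "euler_maruyama"
                     else if (self$method_req %in% c("auto", "exact")) "exponential_euler"
                     else self$method_req
      gexpr <- NULL
      if (self$method == "euler_maruyama") {
        parts <- lapply(fexprs, split_noise)
        fexprs <- lapply(parts, `[[`, "drift")
        gexpr <- lapply(parts, `[[`, "g")
      }
      reads <- setdiff(unique(unlist(lapply(fexprs, function(e) expr_names(e)$vars))),
                       self$diff_vars)
      reads <- intersect(reads, c(self$resolvable_names(), self$params))
      jac_exprs <- lapply(self$diff_vars, function(v) eq_deriv(fexprs[[v]], v))
      names(jac_exprs) <- self$diff_vars
      private$ode_step <- function() {
        if (!pop$n_syn) return(invisible())
        base <- pop$subset_env(NULL, reads)
        derivs <- function(st) {
          e <- list2env(st, parent = base)
          lapply(fexprs, eval, envir = e)
        }
        st <- mget(pop$diff_vars, envir = pop$syn_env)
        new <- switch(pop$method,
          euler = euler_step(derivs, st, dt_s),
          rk4 = rk4_step(derivs, st, dt_s),
          exponential_euler = {
            jac <- function(stl) {
              e <- list2env(stl, parent = base)
              lapply(jac_exprs, function(jx) if (is.null(jx)) NULL else eval(jx, e))
            }
            exponential_euler_step(derivs, jac, st, dt_s)
          },
          euler_maruyama = {
            noise <- function(stl) {
              e <- list2env(stl, parent = base)
              lapply(gexpr, eval, envir = e)
            }
            euler_maruyama_step(derivs, noise, st, dt_s)
          })
        for (v in pop$diff_vars) {
          if (!all(is.finite(new[[v]])))
            integration_error(sprintf("synapses '%s': variable '%s' became non-finite",
                                      pop$name, v))
          assign(v, rep_len(new[[v]], pop$n_syn), envir = pop$syn_env)
        }
      }
    }
  )
)

# rename state-variable identifiers by appending a suffix
suffix_expr <- function(e, suffix, names) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm %in% names) return(as.name(paste0(nm, suffix)))
    return(e)
  }
  if (is.call(e)) {
    start <- if (is.name(e[[1]])) 2L else 1L
    for (k in seq_along(e)[-seq_len(start - 1L)]) e[[k]] <- suffix_expr(e[[k]], suffix, names)
    return(e)
  }
  e
}

#' Create a synapse population
#'
#' @param source,target neuron groups.
#' @param model optional per-synapse model string. Differential and
#'   parameter entries become per-synapse state; a subexpression entry
#'   named `X_post` (or `X_pre`) with the `(summed)` flag continuously sets
#'   variable X of the target (source) group to the sum of the expression
#'   over each neuron's synapses.
#' @param on_pre statements executed when a presynaptic spike arrives
#'   (after its pathway delay): a single string, or a named list of strings
#'   defining multiple pathways with independent delays.
#' @param on_post as `on_pre`, triggered by postsynaptic spikes.
#' @param namespace constants and registered functions, as for
#'   [create_group()].
#' @param method integration method for per-synapse differential equations
#'   (default exponential Euler; Euler-Maruyama if stochastic).
#' @param name label.
#' @export
create_synapses <- function(source, target, model = NULL, on_pre = NULL,
                            on_post = NULL, namespace = list(),
                            method = "auto", name = "synapses") {
  SynapsePopulation$new(source, target, model, on_pre, on_post,
                        namespace, method, name)
}

#' Populate a synapse population
#'
#' Exactly one of `condition` (optionally with `p`), `p` alone, or explicit
#' `pairs` must be given. With a condition, a synapse is created for every
#' (i, j) in the full source x target cross product where the condition
#' holds (and, if `p` is given, an independent uniform draw falls below p).
#' Creation order is row-major in (i, j) and deterministic given the seed.
#'
#' @param pop a synapse population.
#' @param condition boolean string over `i`, `j` and `_pre`/`_post`
#'   variables, e.g. `"i != j"`.
#' @param p connection probability in `[0, 1]`.
#' @param pairs list with 0-based integer vectors `i` and `j`.
#' @export
connect <- function(pop, condition = NULL, p = NULL, pairs = NULL) {
  pop$connect(condition, p, pairs)
}

#' Set per-synapse state (including delays)
#'
#' @param pop a connected synapse population.
#' @param variable per-synapse variable name, a `_pre`/`_post` suffixed
#'   group variable, or `"delay"`.
#' @param value quantity or expression string; expressions may use `i`,
#'   `j`, per-synapse variables and `_pre`/`_post` variables.
#' @param subset NULL, 1-based synapse indices, or a boolean condition.
#' @param pathway pathway name for `"delay"` when several pathways exist.
#' @export
set_synapse_state <- function(pop, variable, value, subset = NULL, pathway = NULL) {
  pop$set_synapse_state(variable, value, subset, pathway)
}

#' Read per-synapse state as a Quantity
#' @inheritParams set_synapse_state
#' @param idx optional 1-based synapse indices.
#' @export
get_synapse_state <- function(pop, variable, idx = NULL, pathway = NULL) {
  pop$get_synapse_state(variable, idx, pathway)
}

#' Recompute summed variables and integrate per-synapse dynamics
#'
#' Runs the population's slot-1 work outside of [run_network()]: advances
#' per-synapse differential equations by one step (when prepared) and
#' overwrites each summed target variable with the per-neuron sum of its
#' expression (neurons without synapses get zero).
#'
#' @param pop a connected synapse population.
#' @export
update_summed <- function(pop) pop$integrate_and_sum()

#' Write connectivity and per-synapse state to CSV
#'
#' Columns: `i`, `j` (0-based), one `delay_<pathway>_seconds` column per
#' pathway, then per-synapse variables in SI scale.
#' @param pop a connected synapse population.
#' @param path output file.
#' @export
write_connectivity_csv <- function(pop, path) {
  df <- data.frame(i = pop$i, j = pop$j)
  for (pw in names(pop$pathways))
    df[[paste0("delay_", pw, "_seconds")]] <- pop$pathways[[pw]]$delay_s
  for (v in c(pop$diff_vars, pop$params))
    df[[v]] <- get(v, envir = pop$syn_env)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Connect a population from a CSV pair list
#'
#' Expects columns `i` and `j` holding 0-based neuron indices.
#' @param pop a synapse population.
#' @param path CSV file.
#' @export
connect_from_csv <- function(pop, path) {
  df <- utils::read.csv(path)
  pop$connect(pairs = list(i = df$i, j = df$j))
}
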