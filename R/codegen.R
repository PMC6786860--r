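# Kernel compilation: validated expression trees and statement strings are
# turned into vectorized kernels evaluated over named state arrays. Kernels
# are grouped into the per-timestep code blocks of the simulation schedule:
# state_update, threshold, reset, synapse_event, summed_update.
#
# "Code generation" here means compilation to vectorized host-runtime
# kernels (R expressions evaluated over full state arrays or index
# subsets), preserving the abstract-code -> blocks -> schedule
# architecture; no native source is emitted.

builtin_funs_env <- function() {
  e <- new.env(parent = unit_value_env())
  e$clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  e$int <- function(x) as.numeric(trunc(as.numeric(x)))
  # (exp(x)-1)/x with its removable singularity at 0 filled in; keeps
  # Hodgkin-Huxley style rate functions finite at their crossover voltages
  e$exprel <- function(x) ifelse(abs(x) < 1e-9, 1 + x / 2, expm1(x) / x)
  e$ceiling <- ceiling
  e$rand <- function() stats::runif(get(".n", envir = parent.frame()))
  e$randn <- function() stats::rnorm(get(".n", envir = parent.frame()))
  e
}

#' Compile an expression tree to a vectorized kernel
#'
#' The kernel evaluates the tree element-wise over the instances of the
#' context (all of them, or an index subset); `rand()`/`randn()` draw one
#' value per evaluated instance from the simulation RNG stream.
#'
#' @param tree expression tree (or string), using the model grammar.
#' @param ctx a neuron group or synapse population supplying state arrays
#'   and namespace.
#' @return a function `(idx = NULL) -> numeric/logical vector`; `idx` is a
#'   1-based instance subset (NULL = all instances).
#' @export
compile_expression <- function(tree, ctx) {
  if (is.character(tree)) tree <- parse_rhs(tree)
  ctx$check_resolvable(tree)
  tree <- ctx$inline_subexpressions(tree)
  reads <- intersect(expr_names(tree)$vars, ctx$resolvable_names())
  function(idx = NULL) ctx$eval_expr(tree, idx, reads)
}

#' Compile a statement string into an executable code block
#'
#' Statements execute in source order over the supplied index subset;
#' reads of a variable after an assignment within the same block see the
#' new value. Augmented assignments (`+=`, `-=`) into a shared target
#' array accumulate contributions when several evaluated instances write
#' to the same element.
#'
#' @param statements statement string (see [parse_statements()]).
#' @param ctx a neuron group or synapse pathway context.
#' @param kind block kind label (`"reset"`, `"synapse_event"`, ...).
#' @return a code block: list with `kind`, `reads`, `writes` and an
#'   executor `fn(idx)`.
#' @export
compile_statements <- function(statements, ctx, kind = "reset") {
  stmts <- if (is.character(statements)) parse_statements(statements) else statements
  compiled <- list()
  reads <- character(); writes <- character()
  for (s in stmts) {
    ctx$check_writable(s$target)
    rhs <- ctx$inline_subexpressions(s$rhs)
    ctx$check_resolvable(rhs)
    rd <- infer_dim(rhs, ctx$dim_env(), ctx$function_sigs())
    td <- ctx$dim_of(s$target)
    if (!dim_eq(rd, td))
      dimension_mismatch(sprintf(
        "statement '%s %s %s': right-hand side has dimension [%s], target has [%s]",
        s$target, s$op, s$rhs_text, format(rd), format(td)))
    compiled[[length(compiled) + 1L]] <- list(target = s$target, op = s$op, rhs = rhs)
    reads <- union(reads, intersect(expr_names(rhs)$vars, ctx$resolvable_names()))
    writes <- union(writes, s$target)
  }
  fn <- function(idx = NULL) {
    if (!is.null(idx) && !length(idx)) return(invisible())
    env <- ctx$subset_env(idx, union(reads, writes))
    for (s in compiled) {
      val <- eval(s$rhs, env)
      cur <- get(s$target, envir = env)
      new <- switch(s$op, "=" = rep_len(val, length(cur)),
                    "+=" = cur + val, "-=" = cur - val)
      assign(s$target, new, envir = env)
      ctx$write_back(s$target, idx, new, s$op, val)
    }
    invisible()
  }
  list(kind = kind, reads = reads, writes = writes, fn = fn)
}

#' List the code blocks an object contributes to the schedule
#'
#' A neuron group yields a `state_update` block, plus `threshold` and
#' `reset` blocks when defined; a synapse population yields
#' `summed_update` and/or `synapse_event` blocks.
#'
#' @param obj a neuron group or synapse population.
#' @return list of blocks, each with `kind` and `slot` (schedule position).
#' @export
build_blocks <- function(obj) {
  obj$blocks()
}
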