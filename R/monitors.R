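# Monitors record state trajectories, spikes and population rates during a
# run. They sample in slot (6), after resets, so a recorded membrane
# potential shows its post-reset value on spike steps. Events and samples
# of step k are stamped with the step's start time t_k = k*dt.

Monitor <- R6::R6Class("Monitor",
  public = list(
    name = "monitor", group = NULL,
    record = function(t_s) invisible(),
    snapshot = function() list(),
    restore_snapshot = function(snap) invisible()
  )
)

StateMonitor <- R6::R6Class("StateMonitor", inherit = Monitor,
  public = list(
    variables = NULL, idx = NULL, every = 1L,
    initialize = function(group, variables, record = TRUE, every = 1L,
                          name = paste0("state_", group$name)) {
      self$group <- group
      self$name <- name
      self$variables <- variables
      for (v in variables)
        if (is.null(group$eqs$entries[[v]]))
          unresolved_identifier(sprintf("cannot record unknown variable '%s'", v))
      self$idx <- if (isTRUE(record)) seq_len(group$N) else as.integer(record)
      self$every <- as.integer(every)
      private$buf_t <- numeric(64)
      private$buf_v <- lapply(variables, function(v) matrix(0, 64, length(self$idx)))
      names(private$buf_v) <- variables
    },
    record = function(t_s) {
      private$tick <- private$tick + 1L
      if ((private$tick - 1L) %% self$every != 0L) return(invisible())
      n <- private$count + 1L
      if (n > length(private$buf_t)) {
        private$buf_t <- c(private$buf_t, numeric(length(private$buf_t)))
        for (v in self$variables)
          private$buf_v[[v]] <- rbind(private$buf_v[[v]],
                                      matrix(0, nrow(private$buf_v[[v]]), length(self$idx)))
      }
      private$buf_t[n] <- t_s
      for (v in self$variables)
        private$buf_v[[v]][n, ] <- self$group$get_state(v, self$idx, as_quantity = FALSE)
      private$count <- n
      invisible()
    },
    times = function() private$buf_t[seq_len(private$count)],
    values = function(variable, as_quantity = TRUE) {
      m <- private$buf_v[[variable]][seq_len(private$count), , drop = FALSE]
      if (as_quantity) quantity(m, self$group$eqs$entries[[variable]]$dim) else m
    },
    snapshot = function() list(count = private$count, tick = private$tick,
                               t = private$buf_t, v = private$buf_v),
    restore_snapshot = function(snap) {
      private$count <- snap$count; private$tick <- snap$tick
      private$buf_t <- snap$t; private$buf_v <- snap$v
      invisible()
    }
  ),
  private = list(buf_t = NULL, buf_v = NULL, count = 0L, tick = 0L)
)

SpikeMonitor <- R6::R6Class("SpikeMonitor", inherit = Monitor,
  public = list(
    initialize = function(group, name = paste0("spikes_", group$name)) {
      self$group <- group
      self$name <- name
      private$buf_t <- numeric(256)
      private$buf_i <- integer(256)
    },
    record = function(t_s) {
      spk <- self$group$spikes
      ns <- length(spk)
      if (!ns) return(invisible())
      need <- private$count + ns
      while (need > length(private$buf_t)) {
        private$buf_t <- c(private$buf_t, numeric(length(private$buf_t)))
        private$buf_i <- c(private$buf_i, integer(length(private$buf_i)))
      }
      private$buf_t[private$count + seq_len(ns)] <- t_s
      private$buf_i[private$count + seq_len(ns)] <- spk - 1L  # 0-based indices
      private$count <- need
      invisible()
    },
    times = function() private$buf_t[seq_len(private$count)],
    indices = function() private$buf_i[seq_len(private$count)],
    n_spikes = function() private$count,
    spike_counts = function() tabulate(private$buf_i[seq_len(private$count)] + 1L,
                                       nbins = self$group$N),
    snapshot = function() list(count = private$count, t = private$buf_t, i = private$buf_i),
    restore_snapshot = function(snap) {
      private$count <- snap$count; private$buf_t <- snap$t; private$buf_i <- snap$i
      invisible()
    }
  ),
  private = list(buf_t = NULL, buf_i = NULL, count = 0L)
)

RateMonitor <- R6::R6Class("RateMonitor", inherit = Monitor,
  public = list(
    dt_s = NA_real_,
    initialize = function(group, name = paste0("rate_", group$name)) {
      self$group <- group
      self$name <- name
      private$buf_t <- numeric(256)
      private$buf_r <- numeric(256)
    },
    record = function(t_s) {
      n <- private$count + 1L
      if (n > length(private$buf_t)) {
        private$buf_t <- c(private$buf_t, numeric(length(private$buf_t)))
        private$buf_r <- c(private$buf_r, numeric(length(private$buf_r)))
      }
      dt_s <- get("dt", envir = self$group$rt)
      self$dt_s <- dt_s
      private$buf_t[n] <- t_s
      private$buf_r[n] <- length(self$group$spikes) / (self$group$N * dt_s)
      private$count <- n
      invisible()
    },
    times = function() private$buf_t[seq_len(private$count)],
    rates = function() quantity(private$buf_r[seq_len(private$count)], dimension(s = -1)),
    snapshot = function() list(count = private$count, t = private$buf_t, r = private$buf_r),
    restore_snapshot = function(snap) {
      private$count <- snap$count; private$buf_t <- snap$t; private$buf_r <- snap$r
      invisible()
    }
  ),
  private = list(buf_t = NULL, buf_r = NULL, count = 0L)
)

#' Record state variables during a run
#'
#' One sample per `every` timesteps, taken after resets. Recording a subset
#' of instances yields exactly the corresponding slice of a full recording.
#'
#' @param group a neuron group.
#' @param variables character vector of variables (subexpressions allowed).
#' @param record TRUE for all instances or a 1-based index vector.
#' @param every sample every k-th timestep (default every step).
#' @param name monitor label.
#' @export
state_monitor <- function(group, variables, record = TRUE, every = 1L,
                          name = paste0("state_", group$name)) {
  StateMonitor$new(group, variables, record, every, name)
}

#' Record spikes during a run
#' @param group a neuron group.
#' @param name monitor label.
#' @return a monitor with `$times()` (seconds, nondecreasing) and
#'   `$indices()` (0-based neuron indices).
#' @export
spike_monitor <- function(group, name = paste0("spikes_", group$name)) {
  SpikeMonitor$new(group, name)
}

#' Record the instantaneous population rate
#'
#' rate_k = spikes_in_step_k / (N * dt), so that sum(rate * dt * N) over a
#' run equals the total spike count.
#' @param group a neuron group.
#' @param name monitor label.
#' @export
rate_monitor <- function(group, name = paste0("rate_", group$name)) {
  RateMonitor$new(group, name)
}

#' Write recorded spikes as CSV (columns: t, neuron)
#' @param monitor a spike monitor.
#' @param path output file.
#' @export
write_spikes_csv <- function(monitor, path) {
  utils::write.csv(data.frame(t = monitor$times(), neuron = monitor$indices()),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write recorded state as CSV
#'
#' Columns: `t_seconds`, then one column per recorded variable and
#' instance (`<var>_<neuron>`, 0-based), in SI scale.
#' @param monitor a state monitor.
#' @param path output file.
#' @export
write_states_csv <- function(monitor, path) {
  df <- data.frame(t_seconds = monitor$times())
  for (v in monitor$variables) {
    m <- monitor$values(v, as_quantity = FALSE)
    colnames(m) <- paste0(v, "_", monitor$idx - 1L)
    df <- cbind(df, m)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
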