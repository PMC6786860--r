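# The computational-experiment backbone: a single global clock, the fixed
# per-timestep schedule, named full-state snapshots, and seeding.
#
# Slot order within one timestep:
#   (1) summed/graded updates and per-synapse integration
#   (2) group state updates
#   (3) thresholds
#   (4) spike delivery (queue push for this step's spikes, then pop + on_pre)
#   (5) resets
#   (6) monitors
# so that the integration of each step sees this step's graded synaptic
# drive, zero-delay spikes are delivered within the step that produced
# them, and monitors sample post-reset values.

Network <- R6::R6Class("Network",
  public = list(
    dt_s = NULL, timestep = 0L,
    groups = list(), synapses = list(), monitors = list(),
    stored = list(), slot_log = NULL,

    initialize = function(..., dt = parse_unit_expression("0.1*ms")) {
      if (!dim_eq(quantity_dim(dt), dimension(s = 1)))
        dimension_mismatch("dt must be a time")
      self$dt_s <- si_value(dt)
      stopifnot(self$dt_s > 0)
      for (obj in list(...)) self$add(obj)
      invisible(self)
    },

    add = function(obj) {
      if (inherits(obj, "NeuronGroup")) self$groups <- c(self$groups, list(obj))
      else if (inherits(obj, "SynapsePopulation")) self$synapses <- c(self$synapses, list(obj))
      else if (inherits(obj, "Monitor")) self$monitors <- c(self$monitors, list(obj))
      else if (is.list(obj)) for (o in obj) self$add(o)
      else eq_abort("eqspike_error", "cannot add object of this class to a network")
      invisible(self)
    },

    t_now = function() quantity(self$timestep * self$dt_s, dimension(s = 1)),

    prepare = function() {
      # two populations must not sum into the same target variable
      keys <- unlist(lapply(self$synapses, function(sp)
        vapply(sp$summed, function(s) {
          grp <- if (s$side == "post") sp$target else sp$source
          paste(grp$name, s$var, sep = "\r")
        }, character(1))))
      if (anyDuplicated(keys)) {
        k <- strsplit(keys[duplicated(keys)][1], "\r")[[1]]
        summed_collision(sprintf(
          "two synapse populations sum into variable '%s' of group '%s'", k[2], k[1]))
      }
      for (g in self$groups) g$prepare(self$dt_s)
      for (s in self$synapses) s$prepare(self$dt_s)
      private$prepared_dt <- self$dt_s
      invisible(self)
    },

    run = function(duration) {
      if (!dim_eq(quantity_dim(duration), dimension(s = 1)))
        dimension_mismatch("duration must be a time")
      dur <- si_value(duration)
      stopifnot(dur >= 0)
      steps <- as.integer(floor(dur / self$dt_s + 0.5))
      if (abs(dur - steps * self$dt_s) > 1e-9 * self$dt_s)
        warning(sprintf("duration %g s is not a multiple of dt; running %d steps",
                        dur, steps))
      if (is.null(private$prepared_dt) || private$prepared_dt != self$dt_s)
        self$prepare()
      dt_s <- self$dt_s
      log_on <- !is.null(self$slot_log)
      for (k in seq_len(steps)) {
        t_s <- self$timestep * dt_s
        for (g in self$groups) g$set_time(t_s, dt_s)
        for (s in self$synapses) s$set_time(t_s, dt_s)
        for (s in self$synapses) { s$integrate_and_sum()
          if (log_on) private$log_slot(1L, s$name) }
        for (g in self$groups) { g$state_update(t_s)
          if (log_on) private$log_slot(2L, g$name) }
        for (g in self$groups) { g$apply_threshold(t_s)
          if (log_on) private$log_slot(3L, g$name) }
        for (s in self$synapses) { s$deliver()
          if (log_on) private$log_slot(4L, s$name) }
        for (g in self$groups) { g$do_reset()
          if (log_on) private$log_slot(5L, g$name) }
        for (m in self$monitors) { m$record(t_s)
          if (log_on) private$log_slot(6L, m$name) }
        self$timestep <- self$timestep + 1L
      }
      invisible(self)
    },

    store = function(name = "default") {
      if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
      self$stored[[name]] <- list(
        timestep = self$timestep,
        rng = get(".Random.seed", envir = globalenv()),
        groups = lapply(self$groups, function(g) g$snapshot()),
        synapses = lapply(self$synapses, function(s) s$snapshot()),
        monitors = lapply(self$monitors, function(m) m$snapshot()))
      invisible(self)
    },

    restore = function(name = "default") {
      snap <- self$stored[[name]]
      if (is.null(snap))
        restore_without_store(sprintf("no snapshot named '%s'", name))
      self$timestep <- snap$timestep
      assign(".Random.seed", snap$rng, envir = globalenv())
      for (k in seq_along(self$groups)) self$groups[[k]]$restore_snapshot(snap$groups[[k]])
      for (k in seq_along(self$synapses)) self$synapses[[k]]$restore_snapshot(snap$synapses[[k]])
      for (k in seq_along(self$monitors)) self$monitors[[k]]$restore_snapshot(snap$monitors[[k]])
      invisible(self)
    },

    enable_slot_log = function() { self$slot_log <- list(); invisible(self) }
  ),
  private = list(
    prepared_dt = NULL,
    log_slot = function(slot, name) {
      self$slot_log[[length(self$slot_log) + 1L]] <-
        list(step = self$timestep, slot = slot, object = name)
    }
  )
)

#' Assemble a network
#'
#' @param ... neuron groups, synapse populations, monitors, or lists of
#'   them.
#' @param dt the global timestep (a time [quantity()], default 0.1 ms).
#'   A single clock drives all objects.
#' @return a `Network`.
#' @export
create_network <- function(..., dt = parse_unit_expression("0.1*ms")) {
  Network$new(..., dt = dt)
}

#' Advance a network
#'
#' Executes `round(duration/dt)` timesteps of the fixed schedule; repeated
#' calls continue from the current time, so two consecutive runs of 50 ms
#' equal one 100 ms run exactly.
#'
#' @param network a network.
#' @param duration a time [quantity()] (>= 0).
#' @export
run_network <- function(network, duration) network$run(duration)

#' Snapshot / restore complete network state
#'
#' `store_network()` saves a named, complete copy of the clock, every state
#' array, spike queues, monitor buffers and the RNG state;
#' `restore_network()` replaces the live state with the snapshot, after
#' which continued simulation reproduces the original continuation
#' bit-exactly under the same seed.
#'
#' @param network a network.
#' @param name snapshot name.
#' @export
store_network <- function(network, name = "default") network$store(name)

#' @rdname store_network
#' @export
restore_network <- function(network, name = "default") network$restore(name)

#' Seed all randomness of a simulation
#'
#' Every stochastic draw (`rand()`/`randn()` in expressions, probabilistic
#' connectivity, Euler-Maruyama noise) consumes one common RNG stream;
#' identical seeds give identical simulations.
#'
#' @param network a network (accepted for symmetry; the stream is global).
#' @param seed integer seed.
#' @export
set_seed <- function(network = NULL, seed) {
  set.seed(as.integer(seed))
  invisible(network)
}
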