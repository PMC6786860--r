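# Condition constructors shared across the package. Every simulator error
# carries a subclass so callers (and tests) can distinguish failure modes
# without matching on message text.

eq_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "eqspike_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

dimension_mismatch <- function(msg, ...) eq_abort("DimensionMismatch", msg, ...)
unknown_unit <- function(msg, ...) eq_abort("UnknownUnit", msg, ...)
unresolved_identifier <- function(msg, ...) eq_abort("UnresolvedIdentifier", msg, ...)
duplicate_definition <- function(msg, ...) eq_abort("DuplicateDefinition", msg, ...)
illegal_flag <- function(msg, ...) eq_abort("IllegalFlag", msg, ...)
cyclic_dependency <- function(msg, ...) eq_abort("CyclicDependency", msg, ...)
illegal_noise <- function(msg, ...) eq_abort("IllegalNoise", msg, ...)
assignment_to_constant <- function(msg, ...) eq_abort("AssignmentToConstant", msg, ...)
write_to_linked <- function(msg, ...) eq_abort("WriteToLinked", msg, ...)
name_collision <- function(msg, ...) eq_abort("NameCollision", msg, ...)
restore_without_store <- function(msg, ...) eq_abort("RestoreWithoutStore", msg, ...)
integration_error <- function(msg, ...) eq_abort("IntegrationError", msg, ...)
summed_collision <- function(msg, ...) eq_abort("Collision", msg, ...)
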