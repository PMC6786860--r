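# Loading group definitions from YAML/JSON configuration. A group entry
# uses the keys `N`, `model`, `threshold`, `reset`, `refractory`,
# `method`, `name` and `namespace`; namespace values given as strings are
# parsed as unit expressions ("20*ms"), bare numbers stay dimensionless.

#' Create a neuron group from a configuration list or YAML file
#'
#' @param config a named list, or a path to a YAML file containing one.
#' @return a `NeuronGroup`.
#' @examples
#' cfg <- list(N = 1, model = "dv/dt = -v/tau : volt",
#'             threshold = "v > -50*mV", reset = "v = -60*mV",
#'             namespace = list(tau = "10*ms"))
#' g <- group_from_config(cfg)
#' @export
group_from_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      eq_abort("eqspike_error", "the yaml package is required to read config files")
    config <- yaml::read_yaml(config)
  }
  ns <- lapply(config$namespace, function(v)
    if (is.character(v)) parse_unit_expression(v) else v)
  refr <- config$refractory
  if (is.character(refr)) refr <- parse_unit_expression(refr)
  create_group(N = config$N, model = config$model,
               threshold = config$threshold, reset = config$reset,
               refractory = refr, namespace = ns,
               method = config$method %||% "auto",
               name = config$name %||% "group")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
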