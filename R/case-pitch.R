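# Pitch-detection fixture: a stored waveform (standing in for live audio)
# drives an integrate-and-fire input cell with an adaptive threshold; its
# spike train reaches an array of coincidence-detector neurons through two
# pathways, one with no delay and one whose delay grows linearly with the
# detector index. A detector fires when spikes from the two pathways
# arrive (nearly) together, which happens most often when its delay
# difference matches the period of the input -- a spike-based
# autocorrelation estimate of pitch.

#' Constants of the pitch-detection fixture
#'
#' Input cell: drive gain 5, integration time constant 1 ms, adaptive
#' threshold resting at 1 with 0.1 per-spike increment decaying with a
#' 10 ms time constant, 1.5 ms refractory period. Detectors: 1 ms membrane
#' time constant, threshold 1.5, synaptic weight 1.0 per pathway (a single
#' pathway cannot fire a detector; two coincident ones can), delay step
#' 1 ms between consecutive detectors.
#' @return named list.
#' @export
pitch_constants <- function() {
  u <- parse_unit_expression
  list(gain = 5, tau_in = u("1*ms"),
       th0 = 1, th_inc = 0.1, tau_th = u("10*ms"),
       refractory_in = u("1.5*ms"),
       tau_d = u("1*ms"), det_threshold = 1.5, wd = 1.0,
       delay_step = u("1*ms"))
}

#' Generate a periodic pulse-train waveform
#'
#' Rectangular pulses of the given period: amplitude 1 during the first
#' `width` of each period, 0 otherwise.
#'
#' @param period pulse period (time quantity).
#' @param duration total duration.
#' @param sample_rate samples per second (bare numeric, default 40000).
#' @param width pulse width (default 1 ms).
#' @return list with `samples` (numeric vector in [0, 1]) and `sample_rate`.
#' @export
make_pulse_train <- function(period, duration, sample_rate = 40000,
                             width = parse_unit_expression("1*ms")) {
  tt <- seq(0, si_value(duration), by = 1 / sample_rate)
  phase <- tt %% si_value(period)
  list(samples = as.numeric(phase < si_value(width)), sample_rate = sample_rate)
}

#' Generate a synthetic tone sequence (rising C major arpeggio)
#'
#' A sum of a fundamental and two weaker harmonics for each tone, with the
#' default pitch sequence C4, E4, G4, C5. Stands in for a live audio
#' stream.
#'
#' @param freqs fundamental frequencies in Hz.
#' @param tone_duration duration of each tone.
#' @param sample_rate samples per second.
#' @return list with `samples` (normalized to peak 1) and `sample_rate`.
#' @export
make_tone_sequence <- function(freqs = c(261.63, 329.63, 392.00, 523.25),
                               tone_duration = parse_unit_expression("250*ms"),
                               sample_rate = 40000) {
  td <- si_value(tone_duration)
  out <- numeric()
  for (f in freqs) {
    tt <- seq(0, td - 1 / sample_rate, by = 1 / sample_rate)
    tone <- sin(2 * pi * f * tt) + 0.5 * sin(4 * pi * f * tt) + 0.25 * sin(6 * pi * f * tt)
    out <- c(out, tone)
  }
  list(samples = out / max(abs(out)), sample_rate = sample_rate)
}

#' Build the pitch-detection network
#'
#' @param waveform list with `samples` and `sample_rate`, e.g. from
#'   [make_pulse_train()] or [make_tone_sequence()].
#' @param n_detectors number of coincidence detectors; detector k (0-based
#'   j) listens for period (j+1) * delay_step.
#' @param dt timestep.
#' @return list with `network`, `input`, `detectors`, `pathways` (synapse
#'   population with pathways `direct` and `delayed`), `input_spikes`,
#'   `detector_spikes` and `constants`.
#' @export
build_pitch <- function(waveform, n_detectors = 10,
                        dt = parse_unit_expression("0.1*ms")) {
  k <- pitch_constants()
  samples <- waveform$samples
  stopifnot(all(is.finite(samples)))
  sr <- waveform$sample_rate
  sound_fn <- register_function("sound", local({
    w <- samples; rate <- sr
    function(t) {
      idx <- pmin(length(w), pmax(1, floor(t * rate) + 1))
      w[idx]
    }
  }), arg_dims = list(dimension(s = 1)), return_dim = dimension())

  input <- create_group(1, "
      dv/dt = (gain*sound(t) - v)/tau_in : 1
      dth/dt = (th0 - th)/tau_th : 1",
    threshold = "v > th", reset = "v = 0\nth += th_inc",
    refractory = k$refractory_in,
    namespace = c(k[c("gain", "tau_in", "th0", "th_inc", "tau_th")],
                  list(sound = sound_fn)),
    method = "exponential_euler", name = "pitch_input")
  set_state(input, "th", k$th0)

  det <- create_group(n_detectors, "dvd/dt = -vd/tau_d : 1",
                      threshold = "vd > det_threshold", reset = "vd = 0",
                      namespace = k[c("tau_d", "det_threshold")],
                      name = "pitch_detectors")

  paths <- create_synapses(input, det,
    on_pre = list(direct = "vd_post += wd", delayed = "vd_post += wd"),
    namespace = k["wd"], name = "pitch_pathways")
  connect(paths, condition = "i == 0")  # input cell to every detector
  set_synapse_state(paths, "delay",
                    sprintf("(j + 1)*%.17g*second", si_value(k$delay_step)),
                    pathway = "delayed")

  smi <- spike_monitor(input)
  smd <- spike_monitor(det)
  net <- create_network(input, det, paths, smi, smd, dt = dt)
  list(network = net, input = input, detectors = det, pathways = paths,
       input_spikes = smi, detector_spikes = smd, constants = k)
}

#' Run the pitch network on a waveform and return the detector raster
#'
#' @param waveform as in [build_pitch()].
#' @param duration how long to run (defaults to the waveform length).
#' @param n_detectors number of detectors.
#' @param dt timestep.
#' @return list as [build_pitch()] plus `raster` (data.frame t, detector)
#'   and `counts` (spikes per detector).
#' @export
run_pitch <- function(waveform, duration = NULL, n_detectors = 10,
                      dt = parse_unit_expression("0.1*ms")) {
  p <- build_pitch(waveform, n_detectors, dt)
  if (is.null(duration))
    duration <- quantity(length(waveform$samples) / waveform$sample_rate,
                         dimension(s = 1))
  run_network(p$network, duration)
  p$raster <- data.frame(t = p$detector_spikes$times(),
                         detector = p$detector_spikes$indices())
  p$counts <- p$detector_spikes$spike_counts()
  p
}

#' Preferred period of each detector
#' @param p result of [build_pitch()]/[run_pitch()].
#' @return time [quantity()]: delay difference of each detector.
#' @export
pitch_preferred_periods <- function(p) {
  quantity((seq_len(p$detectors$N)) * si_value(p$constants$delay_step),
           dimension(s = 1))
}
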