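#' Create a neuron state
#'
#' @param membrane_potential Initial membrane potential.
#' @param adaptation_current Initial adaptation current.
#' @param calcium Initial calcium trace (>= 0).
#' @param refractory_remaining Remaining refractory time (ms).
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(membrane_potential = 0, adaptation_current = 0,
                         calcium = 0, refractory_remaining = 0) {
  if (calcium < 0) stop("calcium must be >= 0")
  if (refractory_remaining < 0) stop("refractory_remaining must be >= 0")
  structure(list(membrane_potential = membrane_potential,
                 adaptation_current = adaptation_current,
                 calcium = calcium,
                 refractory_remaining = refractory_remaining),
            class = "neuron_state")
}

#' Advance one neuron by a single time step
#'
#' Reference (single-neuron) implementation of the integration scheme used by
#' the compiled network core: exponential-Euler leak integration when the
#' exponential spike-initiation term is disabled (`exponential_slope = 0`),
#' forward Euler with a guarded exponential term otherwise. During the
#' refractory period the membrane is clamped at the reset potential. On a
#' spike the membrane is reset, the refractory timer restarted, and the
#' adaptation and calcium traces incremented.
#'
#' @param state A [neuron_state()].
#' @param params A [neuron_params()].
#' @param input_current Total input current over this step.
#' @param dt Time step (ms), > 0.
#' @return A list with elements `state` (updated [neuron_state()]) and
#'   `spiked` (logical flag).
#' @examples
#' st <- neuron_state(membrane_potential = 0.5)
#' integrate_step(st, neuron_params(), input_current = 0, dt = 0.1)
#' @export
integrate_step <- function(state, params, input_current, dt) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "neuron_params"))
  if (dt <= 0) stop("dt must be > 0")
  if (!is.finite(input_current) ||
      !all(is.finite(unlist(state, use.names = FALSE))))
    stop("non-finite neuron state or input current (numerical blow-up; ",
         "reduce dt or input magnitudes)")

  v <- state$membrane_potential
  adapt <- state$adaptation_current
  ca <- state$calcium
  refr <- state$refractory_remaining
  spiked <- FALSE

  if (refr > 0) {
    refr <- refr - dt
    v <- params$reset_potential
  } else {
    I <- input_current - adapt
    slope <- params$exponential_slope
    if (slope > 0) {
      a <- min((v - params$spike_threshold) / slope, 20)
      v <- v + dt / params$membrane_time_constant *
        (-(v - params$resting_potential) + slope * exp(a) + I)
    } else {
      vinf <- params$resting_potential + I
      v <- vinf + (v - vinf) * exp(-dt / params$membrane_time_constant)
    }
    if (!is.finite(v))
      stop("membrane potential became non-finite (numerical blow-up; ",
           "dt is probably too large)")
    cutoff <- if (slope > 0) params$spike_threshold + 5 * slope else
      params$spike_threshold
    if (v >= cutoff) {
      spiked <- TRUE
      v <- params$reset_potential
      refr <- params$refractory_period
      adapt <- adapt + params$adaptation_increment
      ca <- ca + params$calcium_increment
    }
  }
  adapt <- adapt * exp(-dt / params$adaptation_time_constant)
  ca <- max(0, ca * exp(-dt / params$calcium_time_constant))

  list(state = neuron_state(v, adapt, ca, max(0, refr)), spiked = spiked)
}

#' Update the calcium trace of a neuron
#'
#' The calcium trace is a low-pass filter of the neuron's own spikes: it
#' decays exponentially with the calcium time constant and is incremented by
#' `calcium_increment` whenever the neuron spikes. At regular firing rate
#' `r` (spikes/ms) its steady state is
#' `calcium_increment * r * calcium_time_constant`.
#'
#' @param state A [neuron_state()].
#' @param params A [neuron_params()].
#' @param spiked Logical; did the neuron spike in this step?
#' @param dt Time step (ms), > 0.
#' @return The updated [neuron_state()].
#' @export
update_calcium <- function(state, params, spiked, dt) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "neuron_params"))
  if (dt <= 0) stop("dt must be > 0")
  ca <- state$calcium
  if (isTRUE(spiked)) ca <- ca + params$calcium_increment
  ca <- max(0, ca * exp(-dt / params$calcium_time_constant))
  neuron_state(state$membrane_potential, state$adaptation_current, ca,
               state$refractory_remaining)
}

#' Closed-form firing rate of a leaky integrate-and-fire neuron
#'
#' Steady firing rate (Hz) of a leaky integrate-and-fire neuron (exponential
#' term and adaptation disabled) under a constant suprathreshold current:
#' `1000 / (t_ref + tau * log((I - (V_thr - V_rest)) / (I - (V_reset - V_rest))))`.
#' Used as the independent oracle for the network integrator.
#'
#' @param params A [neuron_params()] with `exponential_slope = 0`.
#' @param input_current Constant input current (must be suprathreshold).
#' @return Firing rate in Hz.
#' @export
lif_rate_closed_form <- function(params, input_current) {
  stopifnot(inherits(params, "neuron_params"))
  dthr <- params$spike_threshold - params$resting_potential
  drst <- params$reset_potential - params$resting_potential
  if (input_current <= dthr) return(0)
  isi <- params$refractory_period +
    params$membrane_time_constant *
      log((input_current - drst) / (input_current - dthr))
  1000 / isi
}
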