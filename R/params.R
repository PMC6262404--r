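#' Neuron model parameters
#'
#' Parameters of the adaptive exponential integrate-and-fire neuron used for
#' every silicon-neuron analogue in a simulated network. Voltages and currents
#' are in arbitrary-but-consistent units (the resting-to-threshold distance is
#' 1 by default); only time is physical (milliseconds).
#'
#' The defaults are a documented reference set, tuned once so that the
#' serial-order stimulation protocol produces stable activity bumps and
#' persistent memory-group activity; they are not measurements of any
#' particular hardware device.
#'
#' @param membrane_time_constant Membrane leak time constant (ms).
#' @param resting_potential Resting (leak reversal) potential.
#' @param spike_threshold Spike threshold. With a positive
#'   `exponential_slope` this is the spike-initiation threshold of the
#'   exponential term and the numerical cutoff sits 5 slopes above it; with
#'   `exponential_slope = 0` the exponential term is disabled and this is the
#'   hard leaky-integrate-and-fire threshold.
#' @param exponential_slope Sharpness of spike initiation (voltage units);
#'   0 disables the exponential term.
#' @param reset_potential Post-spike reset potential; the membrane is clamped
#'   here throughout the refractory period.
#' @param refractory_period Absolute refractory period (ms).
#' @param adaptation_increment Spike-triggered adaptation current increment.
#' @param adaptation_time_constant Adaptation decay time constant (ms).
#' @param calcium_increment Per-spike increment of the calcium trace
#'   (dimensionless).
#' @param calcium_time_constant Calcium decay time constant (ms).
#' @return An object of class `neuron_params` (a validated named list).
#' @examples
#' p <- neuron_params()
#' p$membrane_time_constant
#' @export
neuron_params <- function(membrane_time_constant = 20,
                          resting_potential = 0,
                          spike_threshold = 1,
                          exponential_slope = 0,
                          reset_potential = 0,
                          refractory_period = 4,
                          adaptation_increment = 0,
                          adaptation_time_constant = 100,
                          calcium_increment = 0.1,
                          calcium_time_constant = 100) {
  p <- list(membrane_time_constant = membrane_time_constant,
            resting_potential = resting_potential,
            spike_threshold = spike_threshold,
            exponential_slope = exponential_slope,
            reset_potential = reset_potential,
            refractory_period = refractory_period,
            adaptation_increment = adaptation_increment,
            adaptation_time_constant = adaptation_time_constant,
            calcium_increment = calcium_increment,
            calcium_time_constant = calcium_time_constant)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("neuron parameter '", nm, "' must be a single finite number")
  }
  if (membrane_time_constant <= 0 || adaptation_time_constant <= 0 ||
      calcium_time_constant <= 0)
    stop("all neuron time constants must be > 0")
  if (refractory_period < 0) stop("refractory_period must be >= 0")
  if (spike_threshold <= reset_potential)
    stop("spike_threshold must be greater than reset_potential")
  if (exponential_slope < 0) stop("exponential_slope must be >= 0")
  structure(p, class = "neuron_params")
}

# Column order must match enum NP in src/core.cpp.
neuron_param_names <- c("membrane_time_constant", "resting_potential",
                        "spike_threshold", "exponential_slope",
                        "reset_potential", "refractory_period",
                        "adaptation_increment", "adaptation_time_constant",
                        "calcium_increment", "calcium_time_constant")

#' Expand neuron parameters to a per-neuron matrix, with optional mismatch
#'
#' Fabrication mismatch of analog neurons is emulated as multiplicative
#' Gaussian jitter on every parameter except the resting and reset potentials
#' and thresholds' ordering-critical entries; jitter is applied to time
#' constants, increments and the threshold distance.
#'
#' @param params A [neuron_params()] object.
#' @param n Number of neurons.
#' @param mismatch_sigma Fractional standard deviation of the jitter
#'   (0 = identical neurons; draws use the current RNG state).
#' @return An `n x 10` numeric matrix, one row per neuron.
#' @keywords internal
neuron_param_matrix <- function(params, n, mismatch_sigma = 0) {
  stopifnot(inherits(params, "neuron_params"), n >= 0)
  base <- unlist(params[neuron_param_names])
  m <- matrix(rep(base, each = n), nrow = n, ncol = length(base),
              dimnames = list(NULL, neuron_param_names))
  if (n > 0 && mismatch_sigma > 0) {
    jitter_cols <- c("membrane_time_constant", "refractory_period",
                     "adaptation_increment", "adaptation_time_constant",
                     "calcium_increment", "calcium_time_constant")
    for (cn in jitter_cols) {
      f <- pmax(0.2, 1 + stats::rnorm(n, 0, mismatch_sigma))
      m[, cn] <- m[, cn] * f
    }
    # jitter the rest-to-threshold distance, keeping threshold > reset
    d <- m[, "spike_threshold"] - m[, "resting_potential"]
    f <- pmax(0.2, 1 + stats::rnorm(n, 0, mismatch_sigma))
    m[, "spike_threshold"] <- m[, "resting_potential"] + d * f
  }
  m
}

#' Plasticity rule parameters
#'
#' Thresholds and amplitudes of the calcium- and voltage-gated bistable
#' plasticity rule. On each presynaptic spike the synapse is potentiated by
#' `delta_w_plus` if the postsynaptic membrane potential exceeds `theta_mem`
#' and the postsynaptic calcium trace lies strictly inside
#' (`theta1`, `theta_max`); it is depressed by `delta_w_minus` if the membrane
#' potential is below `theta_mem` and the calcium trace lies in
#' [`theta1_ltd`, `theta_max`). Independently of spiking, the weight drifts at
#' constant rate `c_drift` toward `w_max` when above `theta_w` and toward
#' `w_min` when below, making the synapse binary in the long term.
#'
#' The depression gate has its own lower calcium bound `theta1_ltd`
#' (default 0), so that a completely silent postsynaptic neuron is still
#' slowly forgotten by presynaptic activity; setting
#' `theta1_ltd = theta1` recovers a shared calcium window for both branches.
#'
#' @param theta_mem Membrane-potential threshold separating the potentiation
#'   and depression branches.
#' @param theta1 Lower calcium bound of the potentiation gate (exclusive).
#' @param theta_max Upper calcium bound of both gates (exclusive).
#' @param delta_w_plus Potentiation amplitude per eligible presynaptic spike.
#' @param delta_w_minus Depression amplitude per eligible presynaptic spike.
#' @param c_drift Bistable drift rate (weight units per ms).
#' @param theta_w Weight threshold deciding the drift direction.
#' @param w_min,w_max Weight rails; weights are clamped to `[w_min, w_max]`.
#' @param theta1_ltd Lower calcium bound of the depression gate (inclusive).
#' @return An object of class `plasticity_params`.
#' @examples
#' pp <- plasticity_params()
#' plastic_update_on_pre(0.2, v_post = 0.8, ca_post = 1, params = pp)
#' @export
plasticity_params <- function(theta_mem = 0.3,
                              theta1 = 0.3,
                              theta_max = 6,
                              delta_w_plus = 0.12,
                              delta_w_minus = 0.04,
                              c_drift = 2e-5,
                              theta_w = 0.5,
                              w_min = 0,
                              w_max = 1,
                              theta1_ltd = 0) {
  p <- list(theta_mem = theta_mem, theta1 = theta1, theta_max = theta_max,
            delta_w_plus = delta_w_plus, delta_w_minus = delta_w_minus,
            c_drift = c_drift, theta_w = theta_w,
            w_min = w_min, w_max = w_max, theta1_ltd = theta1_ltd)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("plasticity parameter '", nm, "' must be a single finite number")
  }
  if (!(w_min < theta_w && theta_w < w_max))
    stop("w_min < theta_w < w_max is required")
  if (delta_w_plus <= 0 || delta_w_minus <= 0)
    stop("delta_w_plus and delta_w_minus must be > 0")
  if (theta1 >= theta_max) stop("theta1 must be < theta_max")
  if (c_drift < 0) stop("c_drift must be >= 0")
  structure(p, class = "plasticity_params")
}

plast_par_vector <- function(p) {
  stopifnot(inherits(p, "plasticity_params"))
  c(p$theta_mem, p$theta1, p$theta_max, p$delta_w_plus, p$delta_w_minus,
    p$c_drift, p$theta_w, p$w_min, p$w_max, p$theta1_ltd)
}

#' Simulation configuration
#'
#' @param dt Integration time step (ms). 0.1 ms resolves 800 Hz inputs and
#'   the default refractory period; closed-form comparisons use finer steps.
#' @param duration Simulated time (ms).
#' @param seed Integer RNG seed; every source of randomness in a run is
#'   derived from it.
#' @param mismatch_sigma Fractional per-neuron parameter jitter emulating
#'   device mismatch (0 = identical neurons).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, duration = 1000, seed = 1L,
                       mismatch_sigma = 0) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.numeric(duration) || duration < dt)
    stop("duration must be >= dt")
  if (mismatch_sigma < 0) stop("mismatch_sigma must be >= 0")
  structure(list(dt = dt, duration = duration, seed = as.integer(seed),
                 mismatch_sigma = mismatch_sigma),
            class = "sim_config")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("<plasticity_params>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}
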