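#' Table of discrete static synaptic weight levels
#'
#' Non-plastic synapses draw their efficacies from a small set of programmable
#' levels, mimicking hardware with a fixed number of on-chip weights: exactly
#' four ordered excitatory levels and a few inhibitory levels. All synapses
#' (static, plastic and virtual input synapses) share one postsynaptic-current
#' time constant; each delivered spike adds its weight to the target's input
#' current, which then decays exponentially.
#'
#' @param excitatory_levels Four strictly increasing positive weights.
#' @param inhibitory_levels Ordered negative weights (any number >= 1).
#' @param psc_time_constant Postsynaptic-current decay time constant (ms).
#' @return An object of class `static_weight_table`.
#' @export
static_weight_table <- function(excitatory_levels = c(0.03, 0.05, 0.12, 0.2),
                                inhibitory_levels = c(-0.15, -0.06, -0.015),
                                psc_time_constant = 20) {
  if (length(excitatory_levels) != 4L)
    stop("exactly 4 excitatory weight levels are available")
  if (any(excitatory_levels <= 0) || any(diff(excitatory_levels) <= 0))
    stop("excitatory levels must be positive and strictly increasing")
  if (any(inhibitory_levels >= 0))
    stop("inhibitory levels must be negative")
  if (psc_time_constant <= 0) stop("psc_time_constant must be > 0")
  structure(list(excitatory_levels = excitatory_levels,
                 inhibitory_levels = inhibitory_levels,
                 psc_time_constant = psc_time_constant),
            class = "static_weight_table")
}

#' Check that a static matrix only uses table levels
#'
#' Every nonzero entry of a static connectivity matrix must equal one of the
#' excitatory or inhibitory levels of its weight table.
#'
#' @param w Numeric matrix of static weights.
#' @param table A [static_weight_table()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_static_levels <- function(w, table) {
  lv <- c(0, table$excitatory_levels, table$inhibitory_levels)
  bad <- !(w %in% lv)
  if (any(bad))
    stop(sum(bad), " static weight entries are not levels of the weight table")
  invisible(TRUE)
}

#' Postsynaptic currents from a volley of spikes
#'
#' Reference implementation of linear spike delivery: the instantaneous
#' per-neuron input current contributed by a set of presynaptic spikes through
#' a weight matrix. Currents superpose linearly; each spike contributes its
#' synapse's weight (times the plastic gain for plastic matrices).
#'
#' @param spikes Integer vector of presynaptic neuron indices (0-based; may
#'   contain repeats for simultaneous spikes).
#' @param matrix Numeric weight matrix, rows = presynaptic neurons.
#' @param gain Scalar multiplier applied to the weights (used for plastic
#'   matrices, whose analog weight is scaled into current units).
#' @return Numeric vector of per-neuron injected current (length `ncol(matrix)`).
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- 0.5
#' deliver_spikes(c(0L, 0L), w)  # two simultaneous spikes: doubled current
#' @export
deliver_spikes <- function(spikes, matrix, gain = 1) {
  spikes <- as.integer(spikes)
  if (length(spikes) == 0) return(numeric(ncol(matrix)))
  if (any(spikes < 0 | spikes >= nrow(matrix)))
    stop("spike index out of range for the synapse matrix")
  out <- numeric(ncol(matrix))
  for (s in spikes) out <- out + matrix[s + 1L, ] * gain
  out
}

#' Event-driven plastic weight update at a presynaptic spike
#'
#' Applies the calcium- and voltage-gated rule at the arrival time of one
#' presynaptic spike: potentiate by `delta_w_plus` if the postsynaptic
#' membrane potential is above `theta_mem` and the postsynaptic calcium trace
#' is strictly inside (`theta1`, `theta_max`); depress by `delta_w_minus` if
#' the membrane potential is below `theta_mem` and the calcium trace is in
#' [`theta1_ltd`, `theta_max`); otherwise leave the weight unchanged. The
#' result is clamped to [`w_min`, `w_max`].
#'
#' @param w Current analog weight (scalar or vector).
#' @param v_post Postsynaptic membrane potential at spike arrival.
#' @param ca_post Postsynaptic calcium trace at spike arrival.
#' @param params A [plasticity_params()].
#' @return Updated weight(s), clamped to the rails.
#' @export
plastic_update_on_pre <- function(w, v_post, ca_post, params) {
  stopifnot(inherits(params, "plasticity_params"))
  up <- v_post > params$theta_mem &
    ca_post > params$theta1 & ca_post < params$theta_max
  down <- v_post < params$theta_mem &
    ca_post >= params$theta1_ltd & ca_post < params$theta_max
  w2 <- w + ifelse(up, params$delta_w_plus,
                   ifelse(down, -params$delta_w_minus, 0))
  pmin(params$w_max, pmax(params$w_min, w2))
}

#' Bistable drift of a plastic weight over one time step
#'
#' Weights above `theta_w` drift up at rate `c_drift` (capped at `w_max`);
#' weights below drift down (floored at `w_min`); a weight exactly at
#' `theta_w` does not move (strict inequalities). Applied independently of
#' spiking, the drift makes every weight binary in the long term.
#'
#' @param w Current weight (scalar or vector).
#' @param dt Elapsed time (ms), > 0. Because the rate is constant and the
#'   direction cannot flip, a single call with a long `dt` equals repeated
#'   small steps.
#' @param params A [plasticity_params()].
#' @return Updated weight(s).
#' @export
drift_step <- function(w, dt, params) {
  stopifnot(inherits(params, "plasticity_params"))
  if (dt <= 0) stop("dt must be > 0")
  up <- w > params$theta_w
  down <- w < params$theta_w
  w2 <- w
  w2[up] <- pmin(params$w_max, w[up] + params$c_drift * dt)
  w2[down] <- pmax(params$w_min, w[down] - params$c_drift * dt)
  w2
}

#' Initialize the plastic synapse matrix of a serial-order network
#'
#' The ordinal-to-content block starts fully depressed (all weights at
#' `w_min`); the recurrent within-ordinal and within-memory blocks receive a
#' given fraction of randomly potentiated entries (at `w_max`) that strengthen
#' self-excitation but are frozen: they transmit current yet do not
#' participate in learning or drift.
#'
#' @param layout A [population_layout()].
#' @param recurrent_potentiated_fraction Fraction in [0, 1] of recurrent
#'   entries set to `w_max` (default 0.3).
#' @param params A [plasticity_params()].
#' @param gain Current injected per presynaptic spike and unit weight.
#' @param seed Optional integer seed for the random potentiated entries.
#' @return An object of class `plastic_matrix`: list with numeric matrix `w`,
#'   integer matrices `exists` and `learn`, scalar `gain`, `params`, and
#'   logical `enabled`.
#' @export
initialize_plastic_matrix <- function(layout,
                                      recurrent_potentiated_fraction = 0.3,
                                      params = plasticity_params(),
                                      gain = 0.06,
                                      seed = NULL) {
  stopifnot(inherits(layout, "population_layout"))
  f <- recurrent_potentiated_fraction
  if (!is.numeric(f) || f < 0 || f > 1)
    stop("recurrent_potentiated_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- n_neurons(layout)
  w <- matrix(0, n, n)
  exists <- matrix(0L, n, n)
  learn <- matrix(0L, n, n)

  content <- layout_range(layout, "content_exc")
  # frozen potentiated recurrent entries: round(f * m^2) random cells of each
  # within-ordinal and within-memory block, existing but non-learning
  mark_recurrent <- function(idx) {
    m <- length(idx)
    n_pot <- round(f * m * m)
    if (n_pot == 0) return(invisible(NULL))
    pick <- sample.int(m * m, n_pot)
    pre <- idx[(pick - 1L) %% m + 1L] + 1L
    post <- idx[(pick - 1L) %/% m + 1L] + 1L
    cells <- cbind(pre, post)
    w[cells] <<- params$w_max
    exists[cells] <<- 1L
    learn[cells] <<- 0L
    invisible(NULL)
  }
  for (k in ordinal_groups(layout)) {
    ord <- layout_range(layout, "ordinal", k)
    # learnable ordinal -> content block, fully depressed at start
    exists[ord + 1L, content + 1L] <- 1L
    learn[ord + 1L, content + 1L] <- 1L
    w[ord + 1L, content + 1L] <- params$w_min
    mark_recurrent(ord)
    mark_recurrent(layout_range(layout, "memory", k))
  }
  structure(list(w = w, exists = exists, learn = learn, gain = gain,
                 params = params, enabled = TRUE),
            class = "plastic_matrix")
}

#' @export
print.plastic_matrix <- function(x, ...) {
  cat("<plastic_matrix> ", nrow(x$w), "x", ncol(x$w),
      " | existing synapses:", sum(x$exists),
      " (learnable:", sum(x$learn), ")\n", sep = "")
  cat("  weights in [", x$params$w_min, ", ", x$params$w_max,
      "], gain ", x$gain, ", plasticity ",
      if (x$enabled) "enabled" else "disabled", "\n", sep = "")
  invisible(x)
}
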