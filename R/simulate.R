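#' Stimulus epoch
#'
#' One episode of external Poisson drive delivered through virtual input
#' synapses: a set of target neurons, a spatial rate profile, a time window
#' and a per-spike synaptic weight. Profiles:
#' \describe{
#'   \item{constant}{every target receives rate `rate` (Hz).}
#'   \item{gaussian}{target `j` (absolute index) receives
#'     `peak * exp(-(j - center)^2 / (2 sigma^2))` Hz.}
#'   \item{uniform_background}{each target receives an independent rate drawn
#'     uniformly from `[0, max_rate]` Hz, drawn once per epoch and then held
#'     (draws use the simulation seed).}
#' }
#'
#' @param targets Integer vector of 0-based target neuron indices.
#' @param profile `"constant"`, `"gaussian"` or `"uniform_background"`.
#' @param rate Constant rate (Hz), for the constant profile.
#' @param center,sigma,peak Gaussian profile parameters (center and sigma in
#'   neuron index units, peak in Hz).
#' @param max_rate Upper bound (Hz) of the uniform background profile.
#' @param start,duration Time window (ms).
#' @param weight Input current injected per external spike.
#' @return An object of class `stimulus_epoch`.
#' @export
stimulus_epoch <- function(targets,
                           profile = c("constant", "gaussian",
                                       "uniform_background"),
                           rate = NULL, center = NULL, sigma = NULL,
                           peak = NULL, max_rate = NULL,
                           start = 0, duration = 1000, weight = 1) {
  profile <- match.arg(profile)
  targets <- as.integer(targets)
  if (any(targets < 0)) stop("targets must be 0-based non-negative indices")
  if (start < 0 || duration <= 0) stop("epoch window must be non-negative")
  rates_spec <- switch(profile,
    constant = {
      if (is.null(rate) || rate < 0) stop("constant profile needs rate >= 0")
      list(rate = rate)
    },
    gaussian = {
      if (is.null(peak) || is.null(center) || is.null(sigma) ||
          peak < 0 || sigma <= 0)
        stop("gaussian profile needs peak >= 0, center, sigma > 0")
      list(peak = peak, center = center, sigma = sigma)
    },
    uniform_background = {
      if (is.null(max_rate) || max_rate < 0)
        stop("uniform_background profile needs max_rate >= 0")
      list(max_rate = max_rate)
    })
  structure(c(list(targets = targets, profile = profile,
                   start = start, duration = duration, weight = weight),
              rates_spec),
            class = "stimulus_epoch")
}

# Realize the per-target rate vector (Hz) of an epoch. Uses the current RNG
# state for the uniform background profile.
realize_rates <- function(epoch) {
  switch(epoch$profile,
    constant = rep(epoch$rate, length(epoch$targets)),
    gaussian = epoch$peak *
      exp(-(epoch$targets - epoch$center)^2 / (2 * epoch$sigma^2)),
    uniform_background = stats::runif(length(epoch$targets), 0,
                                      epoch$max_rate))
}

#' Generate the external Poisson spike drive of an epoch
#'
#' Realizes an epoch's rate profile and draws per-neuron, per-step Poisson
#' spike counts, as the simulation core does internally. Intended for
#' inspection and testing at small scale (the full matrix is targets x steps).
#'
#' @param epoch A [stimulus_epoch()].
#' @param dt Time step (ms).
#' @param seed Integer seed.
#' @return A list with `rates` (Hz per target) and `counts` (integer matrix,
#'   targets x steps over the epoch's own duration).
#' @export
make_poisson_input <- function(epoch, dt, seed = 1L) {
  stopifnot(inherits(epoch, "stimulus_epoch"))
  if (dt <= 0) stop("dt must be > 0")
  set.seed(seed)
  rates <- realize_rates(epoch)
  n_steps <- ceiling(epoch$duration / dt)
  lam <- rates * dt / 1000
  counts <- matrix(stats::rpois(length(rates) * n_steps, lam),
                   nrow = length(rates))
  list(rates = rates, counts = counts)
}

#' Construct a spike raster
#'
#' @param times Numeric spike times (ms), non-decreasing.
#' @param neurons Integer 0-based neuron indices.
#' @param n_neurons Network size.
#' @param duration Covered time span (ms).
#' @param layout Optional [population_layout()] carried as an attribute.
#' @return An object of class `spike_raster` (data.frame with columns
#'   `time`, `neuron`).
#' @export
spike_raster <- function(times, neurons, n_neurons, duration, layout = NULL) {
  if (length(times) != length(neurons))
    stop("times and neurons must have equal length")
  if (is.unsorted(times)) stop("spike times must be non-decreasing")
  neurons <- as.integer(neurons)
  if (length(neurons) && (min(neurons) < 0 || max(neurons) >= n_neurons))
    stop("neuron indices must lie in [0, n_neurons)")
  structure(data.frame(time = as.numeric(times), neuron = neurons),
            class = c("spike_raster", "data.frame"),
            n_neurons = as.integer(n_neurons),
            duration = as.numeric(duration),
            layout = layout)
}

#' @export
print.spike_raster <- function(x, ...) {
  cat("<spike_raster> ", nrow(x), " spikes, ", attr(x, "n_neurons"),
      " neurons, ", attr(x, "duration"), " ms\n", sep = "")
  invisible(x)
}

#' Mean firing rate of a set of neurons in a time window
#'
#' @param raster A [spike_raster()].
#' @param neurons Integer vector of 0-based neuron indices.
#' @param from,to Time window (ms); defaults to the whole raster.
#' @return Mean rate in Hz per neuron.
#' @export
mean_rate <- function(raster, neurons, from = 0,
                      to = attr(raster, "duration")) {
  sel <- raster$neuron %in% neurons & raster$time >= from & raster$time < to
  sum(sel) / length(neurons) / (to - from) * 1000
}

#' Wrap a bare connectivity matrix as a simulatable network
#'
#' Convenience for simulating an isolated population (e.g. one WTA field)
#' without the serial-order scaffolding.
#'
#' @param static_w Square numeric weight matrix.
#' @param neuron A [neuron_params()].
#' @param psc_time_constant Postsynaptic-current time constant (ms).
#' @param layout Optional [population_layout()].
#' @return An `snn_network` without plastic synapses.
#' @export
simple_network <- function(static_w, neuron = neuron_params(),
                           psc_time_constant = 5, layout = NULL) {
  if (is.null(layout))
    layout <- population_layout(c(field = nrow(static_w)))
  structure(list(layout = layout, static_w = static_w, plastic = NULL,
                 weight_table = static_weight_table(
                   psc_time_constant = psc_time_constant),
                 neuron = neuron, config = NULL),
            class = "snn_network")
}

#' Run a network simulation
#'
#' Clock-driven integration of a network under a set of stimulus epochs and
#' optional explicit external spike events. Deterministic given
#' (`config$seed`, inputs): identical calls produce bit-identical rasters.
#' Spikes are transmitted with a one-step delay. Plastic weights evolve under
#' the gated update rule (if plasticity is enabled) and the bistable drift;
#' the input network is not modified — the returned copy carries the final
#' weights.
#'
#' @param network An `snn_network`.
#' @param stimuli List of [stimulus_epoch()] objects.
#' @param config A [sim_config()].
#' @param ext_events Optional data.frame with columns `time`, `neuron`
#'   (0-based), `weight`: explicit external input spikes (e.g. from an event
#'   camera), sorted by time.
#' @param initial_state Optional numeric matrix (n x 5: membrane potential,
#'   adaptation, calcium, refractory, synaptic current) to resume from.
#' @param record Record spikes? (Disable for state-only runs.)
#' @param plasticity Override the network's plasticity-enabled flag.
#' @param drift Apply the bistable drift (default TRUE).
#' @return An object of class `sim_result`: list with `raster`
#'   ([spike_raster()]), `state` (final n x 5 matrix) and `network` (input
#'   network carrying the final plastic weights).
#' @examples
#' cfg <- wta_config(excitatory_radius = 1)
#' net <- simple_network(build_wta_lateral(8, cfg))
#' res <- run_simulation(net, list(
#'   stimulus_epoch(0:7, "constant", rate = 50, duration = 200, weight = 1)),
#'   sim_config(dt = 0.1, duration = 200, seed = 1))
#' nrow(res$raster)
#' @export
run_simulation <- function(network, stimuli = list(),
                           config = sim_config(),
                           ext_events = NULL, initial_state = NULL,
                           record = TRUE, plasticity = NULL, drift = TRUE) {
  stopifnot(inherits(network, "snn_network"), inherits(config, "sim_config"))
  n <- n_neurons(network$layout)
  if (nrow(network$static_w) != n || ncol(network$static_w) != n)
    stop("static weight matrix (", nrow(network$static_w), "x",
         ncol(network$static_w), ") does not match the layout (", n,
         " neurons)")
  set.seed(config$seed)
  nparams <- neuron_param_matrix(network$neuron, n, config$mismatch_sigma)

  epochs <- lapply(stimuli, function(ep) {
    stopifnot(inherits(ep, "stimulus_epoch"))
    if (length(ep$targets) && max(ep$targets) >= n)
      stop("stimulus epoch targets neuron ", max(ep$targets),
           " outside the network (size ", n, ")")
    if (ep$start + ep$duration > config$duration + 1e-9)
      stop("stimulus epoch [", ep$start, ", ", ep$start + ep$duration,
           "] exceeds the simulation duration ", config$duration, " ms")
    rates <- realize_rates(ep)
    if (any(rates < 0)) stop("negative stimulus rate")
    list(targets = ep$targets, rates = rates,
         start = ep$start, duration = ep$duration, weight = ep$weight)
  })

  if (is.null(ext_events)) {
    ev_t <- numeric(0); ev_n <- integer(0); ev_w <- numeric(0)
  } else {
    if (is.unsorted(ext_events$time))
      ext_events <- ext_events[order(ext_events$time), ]
    ev_t <- as.numeric(ext_events$time)
    ev_n <- as.integer(ext_events$neuron)
    ev_w <- as.numeric(ext_events$weight)
  }

  if (is.null(initial_state)) initial_state <- matrix(0, n, 5)

  has_plastic <- !is.null(network$plastic)
  if (has_plastic) {
    pl <- network$plastic
    w_copy <- pl$w * 1  # explicit copy: the core mutates it in place
    exists <- pl$exists; learn <- pl$learn
    gain <- pl$gain
    ppar <- plast_par_vector(pl$params)
    plast_on <- if (is.null(plasticity)) pl$enabled else plasticity
  } else {
    w_copy <- matrix(0, 0, 0); exists <- matrix(0L, 0, 0)
    learn <- matrix(0L, 0, 0); gain <- 0; ppar <- numeric(10)
    plast_on <- FALSE
  }

  out <- sm_run_core(n, nparams, initial_state, network$static_w,
                     has_plastic, w_copy, exists, learn, gain, ppar,
                     plast_on, drift, epochs, ev_t, ev_n, ev_w,
                     numeric(n),
                     network$weight_table$psc_time_constant,
                     config$dt, config$duration, record)

  raster <- spike_raster(out$times, out$neurons, n, config$duration,
                         layout = network$layout)
  net_out <- network
  if (has_plastic) net_out$plastic$w <- out$plastic_w
  colnames(out$state) <- c("membrane_potential", "adaptation_current",
                           "calcium", "refractory_remaining",
                           "synaptic_current")
  structure(list(raster = raster, state = out$state, network = net_out),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  print(x$raster)
  invisible(x)
}

# Derive a reproducible sub-seed for a named phase of a protocol.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt) %% 2147483629)
}
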