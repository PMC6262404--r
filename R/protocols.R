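#' Teaching protocol parameters
#'
#' Stimulation schedule for teaching a sequence of items: the sequence is
#' launched by a "go" input to the first ordinal group (3000 ms at 200 Hz);
#' each item is presented to the content field for 6000 ms as Poisson trains
#' with a Gaussian spatial rate profile (peak 900 Hz, sigma 5 neurons);
#' transitions are triggered by stimulating the condition-of-satisfaction
#' (CoS) group for 500 ms at 800 Hz after each item; all content neurons also
#' receive uniform background noise in [0, 10] Hz; after the last item the
#' reset group is stimulated, silencing the memory groups.
#'
#' @param go_duration,go_rate Go-signal duration (ms) and rate (Hz).
#' @param cos_duration,cos_rate CoS trigger duration (ms) and rate (Hz).
#' @param item_duration Presentation time per item (ms).
#' @param item_peak Peak rate (Hz) of the Gaussian item input.
#' @param sigma Spatial standard deviation (neurons) of the item input;
#'   `NULL` uses the network's configured sigma.
#' @param noise_max Upper bound (Hz) of the uniform background noise.
#' @param settle Pause (ms) between a CoS trigger and the next item, giving
#'   the next ordinal group time to ignite.
#' @param reset_duration,reset_rate Reset epoch after the last item.
#' @param go_weight,cos_weight,item_weight,noise_weight,reset_weight Input
#'   current per external spike for each signal path (virtual synapses).
#' @return An object of class `teaching_protocol`.
#' @export
teaching_protocol <- function(go_duration = 3000, go_rate = 200,
                              cos_duration = 500, cos_rate = 800,
                              item_duration = 6000, item_peak = 900,
                              sigma = NULL, noise_max = 10,
                              settle = 500,
                              reset_duration = 1000, reset_rate = 400,
                              go_weight = 0.5, cos_weight = 0.4,
                              item_weight = 0.6, noise_weight = 0.5,
                              reset_weight = 0.5) {
  structure(list(go_duration = go_duration, go_rate = go_rate,
                 cos_duration = cos_duration, cos_rate = cos_rate,
                 item_duration = item_duration, item_peak = item_peak,
                 sigma = sigma, noise_max = noise_max, settle = settle,
                 reset_duration = reset_duration, reset_rate = reset_rate,
                 go_weight = go_weight, cos_weight = cos_weight,
                 item_weight = item_weight, noise_weight = noise_weight,
                 reset_weight = reset_weight),
            class = "teaching_protocol")
}

# Build the epoch list and timing table of a teaching run.
teaching_epochs <- function(network, items, protocol) {
  cfg <- network$config
  lay <- network$layout
  sigma <- if (is.null(protocol$sigma)) cfg$sigma else protocol$sigma
  K <- length(items)
  cycle <- protocol$item_duration + protocol$cos_duration + protocol$settle
  content <- layout_range(lay, "content_exc")
  epochs <- list(
    stimulus_epoch(layout_range(lay, "ordinal", 1), "constant",
                   rate = protocol$go_rate, start = 0,
                   duration = protocol$go_duration,
                   weight = protocol$go_weight))
  item_windows <- data.frame(item = items,
                             start = (seq_len(K) - 1) * cycle,
                             end = (seq_len(K) - 1) * cycle +
                               protocol$item_duration)
  for (k in seq_len(K)) {
    center <- item_center(network, items[k])
    epochs[[length(epochs) + 1L]] <-
      stimulus_epoch(content, "gaussian", peak = protocol$item_peak,
                     center = center, sigma = sigma,
                     start = item_windows$start[k],
                     duration = protocol$item_duration,
                     weight = protocol$item_weight)
    epochs[[length(epochs) + 1L]] <-
      stimulus_epoch(layout_range(lay, "cos"), "constant",
                     rate = protocol$cos_rate,
                     start = item_windows$end[k],
                     duration = protocol$cos_duration,
                     weight = protocol$cos_weight)
  }
  # overlap the reset with the final CoS trigger: the memory groups must be
  # gone before the CoS releases the ordinal groups, or a stale memory group
  # would re-ignite its successor
  reset_start <- (K - 1) * cycle + protocol$item_duration
  epochs[[length(epochs) + 1L]] <-
    stimulus_epoch(layout_range(lay, "reset"), "constant",
                   rate = protocol$reset_rate, start = reset_start,
                   duration = protocol$reset_duration,
                   weight = protocol$reset_weight)
  duration <- reset_start + protocol$reset_duration + 500
  if (protocol$noise_max > 0)
    epochs[[length(epochs) + 1L]] <-
      stimulus_epoch(content, "uniform_background",
                     max_rate = protocol$noise_max, start = 0,
                     duration = duration, weight = protocol$noise_weight)
  list(epochs = epochs, duration = duration, item_windows = item_windows,
       reset_start = reset_start)
}

#' Teach a sequence of items
#'
#' Runs the full teaching protocol: go signal, per-item Gaussian content
#' input, CoS transition triggers, background noise, and a final reset of the
#' memory groups. Plasticity is enabled; the ordinal group active during each
#' item becomes associated with the stimulated content region.
#'
#' @param network An `snn_network` built by [build_serial_order()] (freshly
#'   initialized, or previously taught when overwriting a sequence).
#' @param items Character vector of item labels (e.g. `c("A", "B", "C")`);
#'   repeats are allowed.
#' @param protocol A [teaching_protocol()].
#' @param seed Integer seed.
#' @param dt Time step (ms).
#' @param mismatch_sigma Per-neuron parameter jitter.
#' @param check Diagnose protocol failures (no ordinal group active during an
#'   item) and raise an error naming the phase and time.
#' @return An object of class `teaching_result`: list with `network` (trained),
#'   `raster`, `item_windows`, `protocol`, `duration`.
#' @export
run_teaching <- function(network, items, protocol = teaching_protocol(),
                         seed = 1L, dt = 0.1, mismatch_sigma = 0.1,
                         check = TRUE) {
  stopifnot(inherits(network, "snn_network"),
            !is.null(network$plastic))
  if (!all(items %in% network$config$item_labels))
    stop("unknown item label(s): ",
         paste(setdiff(items, network$config$item_labels), collapse = ", "))
  sched <- teaching_epochs(network, items, protocol)
  config <- sim_config(dt = dt, duration = sched$duration, seed = seed,
                       mismatch_sigma = mismatch_sigma)
  res <- run_simulation(network, sched$epochs, config, plasticity = TRUE)

  if (check) {
    for (k in seq_along(items)) {
      w0 <- sched$item_windows$start[k] + 1000  # after ignition
      w1 <- sched$item_windows$end[k]
      rates <- vapply(ordinal_groups(network$layout), function(g)
        mean_rate(res$raster, layout_range(network$layout, "ordinal", g),
                  w0, w1), numeric(1))
      if (max(rates) < 20)
        stop("protocol failure: no ordinal group active during item ", k,
             " ('", items[k], "', ", w0, "-", w1, " ms); max group rate ",
             round(max(rates), 1), " Hz")
    }
  }
  structure(list(network = res$network, raster = res$raster,
                 item_windows = sched$item_windows, protocol = protocol,
                 duration = sched$duration),
            class = "teaching_result")
}

#' Replay a previously taught sequence
#'
#' The recall is triggered by a go signal to the first ordinal group; the
#' content field receives no external stimulation — its activity is driven
#' solely through the potentiated plastic synapses from the active ordinal
#' group. Transitions are triggered by CoS stimulations at the given onset
#' times, which may be irregularly spaced (flexible timing). The decoded item
#' sequence is recovered from the content raster; an epoch in which no
#' content bump forms is flagged as a recall failure in the result (not an
#' error).
#'
#' @param network A previously taught `snn_network` (memory groups are
#'   assumed reset; the run starts from silent initial states).
#' @param cos_onsets Numeric vector of CoS trigger onset times (ms). Default:
#'   one trigger per taught position, spaced 4000 ms.
#' @param protocol A [teaching_protocol()] (go and CoS parameters are
#'   reused during replay).
#' @param seed,dt,mismatch_sigma As in [run_teaching()].
#' @param rate_threshold,window Bump detection parameters (Hz, ms), see
#'   [detect_bumps()].
#' @return An object of class `replay_result`: list with `raster`, `decoded`
#'   (data.frame from [decode_sequence()]), `sequence` (character vector of
#'   decoded labels, `NA` for failed epochs), `epochs` (data.frame with
#'   per-epoch windows and success flags), `network`.
#' @export
run_replay <- function(network, cos_onsets = NULL,
                       protocol = teaching_protocol(), seed = 1L, dt = 0.1,
                       mismatch_sigma = 0.1, rate_threshold = 40,
                       window = 100) {
  stopifnot(inherits(network, "snn_network"), !is.null(network$plastic))
  lay <- network$layout
  K <- network$config$n_items
  if (is.null(cos_onsets)) cos_onsets <- 4000 * seq_len(K)
  cos_onsets <- sort(cos_onsets)
  duration <- max(cos_onsets) + protocol$cos_duration + 1000
  epochs <- list(
    stimulus_epoch(layout_range(lay, "ordinal", 1), "constant",
                   rate = protocol$go_rate, start = 0,
                   duration = protocol$go_duration,
                   weight = protocol$go_weight))
  for (tt in cos_onsets)
    epochs[[length(epochs) + 1L]] <-
      stimulus_epoch(layout_range(lay, "cos"), "constant",
                     rate = protocol$cos_rate, start = tt,
                     duration = protocol$cos_duration,
                     weight = protocol$cos_weight)
  config <- sim_config(dt = dt, duration = duration, seed = seed,
                       mismatch_sigma = mismatch_sigma)
  res <- run_simulation(network, epochs, config)

  decoded <- decode_sequence(res$raster, lay, item_regions(network),
                             window = window,
                             rate_threshold = rate_threshold)
  ep <- data.frame(start = c(0, cos_onsets[-length(cos_onsets)] +
                               protocol$cos_duration),
                   end = cos_onsets)
  ep$ok <- vapply(seq_len(nrow(ep)), function(i)
    any(decoded$onset < ep$end[i] & decoded$offset > ep$start[i] &
          !is.na(decoded$label)), logical(1))
  seq_labels <- rep(NA_character_, nrow(ep))
  for (i in seq_len(nrow(ep))) {
    hit <- which(decoded$onset < ep$end[i] & decoded$offset > ep$start[i] &
                   !is.na(decoded$label))
    if (length(hit)) seq_labels[i] <- decoded$label[hit[1]]
  }
  structure(list(raster = res$raster, decoded = decoded,
                 sequence = seq_labels, epochs = ep, network = res$network),
            class = "replay_result")
}

#' @export
print.replay_result <- function(x, ...) {
  cat("<replay_result> decoded sequence:",
      paste(ifelse(is.na(x$sequence), "?", x$sequence), collapse = "-"), "\n")
  invisible(x)
}

#' Enable or disable plasticity on a network
#' @param network An `snn_network` with plastic synapses.
#' @param enabled Logical.
#' @return The modified network.
#' @export
set_plasticity <- function(network, enabled) {
  stopifnot(inherits(network, "snn_network"), !is.null(network$plastic))
  network$plastic$enabled <- isTRUE(enabled)
  network
}

#' Probe readout of the plastic weights
#'
#' Plastic synapse states are not read out directly: each synapse is
#' stimulated with a fixed regular burst of input events (delivered with the
#' synapse's current efficacy) while the rest of the network is silent, and
#' the entry is scored high exactly when the postsynaptic neuron spikes
#' during the observation window. Probing is performed row by row
#' (presynaptic neuron by presynaptic neuron), so simultaneous bursts never
#' converge on one postsynaptic neuron. The probe is deterministic and
#' idempotent; the network itself is not modified.
#'
#' Plasticity must be disabled first (see [set_plasticity()]); probing with
#' plasticity on would corrupt the weights and is refused.
#'
#' @param network An `snn_network` with plastic synapses and plasticity
#'   disabled.
#' @param pre_range Integer vector of 0-based presynaptic neuron indices to
#'   probe; default: all rows with at least one existing plastic synapse.
#' @param burst_rate Burst rate (Hz).
#' @param burst_duration Burst/observation window (ms).
#' @param dt Time step (ms).
#' @return Integer 0/1 matrix (n x n); unprobed entries are 0. The probed
#'   rows are recorded in the `probed_rows` attribute.
#' @export
probe_plastic_weights <- function(network, pre_range = NULL,
                                  burst_rate = 1700, burst_duration = 100,
                                  dt = 0.1) {
  stopifnot(inherits(network, "snn_network"), !is.null(network$plastic))
  if (isTRUE(network$plastic$enabled))
    stop("plasticity is enabled; probing would corrupt the weights. ",
         "Disable it first with set_plasticity(network, FALSE).")
  pl <- network$plastic
  n <- n_neurons(network$layout)
  if (is.null(pre_range))
    pre_range <- which(rowSums(pl$exists) > 0) - 1L
  out <- matrix(0L, n, n)

  # silent scaffold: no static synapses, no plasticity, no drift
  probe_net <- network
  probe_net$static_w <- matrix(0, n, n)
  ev_times <- seq(0, burst_duration - 1e-9, by = 1000 / burst_rate)
  for (pre in pre_range) {
    posts <- which(pl$exists[pre + 1L, ] == 1L & pl$w[pre + 1L, ] > 0) - 1L
    if (!length(posts)) next
    ev <- data.frame(
      time = rep(ev_times, times = length(posts)),
      neuron = rep(posts, each = length(ev_times)),
      weight = rep(pl$gain * pl$w[pre + 1L, posts + 1L],
                   each = length(ev_times)))
    res <- run_simulation(probe_net, list(),
                          sim_config(dt = dt,
                                     duration = burst_duration + 20,
                                     seed = 0L),
                          ext_events = ev, plasticity = FALSE, drift = FALSE)
    hit <- unique(res$raster$neuron)
    out[pre + 1L, hit + 1L] <- 1L
  }
  attr(out, "probed_rows") <- pre_range
  out
}

#' Overwrite a stored sequence by repeated re-teaching
#'
#' A network previously taught one sequence is re-taught a new sequence
#' without resetting the plastic weights. The external content input must be
#' stronger than the potentiated plastic drive so that the new item wins the
#' content competition; the old associations are then slowly forgotten by
#' synaptic depression (presynaptic spikes arriving at silent postsynaptic
#' neurons). After each teaching trial the plastic matrix is probed and a
#' replay is decoded.
#'
#' @param network An `snn_network` already taught the old sequence.
#' @param new_items Character vector: the new sequence.
#' @param n_trials Number of re-teaching trials to run.
#' @param protocol A [teaching_protocol()].
#' @param seed,dt,mismatch_sigma As in [run_teaching()].
#' @param stop_on_success Stop after the first trial whose replay decodes the
#'   new sequence exactly (default FALSE: run all trials).
#' @return An object of class `unlearning_result`: list with `trials` (one
#'   entry per trial: `probe`, `replay`, `sequence`), `first_success` (first
#'   trial index whose replay matches `new_items`, or `NA`), `network`.
#' @export
run_unlearning <- function(network, new_items, n_trials = 5,
                           protocol = teaching_protocol(), seed = 1L,
                           dt = 0.1, mismatch_sigma = 0.1,
                           stop_on_success = FALSE) {
  stopifnot(inherits(network, "snn_network"), !is.null(network$plastic))
  # dominance condition: external content input must exceed the plastic drive
  tau <- network$weight_table$psc_time_constant
  ext_drive <- protocol$item_weight * protocol$item_peak / 1000 * tau
  plastic_drive <- network$plastic$gain * network$plastic$params$w_max *
    network$config$ordinal_size * 0.15 * tau  # nominal 150 Hz per neuron
  if (ext_drive <= plastic_drive)
    warning("dominance condition violated: external content drive (",
            round(ext_drive, 2), ") does not exceed the potentiated ",
            "plastic drive (", round(plastic_drive, 2),
            "); the old item may keep winning the content competition")

  trials <- vector("list", n_trials)
  first_success <- NA_integer_
  for (trial in seq_len(n_trials)) {
    teach <- run_teaching(network, new_items, protocol,
                          seed = derive_seed(seed, 100 + trial), dt = dt,
                          mismatch_sigma = mismatch_sigma, check = FALSE)
    network <- teach$network
    probe <- probe_plastic_weights(set_plasticity(network, FALSE))
    replay <- run_replay(network, protocol = protocol,
                         seed = derive_seed(seed, 200 + trial), dt = dt,
                         mismatch_sigma = mismatch_sigma)
    ok <- length(replay$sequence) == length(new_items) &&
      !anyNA(replay$sequence) && all(replay$sequence == new_items)
    trials[[trial]] <- list(probe = probe, replay = replay,
                            sequence = replay$sequence, success = ok)
    if (ok && is.na(first_success)) first_success <- trial
    if (ok && stop_on_success) {
      trials <- trials[seq_len(trial)]
      break
    }
  }
  structure(list(trials = trials, first_success = first_success,
                 network = network),
            class = "unlearning_result")
}

#' @export
print.unlearning_result <- function(x, ...) {
  cat("<unlearning_result> ", length(x$trials), " trial(s); first exact ",
      "replay of the new sequence at trial ",
      ifelse(is.na(x$first_success), "none", x$first_success), "\n", sep = "")
  invisible(x)
}
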