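# Synthetic event-camera front end: a blinking laser pointer highlighting
# scene positions produces bursts of address events whose x coordinate maps
# onto the content field; an activity population (dvs_on) tracks whether the
# sensor currently sees the laser and holds down the CoS group.

#' Laser-pointer stimulation script
#'
#' Describes a synthetic event-camera recording of a blinking laser pointer:
#' an ordered list of highlighted pixel columns, each with an on-period
#' (laser visible, events at `on_rate` around the column) followed by an
#' off-period (background noise only).
#'
#' @param x Integer vector of highlighted pixel columns.
#' @param on_duration On-period duration(s) (ms; recycled).
#' @param off_duration Off-period duration(s) following each on-period (ms).
#' @param on_rate Event rate while the laser is on (events/s).
#' @param noise_rate Background noise event rate over the whole sensor
#'   (events/s).
#' @param jitter_sigma Spatial spread of laser events around the column
#'   (pixels).
#' @param resolution Sensor resolution `c(columns, rows)`.
#' @return An object of class `laser_script`.
#' @export
laser_script <- function(x, on_duration = 4000, off_duration = 1500,
                         on_rate = 2000, noise_rate = 100,
                         jitter_sigma = 4, resolution = c(128, 128)) {
  if (any(on_duration <= 0) || any(off_duration <= 0))
    stop("durations must be > 0")
  if (any(x < 0 | x >= resolution[1]))
    stop("laser columns must lie inside the sensor")
  seg <- data.frame(x = as.integer(x),
                    on_duration = rep_len(on_duration, length(x)),
                    off_duration = rep_len(off_duration, length(x)))
  structure(list(segments = seg, on_rate = on_rate,
                 noise_rate = noise_rate, jitter_sigma = jitter_sigma,
                 resolution = as.integer(resolution)),
            class = "laser_script")
}

#' Generate a synthetic address-event stream
#'
#' While the laser is on at column `x`, events occur as a Poisson process at
#' the script's on-rate, spatially jittered around `x` (Gaussian, clipped to
#' the sensor); rows are uniform. Background noise events occur uniformly
#' over all pixels for the whole duration. Polarity is random and carries no
#' information downstream.
#'
#' @param script A [laser_script()].
#' @param duration Total stream duration (ms); default the script's total
#'   on+off time.
#' @param seed Integer seed.
#' @return An object of class `aer_events`: data.frame with columns `t`
#'   (ms, sorted), `x`, `y` (pixels), `pol` (+1/-1), with the sensor
#'   resolution as an attribute.
#' @export
synth_dvs_stream <- function(script, duration = NULL, seed = 1L) {
  stopifnot(inherits(script, "laser_script"))
  set.seed(seed)
  seg <- script$segments
  total <- sum(seg$on_duration + seg$off_duration)
  if (is.null(duration)) duration <- total
  res <- script$resolution

  ts <- numeric(0); xs <- integer(0)
  t0 <- 0
  for (i in seq_len(nrow(seg))) {
    n_ev <- stats::rpois(1, script$on_rate * seg$on_duration[i] / 1000)
    if (n_ev > 0) {
      tt <- sort(stats::runif(n_ev, t0, t0 + seg$on_duration[i]))
      xx <- as.integer(round(seg$x[i] +
                               stats::rnorm(n_ev, 0, script$jitter_sigma)))
      xx <- pmin(res[1] - 1L, pmax(0L, xx))
      ts <- c(ts, tt); xs <- c(xs, xx)
    }
    t0 <- t0 + seg$on_duration[i] + seg$off_duration[i]
  }
  n_bg <- stats::rpois(1, script$noise_rate * duration / 1000)
  if (n_bg > 0) {
    ts <- c(ts, stats::runif(n_bg, 0, duration))
    xs <- c(xs, sample.int(res[1], n_bg, replace = TRUE) - 1L)
  }
  n_all <- length(ts)
  ev <- data.frame(t = ts,
                   x = xs,
                   y = if (n_all) sample.int(res[2], n_all,
                                             replace = TRUE) - 1L
                       else integer(0),
                   pol = if (n_all) sample(c(-1L, 1L), n_all,
                                           replace = TRUE) else integer(0))
  ev <- ev[order(ev$t), ]
  rownames(ev) <- NULL
  structure(ev, class = c("aer_events", "data.frame"), resolution = res)
}

#' Write / read an address-event stream (CSV)
#'
#' Columns `t_ms, x, y, pol`; round-trips exactly.
#' @param events An `aer_events` data.frame.
#' @param path File path.
#' @return `path` invisibly ([write_aer()]) or the events ([read_aer()]).
#' @export
write_aer <- function(events, path) {
  utils::write.csv(data.frame(t_ms = events$t, x = events$x, y = events$y,
                              pol = events$pol),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aer
#' @export
read_aer <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t_ms", "x", "y", "pol") %in% names(d)))
    stop("malformed AER file ", path, ": expected columns t_ms, x, y, pol")
  structure(data.frame(t = d$t_ms, x = d$x, y = d$y, pol = d$pol),
            class = c("aer_events", "data.frame"))
}

#' Map sensor columns onto content neurons
#'
#' Linear binning of the x pixel coordinate onto the content field: column 0
#' maps to the first content neuron, the last column to the last content
#' neuron. Polarity is ignored throughout.
#'
#' @param x Integer vector of pixel columns.
#' @param resolution_x Number of sensor columns.
#' @param layout A [population_layout()] with a content field.
#' @return Absolute 0-based content neuron indices.
#' @export
dvs_column_to_content <- function(x, resolution_x, layout) {
  content <- layout_range(layout, "content_exc")
  n <- length(content)
  idx <- floor(x / resolution_x * n)
  idx <- pmin(n - 1L, pmax(0L, idx))
  content[idx + 1L]
}

#' Convert an event stream into network input
#'
#' Every in-bounds event stimulates one content neuron (by its x column,
#' polarity ignored) and one neuron of the `dvs_on` activity population
#' (round-robin), so that the dvs_on group is active whenever the sensor
#' sees the laser and thereby holds down the CoS group. Out-of-bounds events
#' are rejected and counted.
#'
#' @param events An `aer_events` data.frame.
#' @param network An `snn_network` built with `cos_mode = "dvs"`.
#' @param resolution Sensor resolution `c(columns, rows)`.
#' @param content_weight Input current per event at the content neuron.
#' @param dvs_on_weight Input current per event at the dvs_on neuron.
#' @return data.frame (`time`, `neuron`, `weight`) for
#'   [run_simulation()]'s `ext_events`; rejected-event count in the
#'   `rejected` attribute.
#' @export
dvs_input <- function(events, network, resolution = c(128, 128),
                      content_weight = 0.3, dvs_on_weight = 2.5) {
  lay <- network$layout
  if (!has_population(lay, "dvs_on"))
    stop("network has no dvs_on population; build it with cos_mode = 'dvs'")
  ok <- events$x >= 0 & events$x < resolution[1] &
    events$y >= 0 & events$y < resolution[2]
  rejected <- sum(!ok)
  if (rejected) message(rejected, " event(s) outside sensor bounds rejected")
  ev <- events[ok, ]
  content_n <- dvs_column_to_content(ev$x, resolution[1], lay)
  dvs_on <- layout_range(lay, "dvs_on")
  rr <- dvs_on[(seq_len(nrow(ev)) - 1L) %% length(dvs_on) + 1L]
  out <- data.frame(
    time = rep(ev$t, 2),
    neuron = c(content_n, rr),
    weight = c(rep(content_weight, nrow(ev)),
               rep(dvs_on_weight, nrow(ev))))
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Teach a sequence from a synthetic event-camera stream
#'
#' The robot-experiment configuration: content input comes from the event
#' stream instead of scheduled Gaussian epochs, and transitions are
#' autonomous — while the laser is on, the dvs_on population inhibits the
#' CoS group; in the off-gaps the content bump (recalled through the freshly
#' potentiated synapses) excites the CoS, which suppresses the active
#' ordinal group and advances the sequence.
#'
#' @param network An `snn_network` with `cos_mode = "dvs"`.
#' @param script A [laser_script()]; each segment teaches one item position.
#' @param protocol A [teaching_protocol()] (go and reset parameters are
#'   used).
#' @param seed,dt,mismatch_sigma As in [run_teaching()].
#' @param content_weight,dvs_on_weight Per-event input currents.
#' @return A list of class `dvs_teaching_result`: `network` (trained),
#'   `raster`, `events`, `duration`.
#' @export
run_dvs_teaching <- function(network, script,
                             protocol = teaching_protocol(), seed = 1L,
                             dt = 0.1, mismatch_sigma = 0.1,
                             content_weight = 0.3, dvs_on_weight = 2.5) {
  stopifnot(inherits(network, "snn_network"),
            network$config$cos_mode == "dvs")
  events <- synth_dvs_stream(script, seed = derive_seed(seed, 11))
  ext <- dvs_input(events, network, script$resolution,
                   content_weight, dvs_on_weight)
  t_script <- sum(script$segments$on_duration + script$segments$off_duration)
  duration <- t_script + protocol$reset_duration + 500
  lay <- network$layout
  epochs <- list(
    stimulus_epoch(layout_range(lay, "ordinal", 1), "constant",
                   rate = protocol$go_rate, start = 0,
                   duration = protocol$go_duration,
                   weight = protocol$go_weight),
    stimulus_epoch(layout_range(lay, "reset"), "constant",
                   rate = protocol$reset_rate, start = t_script,
                   duration = protocol$reset_duration,
                   weight = protocol$reset_weight))
  config <- sim_config(dt = dt, duration = duration, seed = seed,
                       mismatch_sigma = mismatch_sigma)
  res <- run_simulation(network, epochs, config, ext_events = ext,
                        plasticity = TRUE)
  structure(list(network = res$network, raster = res$raster,
                 events = events, duration = duration),
            class = "dvs_teaching_result")
}

#' Replay in the event-camera configuration
#'
#' During robot replay the dvs_on population is held active by an auxiliary
#' always-on drive, suppressing the CoS; at each scheduled
#' "movement-complete" time the drive pauses briefly, the content bump
#' excites the CoS and the sequence advances.
#'
#' @param network A trained `snn_network` with `cos_mode = "dvs"`.
#' @param transition_times Times (ms) at which the dvs_on drive pauses.
#' @param gap_duration Pause length (ms).
#' @param protocol A [teaching_protocol()] (go parameters).
#' @param seed,dt,mismatch_sigma As in [run_teaching()].
#' @param rate_threshold,window Bump-detection parameters.
#' @return A `replay_result` (see [run_replay()]).
#' @export
run_dvs_replay <- function(network, transition_times = NULL,
                           gap_duration = 1000,
                           protocol = teaching_protocol(), seed = 1L,
                           dt = 0.1, mismatch_sigma = 0.1,
                           rate_threshold = 40, window = 100) {
  stopifnot(inherits(network, "snn_network"),
            network$config$cos_mode == "dvs")
  lay <- network$layout
  K <- network$config$n_items
  if (is.null(transition_times)) transition_times <- 4000 * seq_len(K)
  transition_times <- sort(transition_times)
  duration <- max(transition_times) + gap_duration + 1000
  dvs_on <- layout_range(lay, "dvs_on")
  # dvs_on drive segments between the pauses
  bounds <- c(0, rep(transition_times, each = 2) +
                rep(c(0, gap_duration), length(transition_times)), duration)
  epochs <- list(
    stimulus_epoch(layout_range(lay, "ordinal", 1), "constant",
                   rate = protocol$go_rate, start = 0,
                   duration = protocol$go_duration,
                   weight = protocol$go_weight))
  for (i in seq(1, length(bounds) - 1, by = 2)) {
    if (bounds[i + 1] - bounds[i] <= 0) next
    epochs[[length(epochs) + 1L]] <-
      stimulus_epoch(dvs_on, "constant", rate = 200, start = bounds[i],
                     duration = bounds[i + 1] - bounds[i], weight = 2.5)
  }
  config <- sim_config(dt = dt, duration = duration, seed = seed,
                       mismatch_sigma = mismatch_sigma)
  res <- run_simulation(network, epochs, config)
  decoded <- decode_sequence(res$raster, lay, item_regions(network),
                             window = window,
                             rate_threshold = rate_threshold)
  ep <- data.frame(start = c(0, transition_times[-length(transition_times)] +
                               gap_duration),
                   end = transition_times)
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
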