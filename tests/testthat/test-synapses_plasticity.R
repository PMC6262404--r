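# Static weight tables, spike delivery, and the calcium/voltage-gated
# bistable plasticity rule checked against an explicit three-branch oracle.

test_that("static weight table enforces the hardware constraints", {
  expect_error(static_weight_table(excitatory_levels = c(0.1, 0.2, 0.3)),
               "exactly 4")
  expect_error(static_weight_table(excitatory_levels = c(0.3, 0.2, 0.4, 0.5)),
               "increasing")
  expect_error(static_weight_table(inhibitory_levels = c(-0.1, 0.2)),
               "negative")
  tbl <- static_weight_table()
  expect_length(tbl$excitatory_levels, 4)
  w <- matrix(0, 3, 3)
  w[1, 2] <- tbl$excitatory_levels[1]
  expect_true(check_static_levels(w, tbl))
  w[2, 3] <- 0.123456
  expect_error(check_static_levels(w, tbl), "not levels")
})

test_that("deliver_spikes superposes currents linearly", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- 0.5
  w[2, 2] <- 0.25
  expect_equal(deliver_spikes(c(0L, 0L), w), c(0, 1.0, 0))
  expect_equal(deliver_spikes(c(0L, 1L), w), c(0, 0.75, 0))
  expect_equal(deliver_spikes(0L, w, gain = 2), c(0, 1.0, 0))
  expect_equal(deliver_spikes(integer(0), w), c(0, 0, 0))
  expect_error(deliver_spikes(3L, w), "out of range")
})

test_that("plastic update equals the three-branch oracle on sampled inputs", {
  pp <- plasticity_params()
  oracle <- function(w, v, ca) {
    if (v > pp$theta_mem && ca > pp$theta1 && ca < pp$theta_max) {
      w <- w + pp$delta_w_plus
    } else if (v < pp$theta_mem && ca >= pp$theta1_ltd && ca < pp$theta_max) {
      w <- w - pp$delta_w_minus
    }
    min(pp$w_max, max(pp$w_min, w))
  }
  set.seed(42)
  for (i in 1:500) {
    w <- runif(1, 0, 1)
    v <- runif(1, -0.5, 1.5)
    ca <- runif(1, 0, 8)
    expect_identical(plastic_update_on_pre(w, v, ca, pp), oracle(w, v, ca))
  }
})

test_that("plasticity gate boundaries are honored exactly", {
  pp <- plasticity_params()
  w <- 0.5
  # calcium exactly at theta1: potentiation gate is strict, so no LTP
  expect_equal(plastic_update_on_pre(w, v_post = 1, ca_post = pp$theta1, pp),
               w)
  # calcium at theta_max: both gates closed
  expect_equal(plastic_update_on_pre(w, v_post = 1, ca_post = pp$theta_max,
                                     pp), w)
  expect_equal(plastic_update_on_pre(w, v_post = 0, ca_post = pp$theta_max,
                                     pp), w)
  # membrane exactly at theta_mem: neither branch
  expect_equal(plastic_update_on_pre(w, v_post = pp$theta_mem, ca_post = 1,
                                     pp), w)
  # calcium exactly at theta1_ltd: depression gate is inclusive
  expect_equal(plastic_update_on_pre(w, v_post = 0, ca_post = pp$theta1_ltd,
                                     pp), w - pp$delta_w_minus)
  # rails clamp
  expect_equal(plastic_update_on_pre(0.98, v_post = 1, ca_post = 1, pp),
               pp$w_max)
  expect_equal(plastic_update_on_pre(0.02, v_post = 0, ca_post = 0, pp),
               pp$w_min)
})

test_that("bistable drift is direction-stable and exact over long steps", {
  pp <- plasticity_params()
  # one long step equals many short steps (constant rate, fixed direction)
  w0 <- c(0.1, 0.45, 0.5, 0.55, 0.9)
  long <- drift_step(w0, 1000, pp)
  short <- w0
  for (i in 1:100) short <- drift_step(short, 10, pp)
  expect_equal(long, short)
  # a weight exactly at theta_w does not move
  expect_equal(long[3], 0.5)
  # long enough drift lands every off-threshold weight exactly on a rail
  final <- drift_step(w0, 1e6, pp)
  expect_equal(final, c(0, 0, 0.5, 1, 1))
  expect_true(all(abs(final[-3] - round(final[-3])) < 1e-9))
  expect_error(drift_step(0.2, 0, pp), "dt")
})

test_that("plastic matrix initialization has the documented structure", {
  lay <- population_layout(c(cos = 10, reset = 10, memory_1 = 10,
                             memory_2 = 10, ordinal_1 = 20, ordinal_2 = 20,
                             content_exc = 60))
  f <- 0.3
  pl <- initialize_plastic_matrix(lay, recurrent_potentiated_fraction = f,
                                  seed = 3)
  content <- layout_range(lay, "content_exc") + 1L
  n_learn_expected <- 2 * 20 * 60
  expect_equal(sum(pl$learn), n_learn_expected)
  n_frozen_expected <- 2 * (round(f * 400) + round(f * 100))
  expect_equal(sum(pl$exists) - sum(pl$learn), n_frozen_expected)
  for (k in 1:2) {
    ord <- layout_range(lay, "ordinal", k) + 1L
    expect_true(all(pl$learn[ord, content] == 1L))
    expect_true(all(pl$w[ord, content] == pl$params$w_min))
  }
  frozen <- pl$exists == 1L & pl$learn == 0L
  expect_true(all(pl$w[frozen] == pl$params$w_max))
  # seeded initialization is reproducible
  pl2 <- initialize_plastic_matrix(lay, recurrent_potentiated_fraction = f,
                                   seed = 3)
  expect_identical(pl$w, pl2$w)
  expect_error(initialize_plastic_matrix(lay,
                                         recurrent_potentiated_fraction = 2),
               "in \\[0, 1\\]")
})

test_that("compiled core applies depression exactly as the rule dictates", {
  # A single plastic synapse onto a silent postsynaptic neuron: every
  # delivered presynaptic spike finds V_post < theta_mem and Ca_post = 0
  # (inside the inclusive depression gate), so the weight must drop by
  # exactly delta_w_minus per delivered spike. Drift is switched off to make
  # the prediction exact.
  lay <- population_layout(c(ordinal_1 = 1, memory_1 = 0, content_exc = 1))
  pp <- plasticity_params(c_drift = 0)
  pl <- initialize_plastic_matrix(lay, recurrent_potentiated_fraction = 0,
                                  params = pp, gain = 0.01)
  # short synaptic time constant: each input event causes exactly one
  # presynaptic spike (the current decays away within the refractory period)
  net <- simple_network(matrix(0, 2, 2), layout = lay,
                        psc_time_constant = 1)
  net$plastic <- pl
  net$plastic$w[1, 2] <- 0.5
  dur <- 200
  dt <- 0.1
  ev <- data.frame(time = seq(10, 190, by = 20), neuron = 0L, weight = 30)
  res <- run_simulation(net, list(), sim_config(dt = dt, duration = dur,
                                                seed = 1), ext_events = ev)
  pre_sp <- res$raster$time[res$raster$neuron == 0]
  expect_gt(length(pre_sp), 3)
  expect_equal(sum(res$raster$neuron == 1), 0)    # post stayed silent
  # spikes emitted in the final step are never delivered
  n_delivered <- sum(pre_sp <= dur - 2 * dt + 1e-9)
  expect_equal(res$network$plastic$w[1, 2],
               0.5 - n_delivered * pp$delta_w_minus)
})

test_that("probe readout reports potentiated synapses without modifying them", {
  net <- build_serial_order(serial_order_config(), seed = 1)
  expect_error(probe_plastic_weights(net), "plasticity is enabled")
  net <- set_plasticity(net, FALSE)
  ord1 <- layout_range(net$layout, "ordinal", 1)
  content <- layout_range(net$layout, "content_exc")
  # potentiate a known block, leave a below-threshold weight elsewhere
  hi_cols <- content[1:10]
  lo_cols <- content[21:30]
  net$plastic$w[ord1 + 1L, hi_cols + 1L] <- 1
  net$plastic$w[ord1 + 1L, lo_cols + 1L] <- 0.3
  w_before <- net$plastic$w
  probe <- probe_plastic_weights(net, pre_range = ord1)
  expect_true(all(probe[ord1 + 1L, hi_cols + 1L] == 1L))
  expect_true(all(probe[ord1 + 1L, lo_cols + 1L] == 0L))
  expect_identical(net$plastic$w, w_before)       # probing is read-only
  probe2 <- probe_plastic_weights(net, pre_range = ord1)
  expect_identical(probe, probe2)                 # and idempotent
})
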