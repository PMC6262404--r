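# Population layouts, WTA patterns and the serial-order architecture,
# checked against independent row-count and block-structure oracles.

test_that("population layout enforces the neuron budget and uniqueness", {
  expect_error(population_layout(c(a = 200, b = 100)), "budget")
  expect_error(population_layout(c(100, 100)), "named")
  expect_error(population_layout(c(a = 10, a = 10)), "duplicate")
  lay <- population_layout(c(a = 10, b = 20, c = 5))
  expect_equal(n_neurons(lay), 35)
  expect_equal(layout_range(lay, "b"), 10:29)
  expect_error(layout_range(lay, "nope"), "no population")
  expect_true(has_population(lay, "a"))
  expect_false(has_population(lay, "z"))
})

test_that("lateral WTA matrix matches the row-count oracle", {
  cfg <- wta_config(excitatory_radius = 2, self_weight = 0.12,
                    neighbor_weight = 0.05, inhibition_weight = -0.06)
  n <- 20
  w <- build_wta_lateral(n, cfg)
  for (i in seq_len(n)) {
    n_neigh <- sum(abs(seq_len(n) - i) <= 2) - 1    # boundary-aware
    expect_equal(sum(w[i, ] == 0.05), n_neigh)
    expect_equal(sum(w[i, ] == -0.06), n - 1 - n_neigh)
  }
  expect_true(all(diag(w) == 0.12))
  expect_error(build_wta_lateral(4, cfg), "radius")
})

test_that("inhibitory-pool WTA matrix has the documented topology", {
  cfg <- wta_config(pattern = "inhibitory_pool", excitatory_radius = 1,
                    self_weight = 0.12, neighbor_weight = 0.05,
                    inhibition_weight = -0.06)
  w <- build_wta_pool(10, 3, cfg)
  field <- 1:10; pool <- 11:13
  expect_true(all(w[pool, pool] == 0))              # no pool recurrence
  expect_true(all(w[field, pool] == 0.12))          # field excites pool
  expect_true(all(w[pool, field] == -0.06))         # pool inhibits field
  expect_true(all(w[field, field] >= 0))            # no long-range inhibition
  expect_error(wta_config(inhibition_weight = 0.1), "negative")
  expect_error(wta_config(excitatory_radius = 0), "radius")
})

test_that("serial-order config validates weights against the table", {
  expect_error(serial_order_config(w_ordinal_self = 0.123),
               "table levels")
  expect_error(serial_order_config(w_cos_ordinal = -0.5), "table level")
  expect_error(serial_order_config(n_items = 3, sigma = 30), "2\\*sigma")
  cfg <- serial_order_config(n_items = 3)
  expect_equal(cfg$item_centers, c(10, 30, 50))
  expect_equal(cfg$sigma, 5)
  expect_equal(cfg$item_labels, c("A", "B", "C"))
})

test_that("serial-order network matches the block-structure oracle", {
  cfg <- serial_order_config(n_items = 3)
  net <- build_serial_order(cfg, seed = 1)
  lay <- net$layout
  w <- net$static_w
  expect_true(check_static_levels(w, net$weight_table))

  ord <- lapply(1:3, function(k) layout_range(lay, "ordinal", k) + 1L)
  mem <- lapply(1:3, function(k) layout_range(lay, "memory", k) + 1L)
  cos <- layout_range(lay, "cos") + 1L
  reset <- layout_range(lay, "reset") + 1L
  content <- layout_range(lay, "content_exc") + 1L

  # rebuild the expected matrix independently, block by block
  n <- n_neurons(lay)
  expected <- matrix(0, n, n)
  for (k in 1:3) {
    expected[ord[[k]], ord[[k]]] <- cfg$w_ordinal_self
    expected[mem[[k]], mem[[k]]] <- cfg$w_memory_self
    expected[ord[[k]], mem[[k]]] <- cfg$w_ordinal_memory
    expected[mem[[k]], ord[[k]]] <- cfg$w_memory_own
    if (k < 3) expected[mem[[k]], ord[[k + 1]]] <- cfg$w_memory_next
    for (l in 1:3) if (l != k)
      expected[ord[[k]], ord[[l]]] <- cfg$w_ordinal_inh
    expected[cos, ord[[k]]] <- cfg$w_cos_ordinal
    expected[reset, mem[[k]]] <- cfg$w_reset_memory
  }
  expected[content, content] <-
    build_wta_lateral(cfg$content_size,
                      wta_config(excitatory_radius = cfg$content_radius,
                                 self_weight = cfg$w_content_exc,
                                 neighbor_weight = cfg$w_content_exc,
                                 inhibition_weight = cfg$w_content_inh))
  expect_equal(sum(w != expected), 0)    # zero block-structure violations

  # ordinal drive to content is exclusively plastic, never static
  for (k in 1:3) expect_true(all(w[ord[[k]], content] == 0))
  expect_true(all(w[content, cos] == 0))   # external CoS mode
})

test_that("DVS mode adds the activity population and CoS wiring", {
  cfg <- serial_order_config(n_items = 3, cos_mode = "dvs")
  net <- build_serial_order(cfg, seed = 1)
  lay <- net$layout
  expect_true(has_population(lay, "dvs_on"))
  dvs_on <- layout_range(lay, "dvs_on") + 1L
  cos <- layout_range(lay, "cos") + 1L
  content <- layout_range(lay, "content_exc") + 1L
  expect_true(all(net$static_w[content, cos] == cfg$w_content_cos))
  expect_true(all(net$static_w[dvs_on, cos] == cfg$w_dvs_cos))

  # external mode has neither
  net2 <- build_serial_order(serial_order_config(n_items = 3), seed = 1)
  expect_false(has_population(net2$layout, "dvs_on"))
  cos2 <- layout_range(net2$layout, "cos") + 1L
  content2 <- layout_range(net2$layout, "content_exc") + 1L
  expect_true(all(net2$static_w[content2, cos2] == 0))
})

test_that("five-item architecture fits the 256-neuron budget", {
  cfg <- serial_order_config(n_items = 5)
  net <- build_serial_order(cfg, seed = 1)
  expect_lte(n_neurons(net$layout), 256)
  expect_equal(length(ordinal_groups(net$layout)), 5)
  expect_equal(cfg$sigma, 2)
  # a sixth item no longer fits at these population sizes
  expect_error(build_serial_order(serial_order_config(n_items = 8), seed = 1),
               "budget")
})

test_that("item regions partition the content field disjointly", {
  net <- build_serial_order(serial_order_config(n_items = 3), seed = 1)
  reg <- item_regions(net)
  expect_named(reg, c("A", "B", "C"))
  all_idx <- unlist(reg, use.names = FALSE)
  expect_equal(anyDuplicated(all_idx), 0)
  expect_setequal(all_idx, layout_range(net$layout, "content_exc"))
  # equidistant boundary cells are owned by the lower region
  expect_equal(lengths(reg), c(A = 21L, B = 20L, C = 19L))
  for (lab in names(reg)) {
    ctr <- item_center(net, lab)
    expect_true(floor(ctr) %in% reg[[lab]])
  }
  expect_error(item_center(net, "Z"), "unknown item")
})

test_that("content WTA forms a single bump at the stronger input", {
  cfg <- serial_order_config(n_items = 3)
  wta <- build_wta_lateral(cfg$content_size,
                           wta_config(excitatory_radius = cfg$content_radius,
                                      self_weight = cfg$w_content_exc,
                                      neighbor_weight = cfg$w_content_exc,
                                      inhibition_weight = cfg$w_content_inh))
  lay <- population_layout(c(content_exc = cfg$content_size))
  net <- simple_network(wta, layout = lay, psc_time_constant = 20)
  weak <- stimulus_epoch(0:59, "gaussian", peak = 300, center = 50,
                         sigma = 5, duration = 2000, weight = 0.6)
  strong <- stimulus_epoch(0:59, "gaussian", peak = 900, center = 10,
                           sigma = 5, duration = 2000, weight = 0.6)
  scfg <- sim_config(dt = 0.1, duration = 2000, seed = 2,
                     mismatch_sigma = 0.1)
  # the weak input alone is enough to form a sustained bump at 50 ...
  alone <- detect_bumps(run_simulation(net, list(weak), scfg)$raster, lay,
                        window = 100, rate_threshold = 40)
  big <- alone[alone$mass >= 200, ]
  expect_gt(nrow(big), 0)
  expect_true(all(abs(big$center - 50) < 6))
  # ... but loses the competition when the strong input is present
  both <- detect_bumps(run_simulation(net, list(weak, strong), scfg)$raster,
                       lay, window = 100, rate_threshold = 40)
  big2 <- both[both$mass >= 200, ]
  expect_gt(nrow(big2), 0)
  expect_true(all(abs(big2$center - 10) < 6))
})

test_that("content WTA rejects background noise at or below 10 Hz", {
  cfg <- serial_order_config(n_items = 3)
  wta <- build_wta_lateral(cfg$content_size,
                           wta_config(excitatory_radius = cfg$content_radius,
                                      self_weight = cfg$w_content_exc,
                                      neighbor_weight = cfg$w_content_exc,
                                      inhibition_weight = cfg$w_content_inh))
  lay <- population_layout(c(content_exc = cfg$content_size))
  net <- simple_network(wta, layout = lay, psc_time_constant = 20)
  eps <- list(stimulus_epoch(0:59, "uniform_background", max_rate = 10,
                             duration = 3000, weight = 0.5))
  res <- run_simulation(net, eps, sim_config(dt = 0.1, duration = 3000,
                                             seed = 3, mismatch_sigma = 0.1))
  bumps <- detect_bumps(res$raster, lay, window = 100, rate_threshold = 40)
  expect_equal(nrow(bumps), 0)
})
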