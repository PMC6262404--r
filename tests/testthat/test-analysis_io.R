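# Bump detection, sequence decoding, probe scoring, and file round-trips.

# Build a synthetic raster with regular spiking at given neuron sets/windows.
synth_raster <- function(windows, n_neurons, duration, layout,
                         rate = 100) {
  times <- numeric(0); neurons <- integer(0)
  for (wnd in windows) {
    r <- if (is.null(wnd$rate)) rate else wnd$rate
    tt <- seq(wnd$from, wnd$to - 1e-9, by = 1000 / r)
    for (nn in wnd$neurons) {
      times <- c(times, tt)
      neurons <- c(neurons, rep(nn, length(tt)))
    }
  }
  o <- order(times)
  spike_raster(times[o], neurons[o], n_neurons, duration, layout)
}

test_that("decoder recovers a known sequence from a synthetic raster", {
  net <- build_serial_order(serial_order_config(n_items = 3), seed = 1)
  lay <- net$layout
  reg <- item_regions(net)
  n <- n_neurons(lay)
  # bumps at A, then B, then C: 8 neurons around each item center
  ctr <- vapply(c("A", "B", "C"), function(l) item_center(net, l), numeric(1))
  wins <- list(
    list(from = 0, to = 2000, neurons = round(ctr["A"]) + (-4:3)),
    list(from = 2500, to = 4500, neurons = round(ctr["B"]) + (-4:3)),
    list(from = 5000, to = 7000, neurons = round(ctr["C"]) + (-4:3)))
  r <- synth_raster(wins, n, 7500, lay)
  dec <- decode_sequence(r, lay, reg)
  expect_equal(dec$label, c("A", "B", "C"))
  expect_true(all(dec$confidence == 1))
  expect_equal(nrow(dec), 3)    # bump count == number of generated epochs
})

test_that("a bump straddling two regions is flagged, not guessed", {
  net <- build_serial_order(serial_order_config(n_items = 3), seed = 1)
  lay <- net$layout
  reg <- item_regions(net)
  content0 <- layout_range(lay, "content_exc")[1]
  # regions A and B meet between local cells 20 and 21: a bump straddling
  # the boundary with a slight majority outside the region that contains
  # its center has confidence below 0.5
  wins <- list(
    list(from = 0, to = 2000, neurons = content0 + 18:20, rate = 100),
    list(from = 0, to = 2000, neurons = content0 + 21:23, rate = 120))
  r <- synth_raster(wins, n_neurons(lay), 2500, lay)
  dec <- decode_sequence(r, lay, reg)
  expect_equal(nrow(dec), 1)
  expect_true(is.na(dec$label[1]))
  expect_lt(dec$confidence[1], 0.5)
})

test_that("bump detection localizes and separates bumps", {
  lay <- population_layout(c(content_exc = 60))
  wins <- list(list(from = 0, to = 1000, neurons = 10:14),
               list(from = 2000, to = 3000, neurons = 40:44))
  r <- synth_raster(wins, 60, 3000, lay)
  b <- detect_bumps(r, lay, window = 100, rate_threshold = 40)
  expect_equal(nrow(b), 2)
  expect_equal(b$center, c(12, 42))
  expect_equal(b$onset, c(0, 2000))
  expect_equal(b$width, c(5, 5))
  # sub-threshold activity yields nothing
  r2 <- synth_raster(list(list(from = 0, to = 1000, neurons = 10:14)),
                     60, 1000, lay, rate = 20)
  expect_equal(nrow(detect_bumps(r2, lay, rate_threshold = 40)), 0)
  # empty raster yields an empty frame
  r0 <- spike_raster(numeric(0), integer(0), 60, 1000, lay)
  expect_equal(nrow(detect_bumps(r0, lay)), 0)
})

test_that("probe scoring finds block winners from an ideal matrix", {
  net <- build_serial_order(serial_order_config(n_items = 3), seed = 1)
  lay <- net$layout
  reg <- item_regions(net)
  n <- n_neurons(lay)
  probe <- matrix(0L, n, n)
  ord1 <- layout_range(lay, "ordinal", 1)
  probe[ord1 + 1L, reg$A + 1L] <- 1L
  sc <- score_probe(probe, lay, reg)
  expect_equal(unname(sc$winners["ordinal_1"]), "A")
  expect_true(is.na(sc$winners["ordinal_2"]))
  expect_equal(sc$fractions["ordinal_1", "A"], 1)
  expect_equal(sc$fractions["ordinal_1", "B"], 0)
  # the Voronoi regions cover the whole field: no off-block columns exist
  expect_true(is.na(sc$off_block_noise))
})

test_that("probe winners survive 5% salt noise", {
  net <- build_serial_order(serial_order_config(n_items = 3), seed = 1)
  lay <- net$layout
  reg <- item_regions(net)
  n <- n_neurons(lay)
  probe <- matrix(0L, n, n)
  assoc <- list("1" = "C", "2" = "A", "3" = "B")
  for (k in 1:3) {
    ord <- layout_range(lay, "ordinal", k)
    probe[ord + 1L, reg[[assoc[[as.character(k)]]]] + 1L] <- 1L
  }
  set.seed(9)
  content <- layout_range(lay, "content_exc")
  ords <- unlist(lapply(1:3, function(k) layout_range(lay, "ordinal", k)))
  flip <- cbind(sample(ords + 1L, 60, replace = TRUE),
                sample(content + 1L, 60, replace = TRUE))
  probe[flip] <- 1L - probe[flip]    # ~5% of the 1200-entry block
  sc <- score_probe(probe, lay, reg)
  expect_equal(unname(sc$winners), c("C", "A", "B"))
})

test_that("raster files round-trip in both formats", {
  lay <- population_layout(c(a = 5, b = 5))
  r <- spike_raster(c(0.1, 5.25, 900.333), c(0L, 7L, 3L), 10, 1000, lay)
  tsv <- tempfile(fileext = ".tsv")
  rds <- tempfile(fileext = ".rds")
  write_raster(r, tsv)
  write_raster(r, rds, format = "rds")
  for (p in c(tsv, rds)) {
    r2 <- read_raster(p)
    expect_equal(r2$time, r$time)
    expect_equal(r2$neuron, r$neuron)
    expect_equal(attr(r2, "n_neurons"), 10L)
    expect_equal(attr(r2, "duration"), 1000)
    expect_equal(attr(r2, "layout")$population, lay$population)
  }
  # empty raster round-trips too
  r0 <- spike_raster(numeric(0), integer(0), 10, 50, lay)
  write_raster(r0, tsv)
  expect_equal(nrow(read_raster(tsv)), 0)
  unlink(c(tsv, rds))
})

test_that("malformed raster files raise located parse errors", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("# serialmem spike raster", "# n_neurons: 5",
               "# duration_ms: 100", "# layout: ",
               "# time_ms\tneuron_index", "1.0\t2", "oops"), p)
  expect_error(read_raster(p), "line 7")
  writeLines(c("# serialmem spike raster", "# n_neurons: 5",
               "# duration_ms: 100", "# layout: ",
               "# time_ms\tneuron_index", "1.0\tx"), p)
  expect_error(read_raster(p), "non-numeric")
  writeLines(c("# serialmem spike raster", "# duration_ms: 100",
               "# layout: ", "1.0\t2"), p)
  expect_error(read_raster(p), "missing header")
  expect_error(read_raster(tempfile()), "no such file")
  unlink(p)
})

test_that("matrix files round-trip with their layout sidecar", {
  lay <- population_layout(c(a = 2, b = 2))
  w <- matrix(c(0, 0.5, -0.25, 0, 1, 0, 0, 0, -1, 0.125, 0, 0, 0, 0, 0, 2),
              4, 4)
  p <- tempfile(fileext = ".csv")
  write_matrix(w, p, layout = lay)
  w2 <- read_matrix(p)
  expect_equal(unclass(w2)[seq_along(w)], as.numeric(w))
  expect_equal(dim(w2), dim(w))
  expect_equal(attr(w2, "layout")$population, c("a", "b"))
  prds <- tempfile(fileext = ".rds")
  write_matrix(w, prds, layout = lay, format = "rds")
  w3 <- read_matrix(prds)
  expect_equal(w3[seq_along(w)], as.numeric(w))
  bad <- tempfile(fileext = ".csv")
  writeLines(c("1,2", "3"), bad)
  expect_error(read_matrix(bad), "malformed matrix")
  unlink(c(p, paste0(p, ".layout.json"), prds, bad))
})

test_that("config files round-trip through their constructors", {
  cfg <- list(neuron = neuron_params(membrane_time_constant = 17),
              plasticity = plasticity_params(delta_w_plus = 0.2),
              protocol = teaching_protocol(item_peak = 750),
              sim = sim_config(dt = 0.2, duration = 1234, seed = 99),
              serial = serial_order_config(n_items = 3),
              note = "hello")
  p <- tempfile(fileext = ".yaml")
  write_config(cfg, p)
  cfg2 <- read_config(p)
  expect_equal(cfg2$neuron$membrane_time_constant, 17)
  expect_s3_class(cfg2$neuron, "neuron_params")
  expect_equal(cfg2$plasticity$delta_w_plus, 0.2)
  expect_equal(cfg2$protocol$item_peak, 750)
  expect_equal(cfg2$sim$seed, 99L)
  expect_equal(cfg2$serial$item_centers, cfg$serial$item_centers)
  expect_equal(cfg2$note, "hello")
  # reading re-validates: a corrupted value is rejected by the constructor
  txt <- readLines(p)
  txt <- sub("membrane_time_constant: 17", "membrane_time_constant: -1", txt)
  writeLines(txt, p)
  expect_error(read_config(p), "time constants")
  unlink(p)
})

test_that("manifests of identical runs differ only in the timestamp", {
  cfg <- list(sim = sim_config(seed = 5), protocol = teaching_protocol())
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_manifest(p1, cfg, seed = 5)
  Sys.sleep(1.1)
  write_manifest(p2, cfg, seed = 5)
  m1 <- read_manifest(p1)
  m2 <- read_manifest(p2)
  expect_equal(m1$config_hash, m2$config_hash)
  expect_equal(m1$seed, m2$seed)
  expect_equal(m1$version, m2$version)
  m1$timestamp <- m2$timestamp <- NULL
  expect_equal(m1, m2)
  unlink(c(p1, p2))
})

test_that("AER event streams round-trip and map onto the content field", {
  script <- laser_script(x = c(20, 100), on_duration = 200,
                         off_duration = 100)
  ev <- synth_dvs_stream(script, seed = 3)
  expect_true(all(diff(ev$t) >= 0))
  expect_true(all(ev$x >= 0 & ev$x < 128))
  p <- tempfile(fileext = ".csv")
  write_aer(ev, p)
  ev2 <- read_aer(p)
  expect_equal(ev2$t, ev$t)
  expect_equal(ev2$x, ev$x)
  expect_equal(ev2$pol, ev$pol)
  writeLines("t,x", p)
  expect_error(read_aer(p), "malformed AER")
  unlink(p)

  lay <- population_layout(c(content_exc = 60))
  expect_equal(dvs_column_to_content(0, 128, lay), 0)
  expect_equal(dvs_column_to_content(127, 128, lay), 59)
  expect_equal(dvs_column_to_content(64, 128, lay), 30)
  expect_error(laser_script(x = 200), "inside the sensor")
  expect_error(laser_script(x = 10, on_duration = 0), "durations")
})
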