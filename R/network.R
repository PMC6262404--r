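#' Population layout of a network
#'
#' Named, non-overlapping index ranges assigning every neuron of the network
#' to one population. Neuron indices are 0-based and contiguous, in the order
#' the populations are given. Ordinal and memory populations are numbered
#' (`ordinal_1` ... `ordinal_K`).
#'
#' @param sizes Named integer vector of population sizes, e.g.
#'   `c(cos = 10, reset = 10, memory_1 = 10, ..., content_exc = 60)`.
#' @param budget Maximum total number of neurons (default 256, the size of
#'   the emulated neuron array).
#' @return An object of class `population_layout`: a data.frame with columns
#'   `population`, `start`, `size`.
#' @export
population_layout <- function(sizes, budget = 256) {
  if (is.null(names(sizes)) || any(names(sizes) == ""))
    stop("population sizes must be named")
  if (any(sizes < 0)) stop("population sizes must be >= 0")
  if (anyDuplicated(names(sizes))) stop("duplicate population names")
  total <- sum(sizes)
  if (total > budget) {
    stop("layout needs ", total, " neurons, exceeding the ", budget,
         "-neuron budget (",
         paste(names(sizes), sizes, sep = "=", collapse = ", "), ")")
  }
  df <- data.frame(population = names(sizes),
                   start = c(0L, cumsum(sizes)[-length(sizes)]),
                   size = as.integer(sizes),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("population_layout", "data.frame"))
}

#' Total number of neurons in a layout
#' @param layout A [population_layout()].
#' @return Integer neuron count.
#' @export
n_neurons <- function(layout) {
  stopifnot(inherits(layout, "population_layout"))
  sum(layout$size)
}

#' 0-based neuron indices of one population
#'
#' @param layout A [population_layout()].
#' @param population Population name, e.g. `"content_exc"`, or a numbered
#'   family name (`"ordinal"`, `"memory"`) combined with `k`.
#' @param k Optional group number for numbered families.
#' @return Integer vector of 0-based neuron indices.
#' @export
layout_range <- function(layout, population, k = NULL) {
  stopifnot(inherits(layout, "population_layout"))
  name <- if (is.null(k)) population else paste0(population, "_", k)
  row <- match(name, layout$population)
  if (is.na(row)) stop("no population named '", name, "' in layout")
  seq.int(layout$start[row], length.out = layout$size[row])
}

#' Does a layout contain a population?
#' @inheritParams layout_range
#' @return Logical.
#' @export
has_population <- function(layout, population) {
  population %in% layout$population
}

#' Ordinal group numbers present in a layout
#' @param layout A [population_layout()].
#' @return Integer vector `1:K`.
#' @export
ordinal_groups <- function(layout) {
  nm <- grep("^ordinal_[0-9]+$", layout$population, value = TRUE)
  sort(as.integer(sub("^ordinal_", "", nm)))
}

#' @export
print.population_layout <- function(x, ...) {
  cat("<population_layout> ", n_neurons(x), " neurons\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s [%d, %d]\n", x$population[i], x$start[i],
                x$start[i] + x$size[i] - 1L))
  invisible(x)
}

#' Soft winner-take-all connectivity configuration
#'
#' Two patterns realize a soft WTA over a linear (non-wraparound) neuron
#' array. In the `"lateral"` pattern each neuron connects excitatorily to
#' itself and its neighbors within `excitatory_radius` and inhibitorily to
#' every other neuron of the field. In the `"inhibitory_pool"` pattern the
#' local excitatory footprint is kept, long-range inhibition is removed, and
#' a small inhibitory group is excited by all field neurons and inhibits them
#' all back.
#'
#' @param pattern `"lateral"` or `"inhibitory_pool"`.
#' @param excitatory_radius Excitatory neighborhood half-width (neurons, >= 1).
#' @param self_weight Excitatory weight of the self-connection (also used for
#'   the field-to-pool projection in the pool pattern).
#' @param neighbor_weight Excitatory weight to neighbors within the radius.
#' @param inhibition_weight Negative weight of the inhibitory connections
#'   (long-range in the lateral pattern, pool-to-field in the pool pattern).
#' @param pool_size Size of the inhibitory group (pool pattern only).
#' @return An object of class `wta_config`.
#' @export
wta_config <- function(pattern = c("lateral", "inhibitory_pool"),
                       excitatory_radius = 2,
                       self_weight = 0.12,
                       neighbor_weight = 0.12,
                       inhibition_weight = -0.06,
                       pool_size = 10) {
  pattern <- match.arg(pattern)
  if (excitatory_radius < 1) stop("excitatory_radius must be >= 1")
  if (self_weight <= 0 || neighbor_weight <= 0)
    stop("excitatory weights must be positive")
  if (inhibition_weight >= 0) stop("inhibition_weight must be negative")
  if (pool_size < 1) stop("pool_size must be >= 1")
  structure(list(pattern = pattern,
                 excitatory_radius = as.integer(excitatory_radius),
                 self_weight = self_weight,
                 neighbor_weight = neighbor_weight,
                 inhibition_weight = inhibition_weight,
                 pool_size = as.integer(pool_size)),
            class = "wta_config")
}

#' Build a lateral-inhibition soft-WTA matrix
#'
#' Row `i` carries excitatory weights to neuron `i` itself and to every
#' neuron within the excitatory radius, and inhibitory weights to all other
#' neurons of the field. Boundaries are linear: no wraparound.
#'
#' @param n Field size (must exceed twice the radius).
#' @param cfg A [wta_config()].
#' @return An `n x n` numeric weight matrix (row = presynaptic neuron).
#' @export
build_wta_lateral <- function(n, cfg) {
  stopifnot(inherits(cfg, "wta_config"))
  r <- cfg$excitatory_radius
  if (r >= n / 2)
    stop("excitatory_radius (", r, ") must be < n/2 (n = ", n, ")")
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  w <- matrix(cfg$inhibition_weight, n, n)
  w[d <= r] <- cfg$neighbor_weight
  diag(w) <- cfg$self_weight
  w
}

#' Build an inhibitory-pool soft-WTA matrix
#'
#' Excitatory field neurons keep the local recurrent footprint of the lateral
#' pattern but no long-range inhibition; all of them excite a small
#' inhibitory pool, which inhibits them all back. There is no pool-to-pool
#' coupling. Field neurons occupy indices `1..n_exc`, pool neurons the rest.
#'
#' @param n_exc Excitatory field size.
#' @param n_inh Inhibitory pool size (>= 1).
#' @param cfg A [wta_config()].
#' @return An `(n_exc + n_inh)` square weight matrix.
#' @export
build_wta_pool <- function(n_exc, n_inh, cfg) {
  stopifnot(inherits(cfg, "wta_config"))
  if (n_inh < 1) stop("n_inh must be >= 1")
  r <- cfg$excitatory_radius
  if (r >= n_exc / 2)
    stop("excitatory_radius (", r, ") must be < n_exc/2")
  n <- n_exc + n_inh
  w <- matrix(0, n, n)
  idx <- seq_len(n_exc)
  d <- abs(outer(idx, idx, "-"))
  loc <- matrix(0, n_exc, n_exc)
  loc[d <= r] <- cfg$neighbor_weight
  diag(loc) <- cfg$self_weight
  w[idx, idx] <- loc
  w[idx, n_exc + seq_len(n_inh)] <- cfg$self_weight
  w[n_exc + seq_len(n_inh), idx] <- cfg$inhibition_weight
  w
}

#' Serial-order architecture configuration
#'
#' All population sizes, projection weights and content-item geometry of the
#' ordinal/memory/content/CoS network. Weights must be levels of the supplied
#' [static_weight_table()]. Item centers are equally spaced along the content
#' field at `content_size / n_items * (k - 1/2)` and are at least two
#' standard deviations apart.
#'
#' @param n_items Sequence length K (>= 1).
#' @param ordinal_size,memory_size,cos_size,reset_size,dvs_on_size Population
#'   sizes.
#' @param content_size Content field size; default 60 for K <= 3 and 40 for
#'   longer sequences (the field shrinks so longer architectures fit the
#'   256-neuron budget).
#' @param sigma Standard deviation (in neurons) of the Gaussian item inputs;
#'   defaults to a quarter of the center spacing (`content_size / (4
#'   n_items)`, i.e. 5 for the K = 3 field of 60), so the +/- 2 sigma
#'   footprint of an item exactly fills its own region of the field.
#' @param content_pattern WTA pattern of the content field: `"lateral"`
#'   (default) or `"inhibitory_pool"`.
#' @param content_radius Excitatory radius of the content WTA.
#' @param cos_mode `"external"` (transitions triggered by direct CoS
#'   stimulation) or `"dvs"` (CoS driven by the content field and held down
#'   by the event-camera activity population).
#' @param weight_table A [static_weight_table()].
#' @param w_ordinal_self,w_memory_self,w_ordinal_memory,w_memory_next,w_content_exc,w_content_cos
#'   Excitatory projection weights (table levels).
#' @param w_ordinal_inh,w_memory_own,w_content_inh,w_cos_ordinal,w_reset_memory,w_dvs_cos
#'   Inhibitory projection weights (table levels, negative).
#' @param plastic_fraction Fraction of randomly potentiated frozen entries in
#'   the recurrent ordinal/memory blocks.
#' @param plastic_gain Current per presynaptic spike and unit plastic weight.
#' @param plasticity A [plasticity_params()].
#' @return An object of class `serial_order_config`.
#' @export
serial_order_config <- function(n_items = 3,
                                ordinal_size = 20,
                                memory_size = 10,
                                cos_size = 10,
                                reset_size = 10,
                                dvs_on_size = 10,
                                content_size = if (n_items <= 3) 60 else 40,
                                sigma = content_size / (4 * n_items),
                                content_pattern = "lateral",
                                content_radius = 2,
                                cos_mode = c("external", "dvs"),
                                weight_table = static_weight_table(),
                                w_ordinal_self = 0.12,
                                w_memory_self = 0.2,
                                w_ordinal_memory = 0.05,
                                w_memory_next = 0.05,
                                w_content_exc = 0.03,
                                w_content_cos = 0.2,
                                w_ordinal_inh = -0.15,
                                w_memory_own = -0.015,
                                w_content_inh = -0.06,
                                w_cos_ordinal = -0.15,
                                w_reset_memory = -0.15,
                                w_dvs_cos = -0.15,
                                plastic_fraction = 0.3,
                                plastic_gain = 0.06,
                                plasticity = plasticity_params()) {
  cos_mode <- match.arg(cos_mode)
  if (n_items < 1) stop("n_items must be >= 1")
  centers <- content_size / n_items * (seq_len(n_items) - 0.5)
  if (n_items > 1 && min(diff(centers)) < 2 * sigma)
    stop("item centers must be at least 2*sigma apart; ",
         "reduce sigma or enlarge the content field")
  cfg <- list(n_items = as.integer(n_items),
              ordinal_size = as.integer(ordinal_size),
              memory_size = as.integer(memory_size),
              cos_size = as.integer(cos_size),
              reset_size = as.integer(reset_size),
              dvs_on_size = as.integer(dvs_on_size),
              content_size = as.integer(content_size),
              sigma = sigma,
              item_centers = centers,
              item_labels = LETTERS[seq_len(n_items)],
              content_pattern = content_pattern,
              content_radius = as.integer(content_radius),
              cos_mode = cos_mode,
              weight_table = weight_table,
              w_ordinal_self = w_ordinal_self,
              w_memory_self = w_memory_self,
              w_ordinal_memory = w_ordinal_memory,
              w_memory_next = w_memory_next,
              w_content_exc = w_content_exc,
              w_content_cos = w_content_cos,
              w_ordinal_inh = w_ordinal_inh,
              w_memory_own = w_memory_own,
              w_content_inh = w_content_inh,
              w_cos_ordinal = w_cos_ordinal,
              w_reset_memory = w_reset_memory,
              w_dvs_cos = w_dvs_cos,
              plastic_fraction = plastic_fraction,
              plastic_gain = plastic_gain,
              plasticity = plasticity)
  exc <- c(w_ordinal_self, w_memory_self, w_ordinal_memory, w_memory_next,
           w_content_exc, w_content_cos)
  inh <- c(w_ordinal_inh, w_memory_own, w_content_inh, w_cos_ordinal,
           w_reset_memory, w_dvs_cos)
  if (!all(exc %in% weight_table$excitatory_levels))
    stop("every excitatory projection weight must be one of the 4 table levels")
  if (!all(inh %in% weight_table$inhibitory_levels))
    stop("every inhibitory projection weight must be a table level")
  structure(cfg, class = "serial_order_config")
}

#' Assemble the serial-order network
#'
#' Materializes the full architecture: K ordinal groups forming a WTA (only
#' one can be active at a time), self-sustaining memory groups that keep
#' track of progress along the sequence, the asymmetric
#' ordinal-to-memory-to-next-ordinal chain, weak memory-to-own-ordinal
#' inhibition, the content WTA field, the condition-of-satisfaction (CoS)
#' group inhibiting all ordinal groups, the reset group inhibiting all memory
#' groups, and the plastic ordinal-to-content block (initialized fully
#' depressed, with a fraction of frozen potentiated recurrent entries
#' strengthening the ordinal and memory groups).
#'
#' @param cfg A [serial_order_config()].
#' @param neuron A [neuron_params()] set shared by all neurons.
#' @param seed Optional seed for the random potentiated recurrent entries.
#' @return An object of class `snn_network`: list with `layout`, `static_w`,
#'   `plastic` (a `plastic_matrix`), `weight_table`, `neuron`, `config`.
#' @examples
#' net <- build_serial_order(serial_order_config(n_items = 3), seed = 1)
#' net
#' @export
build_serial_order <- function(cfg, neuron = neuron_params(), seed = NULL) {
  stopifnot(inherits(cfg, "serial_order_config"))
  K <- cfg$n_items
  sizes <- c(cos = cfg$cos_size, reset = cfg$reset_size)
  for (k in seq_len(K)) sizes[paste0("memory_", k)] <- cfg$memory_size
  for (k in seq_len(K)) sizes[paste0("ordinal_", k)] <- cfg$ordinal_size
  sizes["content_exc"] <- cfg$content_size
  if (cfg$content_pattern == "inhibitory_pool")
    sizes["content_inh"] <- 10L
  if (cfg$cos_mode == "dvs")
    sizes["dvs_on"] <- cfg$dvs_on_size
  layout <- population_layout(sizes)
  n <- n_neurons(layout)
  w <- matrix(0, n, n)

  ord <- lapply(seq_len(K), function(k) layout_range(layout, "ordinal", k) + 1L)
  mem <- lapply(seq_len(K), function(k) layout_range(layout, "memory", k) + 1L)
  cos <- layout_range(layout, "cos") + 1L
  reset <- layout_range(layout, "reset") + 1L
  content <- layout_range(layout, "content_exc") + 1L

  for (k in seq_len(K)) {
    w[ord[[k]], ord[[k]]] <- cfg$w_ordinal_self
    w[mem[[k]], mem[[k]]] <- cfg$w_memory_self
    w[ord[[k]], mem[[k]]] <- cfg$w_ordinal_memory
    w[mem[[k]], ord[[k]]] <- cfg$w_memory_own
    if (k < K) w[mem[[k]], ord[[k + 1L]]] <- cfg$w_memory_next
    for (l in seq_len(K)) if (l != k)
      w[ord[[k]], ord[[l]]] <- cfg$w_ordinal_inh
    w[cos, ord[[k]]] <- cfg$w_cos_ordinal
    w[reset, mem[[k]]] <- cfg$w_reset_memory
  }

  wta <- wta_config(pattern = cfg$content_pattern,
                    excitatory_radius = cfg$content_radius,
                    self_weight = cfg$w_content_exc,
                    neighbor_weight = cfg$w_content_exc,
                    inhibition_weight = cfg$w_content_inh)
  if (cfg$content_pattern == "lateral") {
    w[content, content] <- build_wta_lateral(cfg$content_size, wta)
  } else {
    cinh <- layout_range(layout, "content_inh") + 1L
    wp <- build_wta_pool(cfg$content_size, length(cinh), wta)
    w[c(content, cinh), c(content, cinh)] <- wp
  }

  if (cfg$cos_mode == "dvs") {
    dvs_on <- layout_range(layout, "dvs_on") + 1L
    w[content, cos] <- cfg$w_content_cos
    # recurrent CoS excitation amplifies the content-driven ignition in the
    # laser-off gaps without making the group self-sustaining on its own
    w[cos, cos] <- cfg$w_content_cos
    w[dvs_on, cos] <- cfg$w_dvs_cos
  }

  plastic <- initialize_plastic_matrix(layout,
                                       recurrent_potentiated_fraction =
                                         cfg$plastic_fraction,
                                       params = cfg$plasticity,
                                       gain = cfg$plastic_gain,
                                       seed = seed)
  structure(list(layout = layout, static_w = w, plastic = plastic,
                 weight_table = cfg$weight_table, neuron = neuron,
                 config = cfg),
            class = "snn_network")
}

#' Content-item regions of a serial-order network
#'
#' Each item label owns the content cells closer to its center than to any
#' other center (the Voronoi partition of the field); with equally spaced
#' centers the regions are disjoint, equally sized and cover the whole field.
#'
#' @param network An `snn_network` (or a `serial_order_config` plus layout).
#' @return Named list of integer vectors of absolute 0-based neuron indices.
#' @export
item_regions <- function(network) {
  stopifnot(inherits(network, "snn_network"))
  cfg <- network$config
  content <- layout_range(network$layout, "content_exc")
  cells <- seq_len(cfg$content_size) - 1L
  owner <- vapply(cells, function(j)
    which.min(abs(j - cfg$item_centers)), integer(1))
  out <- lapply(seq_along(cfg$item_centers), function(k)
    content[1] + cells[owner == k])
  names(out) <- cfg$item_labels
  out
}

#' Absolute content neuron index of an item center
#' @param network An `snn_network`.
#' @param label Item label (e.g. `"A"`).
#' @return Absolute 0-based neuron index (may be fractional for even fields).
#' @export
item_center <- function(network, label) {
  cfg <- network$config
  k <- match(label, cfg$item_labels)
  if (is.na(k)) stop("unknown item label '", label, "'")
  layout_range(network$layout, "content_exc")[1] + cfg$item_centers[k]
}

#' @export
print.snn_network <- function(x, ...) {
  cat("<snn_network> ", n_neurons(x$layout), " neurons, ",
      x$config$n_items, "-item serial-order architecture (cos_mode = ",
      x$config$cos_mode, ")\n", sep = "")
  print(x$layout)
  cat("  static synapses: ", sum(x$static_w != 0),
      " | plastic: ", sum(x$plastic$exists),
      " (learnable ", sum(x$plastic$learn), ")\n", sep = "")
  invisible(x)
}
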