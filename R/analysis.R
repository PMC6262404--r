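#' Detect activity bumps in a population raster
#'
#' Computes binned per-neuron population rates (bin width `window`), finds
#' contiguous supra-threshold neuron runs in each bin, and links runs across
#' consecutive bins into bumps when their neuron ranges overlap. A
#' sub-threshold gap of at least one window terminates a bump.
#'
#' @param raster A [spike_raster()].
#' @param layout A [population_layout()].
#' @param window Rate window (ms).
#' @param rate_threshold Per-neuron rate threshold (Hz).
#' @param population Population to analyse (default the content field).
#' @return A data.frame with one row per bump: `onset`, `offset` (ms),
#'   `center` (spike-weighted mean neuron index, absolute), `width` (mean
#'   supra-threshold run width, neurons), `mass` (total spikes).
#' @export
detect_bumps <- function(raster, layout, window = 100, rate_threshold = 40,
                         population = "content_exc") {
  stopifnot(inherits(raster, "spike_raster"))
  if (window <= 0) stop("window must be > 0")
  neurons <- layout_range(layout, population)
  duration <- attr(raster, "duration")
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      center = numeric(0), width = numeric(0),
                      mass = numeric(0))
  n_bins <- floor(duration / window)
  if (n_bins < 1 || nrow(raster) == 0) return(empty)

  sel <- raster$neuron %in% neurons & raster$time < n_bins * window
  if (!any(sel)) return(empty)
  sp <- raster[sel, ]
  ni <- match(sp$neuron, neurons)            # 1..length(neurons)
  bi <- floor(sp$time / window) + 1L         # 1..n_bins
  counts <- matrix(0L, length(neurons), n_bins)
  tab <- table(factor(ni, levels = seq_along(neurons)),
               factor(bi, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  rates <- counts / window * 1000

  bumps <- list()        # finished
  active <- list()       # each: range=c(lo,hi), last_bin, counts (per neuron), widths
  for (b in seq_len(n_bins)) {
    above <- rates[, b] >= rate_threshold
    segs <- list()
    r <- rle(above)
    pos <- cumsum(c(1L, r$lengths))
    for (q in seq_along(r$values)) if (r$values[q])
      segs[[length(segs) + 1L]] <- c(pos[q], pos[q + 1L] - 1L)

    new_active <- list()
    used <- rep(FALSE, length(segs))
    for (a in active) {
      if (a$last_bin != b - 1L) { bumps[[length(bumps) + 1L]] <- a; next }
      best <- 0L; best_ov <- 0L
      for (si in seq_along(segs)) {
        if (used[si]) next
        ov <- min(a$range[2], segs[[si]][2]) - max(a$range[1], segs[[si]][1]) + 1L
        if (ov > best_ov) { best_ov <- ov; best <- si }
      }
      if (best > 0L) {
        s <- segs[[best]]; used[best] <- TRUE
        idx <- s[1]:s[2]
        a$range <- s
        a$last_bin <- b
        a$counts[idx] <- a$counts[idx] + counts[idx, b]
        a$widths <- c(a$widths, length(idx))
        new_active[[length(new_active) + 1L]] <- a
      } else {
        bumps[[length(bumps) + 1L]] <- a
      }
    }
    for (si in seq_along(segs)) {
      if (used[si]) next
      s <- segs[[si]]
      cnt <- numeric(length(neurons))
      idx <- s[1]:s[2]
      cnt[idx] <- counts[idx, b]
      new_active[[length(new_active) + 1L]] <-
        list(range = s, first_bin = b, last_bin = b, counts = cnt,
             widths = length(idx))
    }
    active <- new_active
  }
  for (a in active) bumps[[length(bumps) + 1L]] <- a
  if (!length(bumps)) return(empty)

  out <- do.call(rbind, lapply(bumps, function(a) {
    mass <- sum(a$counts)
    data.frame(onset = (a$first_bin - 1L) * window,
               offset = a$last_bin * window,
               center = sum(a$counts * neurons) / mass,
               width = mean(a$widths),
               mass = mass)
  }))
  out[order(out$onset), , drop = FALSE]
}

#' Decode an item sequence from a raster
#'
#' Detects content-field bumps and assigns each to the item region containing
#' its center. The confidence of an assignment is the fraction of the bump's
#' spike mass that falls inside the region; bumps whose center lies outside
#' every region, or whose confidence falls below the threshold, are flagged
#' unassigned (label `NA`) rather than guessed. Bumps are ordered by onset.
#' Each bump is also matched to the ordinal group most active during its
#' lifetime.
#'
#' @param raster A [spike_raster()].
#' @param layout A [population_layout()].
#' @param regions Named list of absolute 0-based neuron index vectors, one
#'   per item label (see [item_regions()]). Regions must be disjoint.
#' @param window,rate_threshold Bump detection parameters.
#' @param confidence_threshold Minimum confidence for an assignment.
#' @return A data.frame with one row per bump: `label` (NA if unassigned),
#'   `onset`, `offset`, `center`, `confidence`, `ordinal` (matched ordinal
#'   group, NA if none active).
#' @export
decode_sequence <- function(raster, layout, regions, window = 100,
                            rate_threshold = 40,
                            confidence_threshold = 0.5) {
  all_idx <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(all_idx))
    stop("item regions overlap; they must be disjoint")
  bumps <- detect_bumps(raster, layout, window, rate_threshold)
  if (nrow(bumps) == 0)
    return(data.frame(label = character(0), onset = numeric(0),
                      offset = numeric(0), center = numeric(0),
                      confidence = numeric(0), ordinal = integer(0)))
  content <- layout_range(layout, "content_exc")
  groups <- ordinal_groups(layout)

  res <- lapply(seq_len(nrow(bumps)), function(i) {
    b <- bumps[i, ]
    inwin <- raster$time >= b$onset & raster$time < b$offset
    csp <- raster$neuron[inwin & raster$neuron %in% content]
    lab <- NA_character_
    conf <- NA_real_
    hit <- which(vapply(regions, function(r)
      floor(b$center) %in% r || ceiling(b$center) %in% r, logical(1)))
    if (length(hit)) {
      lab <- names(regions)[hit[1]]
      conf <- mean(csp %in% regions[[hit[1]]])
      if (is.nan(conf) || conf < confidence_threshold) {
        lab <- NA_character_
      }
    }
    gr <- NA_integer_
    if (length(groups)) {
      gr_rates <- vapply(groups, function(g)
        mean_rate(raster, layout_range(layout, "ordinal", g),
                  b$onset, b$offset), numeric(1))
      if (max(gr_rates) >= 20) gr <- groups[which.max(gr_rates)]
    }
    data.frame(label = lab, onset = b$onset, offset = b$offset,
               center = b$center, confidence = conf, ordinal = gr)
  })
  do.call(rbind, res)
}

#' Score a probed plastic matrix against the item-region blocks
#'
#' Summarizes a 0/1 probe matrix at block level: for every (ordinal group,
#' item region) pair, the fraction of potentiated entries in the
#' corresponding block of the ordinal-to-content matrix; the winner item of
#' each group is the region with the largest fraction. Entries of the
#' ordinal-to-content matrix outside every item-region column count as
#' off-block noise.
#'
#' @param probe 0/1 matrix from [probe_plastic_weights()].
#' @param layout A [population_layout()].
#' @param regions Named list of absolute item-region indices
#'   (see [item_regions()]).
#' @return An object of class `probe_score`: list with `fractions` (groups x
#'   regions matrix), `winners` (named character vector, NA when a group has
#'   no potentiated entries), `off_block_noise` (scalar fraction).
#' @export
score_probe <- function(probe, layout, regions) {
  groups <- ordinal_groups(layout)
  content <- layout_range(layout, "content_exc")
  fr <- matrix(NA_real_, length(groups), length(regions),
               dimnames = list(paste0("ordinal_", groups), names(regions)))
  for (gi in seq_along(groups)) {
    ord <- layout_range(layout, "ordinal", groups[gi])
    for (ri in seq_along(regions))
      fr[gi, ri] <- mean(probe[ord + 1L, regions[[ri]] + 1L])
  }
  winners <- apply(fr, 1, function(x)
    if (all(x == 0)) NA_character_ else colnames(fr)[which.max(x)])
  off_cols <- setdiff(content, unlist(regions, use.names = FALSE))
  off <- if (length(off_cols)) {
    ords <- unlist(lapply(groups, function(g)
      layout_range(layout, "ordinal", g)))
    mean(probe[ords + 1L, off_cols + 1L])
  } else NA_real_
  structure(list(fractions = fr, winners = winners, off_block_noise = off),
            class = "probe_score")
}

#' @export
print.probe_score <- function(x, ...) {
  cat("<probe_score>\n")
  print(round(x$fractions, 3))
  cat("winners:", paste(names(x$winners), x$winners, sep = "->",
                        collapse = ", "), "\n")
  cat("off-block noise:", round(x$off_block_noise, 4), "\n")
  invisible(x)
}
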