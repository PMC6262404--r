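#' Plot a spike raster
#'
#' Base-graphics raster plot; when the raster carries a population layout,
#' populations are separated by horizontal rules and colored, with labels in
#' the margin.
#'
#' @param x A [spike_raster()].
#' @param y Ignored.
#' @param pch,cex Point style.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.spike_raster <- function(x, y = NULL, pch = ".", cex = 1.5, ...) {
  n <- attr(x, "n_neurons")
  lay <- attr(x, "layout")
  op <- graphics::par(mar = c(4, 4, 1, if (is.null(lay)) 1 else 7))
  on.exit(graphics::par(op))
  cols <- "black"
  if (!is.null(lay)) {
    pal <- grDevices::hcl.colors(max(2L, nrow(lay)), "Dark 3")
    pop_of <- rep(NA_integer_, n)
    for (i in seq_len(nrow(lay)))
      if (lay$size[i] > 0)
        pop_of[lay$start[i] + seq_len(lay$size[i])] <- i
    cols <- pal[pop_of[x$neuron + 1L]]
  }
  graphics::plot(x$time, x$neuron, pch = pch, cex = cex, col = cols,
                 xlim = c(0, attr(x, "duration")), ylim = c(0, n),
                 xlab = "time (ms)", ylab = "neuron index", ...)
  if (!is.null(lay)) {
    graphics::abline(h = lay$start[-1], col = "grey80", lty = 3)
    graphics::mtext(lay$population, side = 4, las = 1, cex = 0.7,
                    at = lay$start + lay$size / 2, line = 0.5,
                    col = pal[seq_len(nrow(lay))])
  }
  invisible(x)
}
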