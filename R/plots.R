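#' Manhattan-style plot of a genome scan
#'
#' LR profile against cumulative map position, linkage groups in alternating
#' shades, with a dashed line at the permutation genome-wide threshold when
#' one is attached.
#'
#' @param scan a \linkS4class{ScanResult}.
#' @param ... further arguments to \code{plot}.
#' @return Invisibly, the plotted data.frame with a \code{cumPos} column.
#' @export
plotScan <- function(scan, ...) {
  stopifnot(is(scan, "ScanResult"))
  f <- lrProfile(scan)
  lgs <- unique(f$lg)
  offset <- 0
  f$cumPos <- NA_real_
  for (g in lgs) {
    i <- f$lg == g
    f$cumPos[i] <- f$pos[i] + offset
    offset <- max(f$cumPos[i]) + 5
  }
  cols <- c("grey30", "steelblue")[(match(f$lg, lgs) %% 2) + 1]
  lr <- f$LR
  lr[!is.finite(lr)] <- max(lr[is.finite(lr)], 1)
  graphics::plot(f$cumPos, lr, col = cols, pch = 16, cex = 0.5,
                 xlab = "map position (cM, linkage groups concatenated)",
                 ylab = "LR", main = sprintf("genome scan: %s", scan@trait), ...)
  if (!is.na(threshold(scan)))
    graphics::abline(h = threshold(scan), lty = 2, col = "blue")
  invisible(f)
}

#' Plot a correlation network on a circular layout
#'
#' Nodes on a circle (grouped by module when tags are supplied), edge width
#' proportional to |r|, blue for positive and orange for negative
#' correlations.
#'
#' @param edges edge data.frame with node_a, node_b, r.
#' @param modules optional named vector node -> module for colouring.
#' @param main plot title.
#' @export
plotNetworkEdges <- function(edges, modules = NULL, main = "correlation network") {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  if (!is.null(modules))
    nodes <- nodes[order(modules[nodes], nodes)]
  if (!length(nodes)) {
    graphics::plot.new()
    graphics::title(main = paste(main, "(no edges)"))
    return(invisible(NULL))
  }
  ang <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  xy <- cbind(cos(ang), sin(ang))
  rownames(xy) <- nodes
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), axes = FALSE,
                 xlab = "", ylab = "", asp = 1, main = main)
  for (i in seq_len(nrow(edges)))
    graphics::segments(xy[edges$node_a[i], 1], xy[edges$node_a[i], 2],
                       xy[edges$node_b[i], 1], xy[edges$node_b[i], 2],
                       lwd = 0.5 + 3 * abs(edges$r[i]),
                       col = if (edges$r[i] >= 0) "steelblue" else "darkorange")
  mod_col <- if (is.null(modules)) "grey40"
             else c(size = "goldenrod", shape = "grey40",
                    color = "steelblue")[modules[nodes]]
  graphics::points(xy, pch = 21, bg = mod_col, cex = 2)
  graphics::text(xy * 1.15, labels = nodes, cex = 0.7)
  invisible(xy)
}
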