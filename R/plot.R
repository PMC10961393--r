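#' Visual-field graph plot of significant edges
#'
#' Draws vertices at their visual-field coordinates and the significant edges
#' of a weight-map summary as lines colored by the level they support
#' (warm = positive-coded level, cool = the other), in the style of the
#' projected-graph weight-map figures.
#'
#' @param summary a [summarize_maps()] result.
#' @param map the retinotopic map.
#' @param main plot title.
#' @export
plot_weight_graph <- function(summary, map, main = "Significant edges") {
  ei <- edge_index(nrow(map))
  graphics::plot(map$vf_x, map$vf_y, pch = 16, cex = 0.4, col = "grey60",
                 asp = 1, xlab = "x (DVA)", ylab = "y (DVA)", main = main)
  graphics::symbols(0, 0, circles = 0.2, inches = FALSE, add = TRUE,
                    bg = "grey80", fg = NA)
  graphics::abline(h = 0, v = 0, col = "grey85", lty = 3)
  draw <- function(idx, col) {
    for (e in idx)
      graphics::segments(map$vf_x[ei[e, 1]], map$vf_y[ei[e, 1]],
                         map$vf_x[ei[e, 2]], map$vf_y[ei[e, 2]],
                         col = col, lwd = 1.2)
  }
  draw(summary$significant_edges$negative, grDevices::adjustcolor("steelblue", 0.7))
  draw(summary$significant_edges$positive, grDevices::adjustcolor("firebrick", 0.7))
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("firebrick", "steelblue"),
                   legend = c(summary$positive_level,
                              paste0("not ", summary$positive_level)))
  invisible(NULL)
}

#' @export
plot.gaze_heatmap <- function(x, ...) {
  graphics::image(t(x$grid)[, rev(seq_len(nrow(x$grid)))],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, asp = nrow(x$grid) / ncol(x$grid), ...)
  graphics::box()
  invisible(x)
}

#' @export
plot.navon_stimulus <- function(x, ...) {
  graphics::image(t(x$raster)[, rev(seq_len(nrow(x$raster)))],
                  col = c("black", "white"), axes = FALSE,
                  asp = nrow(x$raster) / ncol(x$raster), ...)
  invisible(x)
}
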