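# Figures: ternary trait plot and PCoA ordination (base graphics).

#' Ternary plot of carbon-preference traits
#'
#' Draws the unit-side triangle (cellulose, starch, sucrose vertices) and the
#' ASV positions, coloring by class label. Following the framework's plotting
#' convention, ASVs depleted under all three carbons (`triple-`) are omitted.
#'
#' @param assignments output of [assign_traits()].
#' @param main plot title.
#' @export
plot_ternary <- function(assignments, main = "Carbon-preference traits") {
  keep <- assignments$class_label != "triple-"
  a <- assignments[keep, , drop = FALSE]
  xy <- ternary_xy(a)
  cols <- c("none" = "grey70", "triple+" = "black",
            "single+" = "#1b9e77", "single-" = "#d95f02", "mixed" = "#7570b3")
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.1, sqrt(3) / 2 + 0.05),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(0, 0))
  graphics::lines(tri)
  graphics::text(c(0, 1, 0.5), c(-0.05, -0.05, sqrt(3) / 2 + 0.04),
                 c("C-ness", "St-ness", "Su-ness"))
  graphics::points(xy$x, xy$y, pch = 19, cex = 0.6,
                   col = cols[a$class_label])
  invisible(xy)
}

#' PCoA ordination plot
#'
#' First two principal coordinates with axis labels carrying the proportion of
#' (positive) eigenvalue variance explained.
#'
#' @param ord output of [pcoa()].
#' @param groups optional grouping vector for point colors.
#' @param main plot title.
#' @export
plot_pcoa <- function(ord, groups = NULL, main = "PCoA (Bray-Curtis)") {
  co <- ord$coordinates
  if (ncol(co) < 2) stop("fewer than 2 positive axes")
  pe <- 100 * ord$prop_explained[1:2]
  col <- if (is.null(groups)) "black" else as.integer(as.factor(groups))
  graphics::plot(co[, 1], co[, 2], pch = 19, col = col, asp = 1, main = main,
                 xlab = sprintf("Axis 1 (%.1f%%)", pe[1]),
                 ylab = sprintf("Axis 2 (%.1f%%)", pe[2]))
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(as.factor(groups)),
                     col = seq_len(nlevels(as.factor(groups))), pch = 19, cex = 0.8)
  }
  invisible(co)
}
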