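category_palette <- function() {
  c(affective = "#D55E00", cognitive = "#0072B2", arousal_somatic = "#009E73",
    sleep = "#CC79A7", insight = "#999999")
}

#' Plot direct-effect trajectories
#'
#' Line chart of the treatment-edge weight per symptom over the assessment
#' weeks, colored by symptom category (negative = beneficial).
#'
#' @param traj a `direct_effect_trajectory`.
#' @param items item battery for category colors (default [hdrs_items()]).
#' @param ... passed to [graphics::matplot()].
#' @return `traj`, invisibly.
#' @export
plot_direct_effects <- function(traj, items = hdrs_items(), ...) {
  pal <- category_palette()
  cats <- items$category[match(traj$symptoms, items$name)]
  cols <- pal[cats]
  graphics::matplot(traj$weeks, traj$values, type = "b", pch = 16, lty = 1,
                    col = cols, xlab = "week",
                    ylab = "direct treatment effect (edge weight)", ...)
  graphics::abline(h = 0, col = "grey70", lty = 2)
  graphics::legend("bottomleft", legend = names(pal), col = pal, lty = 1,
                   pch = 16, cex = 0.8, bty = "n")
  invisible(traj)
}

#' Plot a symptom network on a category-grouped circle
#'
#' Nodes are placed on a fixed circle grouped by symptom category, with the
#' treatment node at the center; edge width scales with |weight|, red =
#' negative, blue = positive (no force-directed layout).
#'
#' @param x a `network_model`.
#' @param items item battery for grouping (default [hdrs_items()]).
#' @param min_weight hide edges below this magnitude (default 0).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.network_model <- function(x, items = hdrs_items(), min_weight = 0, ...) {
  tr <- treatment_node(x)
  symptoms <- setdiff(x$nodes, tr)
  ord <- order(match(items$category[match(symptoms, items$name)],
                     names(category_palette())))
  symptoms <- symptoms[ord]
  ang <- seq(0, 2 * pi, length.out = length(symptoms) + 1)[-1]
  pos <- rbind(c(0, 0), cbind(cos(ang), sin(ang)))
  rownames(pos) <- c(tr, symptoms)
  graphics::plot(NA, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), axes = FALSE,
                 xlab = "", ylab = "", asp = 1)
  ed <- network_edges(x)
  ed <- ed[abs(ed$weight) >= min_weight, , drop = FALSE]
  if (nrow(ed)) {
    for (i in seq_len(nrow(ed))) {
      a <- pos[ed$node_a[i], ]; b <- pos[ed$node_b[i], ]
      graphics::segments(a[1], a[2], b[1], b[2],
                         lwd = 0.5 + 8 * abs(ed$weight[i]),
                         col = if (isTRUE(ed$weight[i] < 0)) "#D55E0088" else "#0072B288")
    }
  }
  pal <- category_palette()
  cols <- c("black", pal[items$category[match(symptoms, items$name)]])
  graphics::points(pos, pch = c(15, rep(21, length(symptoms))), cex = 2.2,
                   bg = cols, col = "black")
  graphics::text(pos * 1.18, labels = rownames(pos), cex = 0.6)
  invisible(x)
}
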