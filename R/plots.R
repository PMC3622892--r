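# Base-graphics display methods for maps, orbits and state fields.

#' @export
plot.stmap <- function(x, col = grDevices::hcl.colors(64, "viridis"),
                       xlab = "Time (s)", ylab = "Position (cm)", ...) {
  graphics::image(x$times, x$positions, t(x$values), col = col,
                  xlab = xlab, ylab = ylab, main = x$quantity,
                  ylim = rev(range(x$positions)), ...)
  invisible(x)
}

#' Overlay display of a composite map
#'
#' Diameter in magenta and pressure in green, each normalised to its robust
#' range, composited as an RGB raster (time on x, oral end on top).
#'
#' @param x a [composite_map()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.composite_map <- function(x, ...) {
  norm01 <- function(v) {
    q <- stats::quantile(v, c(0.02, 0.98), na.rm = TRUE, names = FALSE)
    pmin(pmax((v - q[1]) / max(q[2] - q[1], 1e-12), 0), 1)
  }
  d <- norm01(x$diameter$values)
  p <- norm01(x$pressure$values)
  d[is.na(d)] <- 0; p[is.na(p)] <- 0
  img <- array(0, dim = c(dim(d), 3))
  img[, , 1] <- d          # magenta = red + blue
  img[, , 3] <- d
  img[, , 2] <- p          # green
  tr <- range(x$diameter$times); pr <- range(x$diameter$positions)
  graphics::plot(NA, xlim = tr, ylim = rev(pr), xlab = "Time (s)",
                 ylab = "Position (cm)", main = "Composite DP map", ...)
  graphics::rasterImage(img, tr[1], pr[2], tr[2], pr[1], interpolate = FALSE)
  invisible(x)
}

#' @export
plot.state_map <- function(x, ...) {
  pal <- unname(state_palette())
  graphics::image(x$times, x$positions, t(x$codes), col = pal,
                  breaks = seq(-0.5, 11.5, by = 1), xlab = "Time (s)",
                  ylab = "Position (cm)", main = "Mechanical states",
                  ylim = rev(range(x$positions)), ...)
  invisible(x)
}

#' @export
plot.clustered_map <- function(x, ...) {
  codes <- matrix(match(x$classes, c("ACTIVE_CONTRACTION", "ACTIVE_RELAXATION",
                                     "OTHER")), nrow(x$classes))
  graphics::image(x$times, x$positions, t(codes),
                  col = c("#d7191c", "#2c7bb6", "#000000"),
                  breaks = c(0.5, 1.5, 2.5, 3.5), xlab = "Time (s)",
                  ylab = "Position (cm)", main = "Active excitation / inhibition",
                  ylim = rev(range(x$positions)), ...)
  invisible(x)
}

#' @export
plot.orbit <- function(x, segments = NULL, ...) {
  cols <- grDevices::hcl.colors(nrow(x), "Blue-Red")
  graphics::plot(x$diameter, x$pressure, type = "l", col = "grey70",
                 xlab = "Diameter (mm)", ylab = "Pressure (mmHg)",
                 main = "Pressure-diameter orbit", ...)
  graphics::points(x$diameter, x$pressure, col = cols, pch = 16, cex = 0.6)
  if (!is.null(segments))
    graphics::points(x$diameter[segments$start], x$pressure[segments$start],
                     pch = 4, cex = 1.2)
  invisible(x)
}
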