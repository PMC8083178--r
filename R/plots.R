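#' Plot an interaction profile
#'
#' Two stacked panels per anchor: the distance-weighted intensity track
#' (intensity times |offset|, a display transform only — statistics always
#' use raw intensities) and the -log10 q-value track with a horizontal
#' line at the significance threshold.
#'
#' @param profile a scored `interaction_profile` (with `q` filled).
#' @param alpha significance threshold drawn as `-log10(alpha)`.
#' @param title plot title (default the anchor name).
#' @param ticks x-axis tick spacing in bins (default 5).
#' @param colors length-2 vector: intensity colour, q-value colour.
#' @return invisibly, `NULL`; draws on the active device.
#' @export
plot_profile <- function(profile, alpha = 0.01, title = NULL, ticks = 5L,
                         colors = c("steelblue", "firebrick")) {
  stopifnot(inherits(profile, "interaction_profile"))
  if (is.null(title)) title <- sprintf("anchor %s", profile$anchor_name)
  delta <- profile$delta
  w_int <- profile$intensity * abs(delta)
  nlq <- -log10(pmax(profile$q, 1e-300))
  old <- graphics::par(mfrow = c(2L, 1L), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  at <- delta[delta %% ticks == 0]
  graphics::plot(delta, w_int, type = "h", lwd = 3, col = colors[1],
                 xlab = "", ylab = "intensity x |offset|", main = title,
                 xaxt = "n")
  graphics::axis(1L, at = at)
  graphics::plot(delta, nlq, type = "p", pch = 16, col = colors[2],
                 xlab = "bin offset", ylab = "-log10 q", xaxt = "n")
  graphics::axis(1L, at = at)
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(NULL)
}

#' Triangular map plot of domain-level significance
#'
#' Renders the raw contact frequencies in the upper-left triangle and
#' `-log10 q` of the domain pairs as filled blocks in the lower-right
#' triangle, the two-in-one view used for domain-mode results.
#'
#' @param map the [hic_map()] the calls were made on.
#' @param calls a [call_domain_interactions()] result.
#' @param title plot title.
#' @param ticks axis tick spacing in bins (default 10).
#' @param colors length-2 vector of ramp end colours for the q-value
#'   triangle.
#' @return invisibly, `NULL`; draws on the active device.
#' @export
plot_domain_map <- function(map, calls, title = "domain interactions",
                            ticks = 10L, colors = c("white", "firebrick")) {
  stopifnot(inherits(map, "hic_map"))
  n <- map$n_bins
  upper <- log1p(map$matrix)
  disp <- matrix(NA_real_, n, n)
  disp[upper.tri(disp, diag = TRUE)] <- upper[upper.tri(upper, diag = TRUE)]
  graphics::image(x = 0:n, y = 0:n, z = t(disp)[, n:1],
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  xlab = "bin", ylab = "bin", main = title, axes = FALSE,
                  useRaster = TRUE)
  at <- seq(0, n, by = ticks)
  graphics::axis(1L, at = at, labels = at)
  graphics::axis(2L, at = at, labels = rev(n - at))
  nlq <- -log10(pmax(calls$q, 1e-300))
  if (nrow(calls) > 0L) {
    ramp <- grDevices::colorRamp(colors)
    rel <- nlq / max(nlq, 1)
    dm <- attr(calls, "domain_matrix")
    res <- map$resolution
    for (r in seq_len(nrow(calls))) {
      bi <- c(dm$domains$bin_start[calls$i[r]],
              dm$domains$bin_end[calls$i[r]] + 1L)
      bj <- c(dm$domains$bin_start[calls$j[r]],
              dm$domains$bin_end[calls$j[r]] + 1L)
      rgb <- ramp(rel[r]) / 255
      graphics::rect(bj[1], n - bi[2], bj[2], n - bi[1],
                     col = grDevices::rgb(rgb[1], rgb[2], rgb[3]),
                     border = NA)
    }
  }
  invisible(NULL)
}

# Render a plotting closure to PNG and SVG next to each other.
render_plot <- function(draw, path_base, width = 7, height = 6) {
  png_path <- paste0(path_base, ".png")
  grDevices::png(png_path, width = width * 100, height = height * 100,
                 res = 100)
  draw()
  grDevices::dev.off()
  svg_path <- paste0(path_base, ".svg")
  grDevices::svg(svg_path, width = width, height = height)
  draw()
  grDevices::dev.off()
  c(png_path, svg_path)
}
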