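#' Plot a composition profile
#'
#' Muscle and collagen relative percentages along the strip, with optional
#' transition-call shading.
#'
#' @param x a [composition_profile()].
#' @param calls optional list of transition calls.
#' @param ... passed to [graphics::plot()].
#' @export
plot.composition_profile <- function(x, calls = NULL, ...) {
  plot(x$position_mm, x$pct_muscle, type = "b", pch = 16, col = "firebrick",
       ylim = c(0, 100), xlab = "position (mm, PM end = 0)",
       ylab = "relative composition (%)", ...)
  lines(x$position_mm, x$pct_collagen, type = "b", pch = 17,
        col = "steelblue")
  if (!is.null(calls)) for (cl in calls)
    rect(cl$start_mm, -4, cl$end_mm, 104, border = NA,
         col = grDevices::adjustcolor("purple", 0.12))
  legend("right", c("muscle", "collagen"), pch = c(16, 17),
         col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Plot a molecular strain heatmap
#'
#' Position x engineering-strain-level heatmap of percent molecular strain
#' (collagen D-period change from rest), unsmoothed.
#'
#' @param x a [molecular_strain_map()].
#' @param ... passed to [graphics::image()].
#' @export
plot.molecular_strain_map <- function(x, ...) {
  image(x = x$positions, y = x$levels, z = x$strain,
        col = hcl.colors(64, "viridis"),
        xlab = "position (mm)", ylab = "engineering strain (%)", ...)
  invisible(x)
}

#' Plot regional stress-strain curves
#'
#' @param curves named list of [stress_strain_curve()] objects.
#' @param ... passed to [graphics::plot()].
#' @export
plot_stress_strain <- function(curves, ...) {
  cols <- setNames(hcl.colors(length(curves), "Dark 3"), names(curves))
  xr <- range(unlist(lapply(curves, `[[`, "strain_pct")), na.rm = TRUE)
  yr <- range(unlist(lapply(curves, `[[`, "stress_mpa")), na.rm = TRUE)
  plot(NA, xlim = xr, ylim = yr, xlab = "engineering strain (%)",
       ylab = "stress (MPa)", ...)
  for (nm in names(curves))
    lines(curves[[nm]]$strain_pct, curves[[nm]]$stress_mpa, col = cols[nm],
          lwd = 1.5)
  legend("topleft", names(curves), col = cols, lwd = 1.5, bty = "n")
  invisible(curves)
}

#' Plot an orientation-ellipse map along the strip
#'
#' One ellipse per scan point: major axis along the fiber direction, minor
#' axis inversely proportional to the angular spread; isotropic points are
#' drawn as dots.
#'
#' @param fit_table data frame with `position_mm`, `angle_deg`,
#'   `spread_deg`, `isotropic` (e.g. from [run_xrd_scan()]).
#' @param kappa minor-axis scale, degrees (matches [orientation()]).
#' @param radius_mm ellipse major radius in plot units.
#' @param ... passed to [graphics::plot()].
#' @export
plot_orientation_map <- function(fit_table, kappa = 5, radius_mm = 1, ...) {
  plot(fit_table$position_mm, rep(0, nrow(fit_table)), type = "n",
       ylim = c(-2, 2), xlab = "position (mm)", ylab = "", yaxt = "n", ...)
  th <- seq(0, 2 * pi, length.out = 60)
  for (i in seq_len(nrow(fit_table))) {
    x0 <- fit_table$position_mm[i]
    if (isTRUE(fit_table$isotropic[i]) || is.na(fit_table$angle_deg[i])) {
      points(x0, 0, pch = 16, cex = 0.7)
      next
    }
    a <- radius_mm
    b <- a * min(1, kappa / fit_table$spread_deg[i])
    ang <- fit_table$angle_deg[i] * pi / 180
    xs <- a * cos(th) * cos(ang) - b * sin(th) * sin(ang)
    ys <- a * cos(th) * sin(ang) + b * sin(th) * cos(ang)
    polygon(x0 + xs, ys, border = "darkgreen")
  }
  invisible(fit_table)
}
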