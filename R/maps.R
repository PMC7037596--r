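#' Relative muscle/collagen composition along the strip
#'
#' Converts per-point collagen 5th-order and muscle (1,1) fitted areas into
#' the relative percentage composition
#' `pct_muscle = 100 * I11 / (I11 + w * I5)`. This is a *relative* measure
#' of the two load-bearing components, not an absolute mass fraction. `w` is
#' the muscle/collagen intensity calibration weight (default 1). Points
#' where both intensities vanish are masked (`NA`) and flagged.
#'
#' @param fit_table data frame from [reduce_frame()] / [run_xrd_scan()]
#'   (one strain level; typically the resting scan).
#' @param w calibration weight.
#' @return A `composition_profile` data frame: `position_mm`, `pct_muscle`,
#'   `pct_collagen`, `masked`.
#' @export
composition_profile <- function(fit_table, w = 1) {
  if (w <= 0) stop("calibration weight must be positive")
  I11 <- fit_table$I11_area
  I5 <- fit_table$I5_area
  tot <- I11 + w * I5
  pct <- ifelse(tot > 0, 100 * I11 / tot, NA_real_)
  out <- data.frame(position_mm = fit_table$position_mm,
                    pct_muscle = pct,
                    pct_collagen = 100 - pct,
                    masked = tot <= 0)
  out <- out[order(out$position_mm), ]
  rownames(out) <- NULL
  attr(out, "w") <- w
  class(out) <- c("composition_profile", "data.frame")
  out
}

#' Molecular strain map (position x engineering-strain level)
#'
#' Molecular strain of each tracked point is the percent change of its
#' collagen D-period relative to the resting state (minimum load):
#' `eps_mol(x, s) = 100 * (D(x, s) - D(x, 0)) / D(x, 0)`. Points are tracked
#' by identity (`point_id`) across levels; the resting level must be
#' present.
#'
#' @param fit_table data frame from [run_xrd_scan()] covering all levels
#'   (columns `point_id`, `position_mm`, `eng_strain_pct`, `D_nm`).
#' @return A `molecular_strain_map`: list with `positions` (mm, resting),
#'   `levels` (percent engineering strain), `strain` (position x level
#'   matrix, percent molecular strain).
#' @export
molecular_strain_map <- function(fit_table) {
  levels <- sort(unique(fit_table$eng_strain_pct))
  if (!any(levels == 0)) stop("resting (0%) level missing")
  ids <- sort(unique(fit_table$point_id))
  rest <- fit_table[fit_table$eng_strain_pct == 0, ]
  D0 <- rest$D_nm[match(ids, rest$point_id)]
  pos <- rest$position_mm[match(ids, rest$point_id)]
  if (any(is.na(D0)))
    stop("missing resting D-period for tracked point(s): ",
         paste(ids[is.na(D0)], collapse = ", "))
  strain <- matrix(NA_real_, length(ids), length(levels),
                   dimnames = list(point = ids, level = levels))
  for (j in seq_along(levels)) {
    lv <- fit_table[fit_table$eng_strain_pct == levels[j], ]
    D <- lv$D_nm[match(ids, lv$point_id)]
    strain[, j] <- 100 * (D - D0) / D0
  }
  strain[, levels == 0] <- 0   # resting is the reference by definition
  structure(list(positions = pos, levels = levels, strain = strain),
            class = "molecular_strain_map")
}

#' @export
print.molecular_strain_map <- function(x, ...) {
  cat(sprintf(
    "molecular_strain_map: %d tracked points x %d levels (%s%% eng strain)\n",
    length(x$positions), length(x$levels),
    paste(x$levels, collapse = ",")))
  invisible(x)
}

#' Molecular strain per unit thickness and predicted failure locus
#'
#' Normalizes the molecular strain at one engineering-strain level (default
#' the 10% series) by the local tissue thickness, `s(x) = eps_mol(x) / t(x)`
#' in percent/mm. The position of the maximum is returned as the predicted
#' point of breakage: thin, molecularly over-strained tissue is where tears
#' initiate.
#'
#' @param map a [molecular_strain_map()].
#' @param thickness either a data frame with `x`/`t` columns (mm) or a
#'   function of position; positions missing from a table are interpolated
#'   linearly and flagged.
#' @param level engineering-strain level, percent.
#' @return data frame (`position_mm`, `strain_pct`, `thickness_mm`,
#'   `strain_per_mm`) with attributes `argmax_mm` and `level`.
#' @export
strain_per_thickness <- function(map, thickness, level = 10) {
  j <- which(map$levels == level)
  if (!length(j)) stop("level ", level, " not present in the map")
  eps <- map$strain[, j]
  t_mm <- if (is.function(thickness)) thickness(map$positions)
  else {
    interp <- !map$positions %in% thickness$x
    approx(thickness$x, thickness$t, xout = map$positions, rule = 2)$y
  }
  if (any(t_mm <= 0)) stop("thickness must be positive")
  s <- eps / t_mm
  out <- data.frame(position_mm = map$positions, strain_pct = eps,
                    thickness_mm = t_mm, strain_per_mm = s)
  attr(out, "argmax_mm") <- map$positions[which.max(s)]
  attr(out, "level") <- level
  out
}

#' Call diffuse transition regions from composition (and orientation)
#'
#' The PM-CT transition is the interval over which the muscle percentage
#' falls from the muscle plateau to the collagen floor, scanning from the
#' PM end: the call spans the (linearly interpolated) crossing of `hi`
#' (default 80%) down to the crossing of `lo` (default 5%). The boundaries
#' are diffuse by nature, so the thresholds are declared conventions.
#'
#' The CT-LL boundary carries no composition contrast (both sides are
#' collagen), so it is called from the orientation signature: a contiguous
#' run of scan points whose fiber direction is rotated by more than 45
#' degrees from the chordae axis (the 90-degree-rotated collagen population
#' at the visible CT-LL junction). Without orientation data no CT-LL call
#' is made and a warning is raised.
#'
#' @param comp a [composition_profile()].
#' @param lo,hi percent-muscle thresholds.
#' @param orientation_table optional data frame with `position_mm`,
#'   `angle_deg` (e.g. the fit table of a 2D scan).
#' @param ct_axis chordae fiber direction, degrees.
#' @return list of `transition_call` objects (fields `kind`, `start_mm`,
#'   `end_mm`).
#' @export
call_transitions <- function(comp, lo = 5, hi = 80,
                             orientation_table = NULL, ct_axis = 90) {
  stopifnot(lo < hi)
  calls <- list()
  x <- comp$position_mm; p <- comp$pct_muscle
  ok <- !is.na(p)
  x <- x[ok]; p <- p[ok]
  cross_down <- function(th) {
    i <- which(p[-length(p)] >= th & p[-1] < th)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    x[i] + (p[i] - th) / (p[i] - p[i + 1]) * (x[i + 1] - x[i])
  }
  x_hi <- cross_down(hi); x_lo <- cross_down(lo)
  if (is.na(x_hi) || is.na(x_lo) || x_lo < x_hi) {
    if (any(p >= hi) || any(p <= lo))
      warning("no monotone muscle-to-collagen crossing: PM-CT not called")
  } else {
    calls <- c(calls, list(structure(
      list(kind = "PM-CT", start_mm = x_hi, end_mm = x_lo),
      class = "transition_call")))
  }
  if (is.null(orientation_table)) {
    warning("no orientation data: CT-LL transition not called")
  } else {
    ot <- orientation_table[order(orientation_table$position_mm), ]
    rot <- .axis_dist(ot$angle_deg, ct_axis) > 45 & !is.na(ot$angle_deg)
    if (!is.na(x_lo)) rot <- rot & ot$position_mm > x_lo
    if (any(rot)) {
      runs <- rle(rot)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      k <- which(runs$values)
      k <- k[which.max(runs$lengths[k])]
      # pad by half the scan spacing: the rotated population extends between
      # sampled points
      dx <- if (length(ot$position_mm) > 1) median(diff(ot$position_mm)) / 2
            else 0
      calls <- c(calls, list(structure(
        list(kind = "CT-LL",
             start_mm = ot$position_mm[starts[k]] - dx,
             end_mm = ot$position_mm[ends[k]] + dx),
        class = "transition_call")))
    }
  }
  calls
}

#' @export
print.transition_call <- function(x, ...) {
  cat(sprintf("transition_call: %s over [%.2f, %.2f] mm\n",
              x$kind, x$start_mm, x$end_mm))
  invisible(x)
}
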