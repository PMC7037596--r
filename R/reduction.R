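#' Detector geometry
#'
#' Geometry sidecar for a 2D detector frame. Defaults place the first nine
#' meridional orders of a 67 nm collagen D-period comfortably on a 512 x 512
#' detector. Pixel coordinates are 0-based `(col, row)`; the default beam
#' center sits on the pixel-grid symmetry point so that a 180 degree rotation
#' maps the grid onto itself.
#'
#' @param wavelength X-ray wavelength, Angstrom.
#' @param distance sample-detector distance, mm.
#' @param pixel_size pixel pitch, mm.
#' @param beam_center `(col, row)` of the beam, 0-based pixels.
#' @param image_shape `(rows, cols)`.
#' @return object of class `detector_geometry`.
#' @export
detector_geometry <- function(wavelength = 1.033, distance = 2500,
                              pixel_size = 0.172,
                              beam_center = c(255.5, 255.5),
                              image_shape = c(512L, 512L)) {
  if (wavelength <= 0 || distance <= 0 || pixel_size <= 0)
    stop("wavelength, distance and pixel_size must be positive")
  if (beam_center[1] < 0 || beam_center[1] > image_shape[2] - 1 ||
      beam_center[2] < 0 || beam_center[2] > image_shape[1] - 1)
    stop("beam_center must lie inside the image")
  structure(list(wavelength = wavelength, distance = distance,
                 pixel_size = pixel_size, beam_center = beam_center,
                 image_shape = as.integer(image_shape)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "detector_geometry: %d x %d px, %.3g mm px, L = %g mm, lambda = %g A, center (%.1f, %.1f)\n",
    x$image_shape[1], x$image_shape[2], x$pixel_size, x$distance,
    x$wavelength, x$beam_center[1], x$beam_center[2]))
  invisible(x)
}

#' Momentum transfer <-> detector radius
#'
#' `q = (4*pi/lambda) * sin(theta)` with `2*theta = atan(r * pixel / L)`;
#' `radius_of_q()` is the exact inverse. d-spacings follow as `d = 2*pi/q`.
#'
#' @param geometry a [detector_geometry()].
#' @param r radial distance from the beam center, pixels (>= 0).
#' @param q momentum transfer, inverse Angstrom.
#' @return numeric vector.
#' @export
q_of_radius <- function(geometry, r) {
  if (any(r < 0)) stop("radius must be >= 0")
  tth <- atan(r * geometry$pixel_size / geometry$distance)
  (4 * pi / geometry$wavelength) * sin(tth / 2)
}

#' @rdname q_of_radius
#' @export
radius_of_q <- function(geometry, q) {
  if (any(q < 0)) stop("q must be >= 0")
  theta <- asin(q * geometry$wavelength / (4 * pi))
  geometry$distance * tan(2 * theta) / geometry$pixel_size
}

# Pixel polar coordinates about the beam center. Rows increase downwards on
# the stored matrix; chi is measured anticlockwise from the +x (equatorial)
# axis with +y up, in [0, 360).
.polar_coords <- function(geometry) {
  sh <- geometry$image_shape
  col0 <- matrix(rep(0:(sh[2] - 1), each = sh[1]), nrow = sh[1])
  row0 <- matrix(rep(0:(sh[1] - 1), times = sh[2]), nrow = sh[1])
  dx <- col0 - geometry$beam_center[1]
  dy <- geometry$beam_center[2] - row0
  r <- sqrt(dx^2 + dy^2)
  chi <- (atan2(dy, dx) * 180 / pi) %% 360
  list(r = r, chi = chi)
}

# Angular distance of chi (deg) to the nearest of the two opposed sector
# axes (axis and axis+180).
.axis_dist <- function(chi, axis) {
  d <- abs((chi - axis) %% 180)
  pmin(d, 180 - d)
}

#' Sector-integrated radial profile
#'
#' Mean intensity in 1-px annular bins restricted to the two opposed sector
#' wedges about the meridional (vertical, fiber) or equatorial (horizontal)
#' axis, converted to a q grid. `sector = "full"` integrates the whole
#' azimuth (used for the count-conservation diagnostics). A central disc of
#' radius `mask_radius` models the beamstop and is excluded. Bins with no
#' pixels are reported as `NA`, not zero.
#'
#' @param frame a `diffraction_frame` (see [render_diffraction()] /
#'   [read_frame_tiff()]).
#' @param sector `"meridional"`, `"equatorial"` or `"full"`.
#' @param half_angle sector half-width about the axis, degrees.
#' @param mask_radius beamstop disc radius, pixels.
#' @return A `radial_profile`: list with `q` (1/A, strictly increasing),
#'   `intensity` (mean counts per bin), `r_px`, `npix`, `sector`,
#'   `half_angle`, `geometry`.
#' @export
sector_profile <- function(frame, sector = c("meridional", "equatorial", "full"),
                           half_angle = 15, mask_radius = 10) {
  sector <- match.arg(sector)
  geom <- frame$geometry
  pc <- .polar_coords(geom)
  keep <- pc$r >= mask_radius
  if (sector != "full") {
    axis <- if (sector == "meridional") 90 else 0
    keep <- keep & .axis_dist(pc$chi, axis) <= half_angle
  }
  rbin <- as.integer(round(pc$r[keep]))
  ints <- frame$image[keep]
  rmax <- max(rbin)
  sums <- rowsum(ints, rbin)
  cnts <- rowsum(rep(1, length(rbin)), rbin)
  rmean <- rowsum(pc$r[keep], rbin) / cnts
  rgrid <- as.integer(rownames(sums))
  full_r <- seq(max(ceiling(mask_radius), 1L), rmax)
  intensity <- rep(NA_real_, length(full_r))
  npix <- rep(0L, length(full_r))
  # q is evaluated at each bin's pixel-centroid radius, not the nominal bin
  # center: in narrow sectors the pixels cluster off-center within the bin
  r_eff <- as.numeric(full_r)
  m <- match(rgrid, full_r)
  ok <- !is.na(m)
  intensity[m[ok]] <- (sums / cnts)[ok]
  npix[m[ok]] <- as.integer(cnts[ok])
  r_eff[m[ok]] <- rmean[ok]
  structure(list(q = q_of_radius(geom, r_eff), intensity = intensity,
                 r_px = full_r, npix = npix, sector = sector,
                 half_angle = if (sector == "full") 180 else half_angle,
                 mask_radius = mask_radius, geometry = geom,
                 provenance = list(source = frame$meta %||% list())),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial_profile (%s, +/-%g deg): %d bins, q %.4g-%.4g 1/A\n",
              x$sector, x$half_angle, length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Estimate the beam center from ring contrast
#'
#' Grid search around the nominal center followed by per-axis parabolic
#' refinement, maximizing the sharpness (mean squared radial gradient) of
#' the full-azimuth radial profile. Rings blur and the score drops when the
#' assumed center is wrong.
#'
#' @param frame a `diffraction_frame`.
#' @param span half-width of the search grid, px.
#' @param step grid step, px.
#' @return numeric `(col, row)`, 0-based pixels.
#' @export
find_beam_center <- function(frame, span = 4, step = 1) {
  geom <- frame$geometry
  img <- frame$image
  if (sd(img) < 1e-12 * (abs(mean(img)) + 1e-300) || sd(img) == 0)
    stop("no ring contrast: image is flat")
  score <- function(cc) {
    g2 <- geom; g2$beam_center <- cc
    pr <- sector_profile(list(image = img, geometry = g2), "full",
                         mask_radius = 10)
    v <- pr$intensity[!is.na(pr$intensity)]
    mean(diff(v)^2)
  }
  offs <- seq(-span, span, by = step)
  grid <- expand.grid(dc = offs, dr = offs)
  sc <- vapply(seq_len(nrow(grid)), function(i)
    score(geom$beam_center + c(grid$dc[i], grid$dr[i])), numeric(1))
  best <- geom$beam_center + c(grid$dc[which.max(sc)], grid$dr[which.max(sc)])
  # parabolic refinement, one axis at a time
  for (ax in 1:2) {
    s <- vapply(c(-step, 0, step), function(d) {
      cc <- best; cc[ax] <- cc[ax] + d; score(cc)
    }, numeric(1))
    den <- s[1] - 2 * s[2] + s[3]
    if (is.finite(den) && den < 0)
      best[ax] <- best[ax] + 0.5 * step * (s[1] - s[3]) / den
  }
  best
}

#' Background subtraction for radial profiles
#'
#' `rolling_minimum`: a running minimum over `window` bins, smoothed by a
#' running mean of the same width, is taken as the background under peaks
#' narrower than the window. `linear_local`: an iterated lower-envelope line
#' fit (fit, keep points at or below the line, refit). The residual is
#' clipped at zero; the method and window are recorded in the profile
#' provenance.
#'
#' @param profile a `radial_profile`.
#' @param method `"rolling_minimum"` or `"linear_local"`.
#' @param window window width in bins (rolling_minimum only).
#' @return a `radial_profile` with the background removed.
#' @export
subtract_background <- function(profile,
                                method = c("rolling_minimum", "linear_local"),
                                window = 41) {
  method <- match.arg(method)
  y <- profile$intensity
  n <- length(y)
  if (method == "rolling_minimum") {
    if (window >= n) stop("window larger than profile")
    ok <- !is.na(y)
    yy <- y
    if (any(!ok) && sum(ok) >= 2)
      yy[!ok] <- approx(profile$q[ok], y[ok], xout = profile$q[!ok],
                        rule = 2)$y
    # pad by linear extrapolation of the end slopes, then apply a
    # morphological opening (erosion + dilation): it follows any monotone
    # background exactly and removes bumps narrower than the window
    w <- window
    ne <- min(max(5L, w %/% 2L), n)
    slope_l <- coef(lm(yy[1:ne] ~ seq_len(ne)))[2]
    slope_r <- coef(lm(yy[(n - ne + 1):n] ~ seq_len(ne)))[2]
    padl <- yy[1] - slope_l * (w:1)
    padr <- yy[n] + slope_r * (1:w)
    yp <- c(padl, yy, padr)
    bg <- zoo::rollapply(yp, w, min, partial = TRUE, align = "center")
    bg <- zoo::rollapply(bg, w, max, partial = TRUE, align = "center")
    bg <- zoo::rollapply(bg, 5, mean, partial = TRUE, align = "center")
    bg <- bg[(w + 1):(w + n)]
    bg[!ok] <- NA
  } else {
    ok <- which(!is.na(y))
    pts <- ok
    for (it in 1:6) {
      fit <- lm(y[pts] ~ profile$q[pts])
      resid_all <- y[ok] - (coef(fit)[1] + coef(fit)[2] * profile$q[ok])
      keep <- ok[resid_all <= pmax(0.02 * mad(resid_all), 0)]
      if (length(keep) < 5) break
      pts <- keep
    }
    bg <- rep(NA_real_, n)
    bg[ok] <- coef(fit)[1] + coef(fit)[2] * profile$q[ok]
  }
  out <- profile
  out$intensity <- pmax(y - bg, 0)
  out$provenance$background <- list(method = method, window = window)
  out
}

#' Azimuthal intensity profile in a q band
#'
#' Mean counts versus azimuth chi (1 degree bins over `[0, 360)`) for pixels
#' with `q` inside `q_band`. A local background, estimated from two flanking
#' annuli of half the band width, is interpolated in q and subtracted per
#' chi bin.
#'
#' @param frame a `diffraction_frame`.
#' @param q_band `c(q_lo, q_hi)`, 1/A.
#' @param bin chi bin width, degrees.
#' @param subtract_annulus subtract the flanking-annulus background?
#' @return An `azimuthal_profile`: list with `chi` (bin centers, degrees),
#'   `intensity`, `q_band`, `npix`.
#' @export
azimuthal_profile <- function(frame, q_band, bin = 1, subtract_annulus = TRUE) {
  if (q_band[1] >= q_band[2]) stop("q_band must satisfy q_lo < q_hi")
  geom <- frame$geometry
  pc <- .polar_coords(geom)
  qpix <- q_of_radius(geom, pc$r)
  sel <- qpix >= q_band[1] & qpix <= q_band[2]
  if (!any(sel)) stop("q band falls off the detector")
  edges <- seq(0, 360, by = bin)
  centers <- edges[-length(edges)] + bin / 2
  bin_of <- function(mask) {
    b <- pmin(findInterval(pc$chi[mask], edges), length(centers))
    s <- rowsum(frame$image[mask], b)
    n <- rowsum(rep(1, sum(mask)), b)
    out <- rep(NA_real_, length(centers))
    out[as.integer(rownames(s))] <- s / n
    out
  }
  prof <- bin_of(sel)
  if (subtract_annulus) {
    w <- (q_band[2] - q_band[1]) / 2
    lo <- qpix >= q_band[1] - w & qpix < q_band[1]
    hi <- qpix > q_band[2] & qpix <= q_band[2] + w
    bg <- rep(0, length(centers))
    if (any(lo) && any(hi)) bg <- (bin_of(lo) + bin_of(hi)) / 2
    else if (any(lo)) bg <- bin_of(lo)
    else if (any(hi)) bg <- bin_of(hi)
    prof <- prof - bg
  }
  structure(list(chi = centers, intensity = prof, q_band = q_band,
                 bin = bin, geometry = geom),
            class = "azimuthal_profile")
}

#' @export
print.azimuthal_profile <- function(x, ...) {
  cat(sprintf("azimuthal_profile: %d bins of %g deg, q band [%.4g, %.4g] 1/A\n",
              length(x$chi), x$bin, x$q_band[1], x$q_band[2]))
  invisible(x)
}
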