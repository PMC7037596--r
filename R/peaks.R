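#' Fit a single reflection on a radial profile
#'
#' Least-squares fit of a Gaussian (or pseudo-Voigt) plus linear baseline
#' inside a q window. The area is reported analytically from the fitted
#' parameters, never by numerical integration of the data. A fit that does
#' not converge, or a window with fewer than 7 finite points, returns a
#' flagged null fit (`converged = FALSE`) rather than a silent zero.
#'
#' @param profile a `radial_profile` (see [sector_profile()]).
#' @param window `c(q_lo, q_hi)`, 1/A.
#' @param model `"gaussian"` or `"pseudo_voigt"`.
#' @return A `peak_fit`: list with `center_q`, `sigma_q`, `area`,
#'   `amplitude`, `baseline` (value at the center), `rms_residual`,
#'   `window`, `model`, `converged`.
#' @export
fit_peak <- function(profile, window, model = c("gaussian", "pseudo_voigt")) {
  model <- match.arg(model)
  if (window[1] >= window[2]) stop("window must satisfy q_lo < q_hi")
  if (window[1] < min(profile$q) || window[2] > max(profile$q))
    stop("window outside profile")
  sel <- which(profile$q >= window[1] & profile$q <= window[2] &
                 !is.na(profile$intensity))
  if (length(sel) < 7) stop("need at least 7 points in the fit window")
  q <- profile$q[sel]; y <- profile$intensity[sel]
  qm <- mean(q)
  # initial values
  flank <- c(head(y, 3), tail(y, 3))
  b0 <- median(flank)
  b1 <- (median(tail(y, 3)) - median(head(y, 3))) /
    (median(tail(q, 3)) - median(head(q, 3)))
  imax <- which.max(y)
  mu0 <- q[imax]
  A0 <- max(y[imax] - b0, .Machine$double.eps)
  above <- y - b0 > A0 / 2
  s0 <- if (any(above)) max(diff(range(q[above])) / 2.355,
                            diff(range(q)) / 20)
        else diff(range(q)) / 10

  df <- data.frame(q = q, y = y, qc = q - qm)
  fit <- tryCatch({
    if (model == "gaussian") {
      nlsLM(y ~ b0 + b1 * qc + A * exp(-(q - mu)^2 / (2 * s^2)), data = df,
            start = list(b0 = b0, b1 = b1, A = A0, mu = mu0, s = s0),
            control = nls.lm.control(maxiter = 200))
    } else {
      nlsLM(y ~ b0 + b1 * qc +
              A * (eta / (1 + ((q - mu) / s)^2) +
                     (1 - eta) * exp(-(q - mu)^2 / (2 * s^2))),
            data = df,
            start = list(b0 = b0, b1 = b1, A = A0, mu = mu0, s = s0,
                         eta = 0.3),
            lower = c(-Inf, -Inf, 0, window[1], 1e-9, 0),
            upper = c(Inf, Inf, Inf, window[2], Inf, 1),
            control = nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  null_fit <- structure(list(center_q = NA_real_, sigma_q = NA_real_,
                             area = NA_real_, amplitude = NA_real_,
                             baseline = NA_real_, rms_residual = NA_real_,
                             window = window, model = model,
                             converged = FALSE),
                        class = "peak_fit")
  if (is.null(fit)) return(null_fit)
  cf <- as.list(coef(fit))
  if (cf$s <= 0 || cf$A < 0 || cf$mu <= window[1] || cf$mu >= window[2])
    return(null_fit)
  area <- if (model == "gaussian") cf$A * abs(cf$s) * sqrt(2 * pi)
          else cf$A * abs(cf$s) * (cf$eta * pi + (1 - cf$eta) * sqrt(2 * pi))
  structure(list(center_q = cf$mu, sigma_q = abs(cf$s), area = area,
                 amplitude = cf$A,
                 baseline = cf$b0 + cf$b1 * (cf$mu - qm),
                 rms_residual = sqrt(mean(residuals(fit)^2)),
                 window = window, model = model, converged = TRUE,
                 eta = cf$eta %||% NULL),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  if (!x$converged) cat("peak_fit: not converged (null fit)\n")
  else cat(sprintf(
    "peak_fit (%s): center %.5g 1/A (d = %.4g A), sigma %.3g, area %.4g\n",
    x$model, x$center_q, 2 * pi / x$center_q, x$sigma_q, x$area))
  invisible(x)
}

# Locate a reflection near an expected q: local maximum search within
# +/- search_frac, then a fit window of +/- window_frac about the located
# maximum. Returns the fit or NULL when no significant peak is present.
.fit_near <- function(profile, q_expect, search_frac = 0.05,
                      window_frac = 0.035, model = "gaussian",
                      min_amplitude = 1, min_half_bins = 8) {
  sel <- which(profile$q >= q_expect * (1 - search_frac) &
                 profile$q <= q_expect * (1 + search_frac) &
                 !is.na(profile$intensity))
  if (length(sel) < 3) return(NULL)
  qpk <- profile$q[sel][which.max(profile$intensity[sel])]
  # window wide enough in both relative q and bin count (1-px bins)
  half <- max(window_frac * qpk, min_half_bins * median(diff(profile$q)))
  win <- c(max(qpk - half, min(profile$q)), min(qpk + half, max(profile$q)))
  fit <- tryCatch(fit_peak(profile, win, model), error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  # the fitted center must stay inside the search band: a neighbouring
  # reflection caught by a wide window must not masquerade as this one
  if (fit$center_q < q_expect * (1 - search_frac) ||
      fit$center_q > q_expect * (1 + search_frac)) return(NULL)
  # significance: amplitude must stand clear of the fit residuals and of
  # numerical dust on noise-free renders
  if (fit$amplitude < min_amplitude ||
      fit$amplitude < 3 * fit$rms_residual) return(NULL)
  fit
}

#' Collagen D-period from the 5th meridional order
#'
#' Reduces a frame to its background-subtracted meridional profile (or takes
#' one directly), locates the 5th-order reflection near `D0_guess / 5`, fits
#' it and returns `D = 5 * d5` with `d5 = 2*pi / center_q`. The 5th order
#' alone carries the measurement; other orders are only used by the
#' consistency diagnostics ([collagen_orders()]).
#'
#' @param x a `diffraction_frame` or a (background-subtracted)
#'   `radial_profile` of the meridional sector.
#' @param D0_guess expected resting D-period, nm.
#' @param ... passed to [sector_profile()] when `x` is a frame.
#' @return list with `D_nm`, `d5_nm`, and the underlying `fit`.
#' @export
collagen_D <- function(x, D0_guess = 67, ...) {
  profile <- .as_meridional(x, ...)
  q5 <- 2 * pi / (D0_guess * 10 / 5)
  fit <- .fit_near(profile, q5)
  if (is.null(fit))
    stop("collagen 5th order not found (missing or off-detector)")
  d5_A <- 2 * pi / fit$center_q
  list(D_nm = 5 * d5_A / 10, d5_nm = d5_A / 10, fit = fit)
}

#' Collagen order consistency table
#'
#' Fits every visible meridional order `n` of an expected D-period and
#' reports `n * d_n`, which must agree across orders for a true axial
#' periodicity.
#'
#' @inheritParams collagen_D
#' @param orders integer orders to attempt.
#' @return data frame: `order`, `d_nm`, `n_d_nm`, `area`.
#' @export
collagen_orders <- function(x, D0_guess = 67, orders = 1:9, ...) {
  profile <- .as_meridional(x, ...)
  rows <- lapply(orders, function(n) {
    q_n <- 2 * pi / (D0_guess * 10 / n)
    if (!.order_on_detector(profile, q_n)) return(NULL)
    fit <- .fit_near(profile, q_n)
    if (is.null(fit)) return(NULL)
    d <- 2 * pi / fit$center_q / 10
    data.frame(order = n, d_nm = d, n_d_nm = n * d, area = fit$area)
  })
  do.call(rbind, rows)
}

# Orders whose arc hugs the beamstop or the detector edge cannot be fitted
# cleanly; skip them in the consistency table.
.order_on_detector <- function(profile, q_expect, margin_px = 8) {
  g <- profile$geometry
  if (is.null(g)) return(TRUE)
  r0 <- radius_of_q(g, q_expect)
  r0 > (profile$mask_radius %||% 0) + margin_px &&
    r0 < max(profile$r_px) - margin_px
}

.as_meridional <- function(x, ...) {
  if (inherits(x, "radial_profile")) return(x)
  if (!inherits(x, "diffraction_frame"))
    stop("need a diffraction_frame or radial_profile")
  subtract_background(sector_profile(x, "meridional", ...))
}

#' Muscle (1,1) equatorial d-spacing
#'
#' Locates and fits the muscle (1,1) reflection on the equatorial profile.
#' The d-spacing is flagged as a *relative* measure of fiber elongation in
#' the provenance: its absolute relation to sarcomere length is loose.
#' Errors when no significant equatorial reflection is present (expected in
#' pure chordae tendinae, where no muscle is detected).
#'
#' @param x a `diffraction_frame` or equatorial `radial_profile`
#'   (background-subtracted).
#' @param d11_guess expected (1,1) d-spacing, nm.
#' @param ... passed to [sector_profile()] when `x` is a frame.
#' @return list with `d11_nm`, `fit`, `provenance`.
#' @export
muscle_d11 <- function(x, d11_guess = 24.5, ...) {
  profile <- if (inherits(x, "radial_profile")) x
             else subtract_background(sector_profile(x, "equatorial", ...))
  fit <- .fit_near(profile, 2 * pi / (d11_guess * 10))
  if (is.null(fit))
    stop("no muscle (1,1) reflection detected",
         call. = FALSE)
  list(d11_nm = 2 * pi / fit$center_q / 10, fit = fit,
       provenance = list(measure = "relative", reflection = "(1,1)"))
}

#' Fiber orientation from azimuthal modulation
#'
#' Fits a two-lobed circular Gaussian (period 180 degrees) plus constant to
#' the azimuthal profile of a q band. The fiber direction is the lobe center
#' modulo 180; the spread is the circular-Gaussian sigma. A frame whose
#' azimuthal modulation depth `(max - min) / mean` falls below
#' `iso_threshold` is called isotropic and drawn as a dot. The plotting
#' ellipse has unit major axis and minor axis `b = min(1, kappa / spread)`,
#' i.e. inversely proportional to the angular spread.
#'
#' @param frame a `diffraction_frame`.
#' @param q_band `c(q_lo, q_hi)` (1/A); default is a band around the
#'   collagen 5th order of `D0_guess`.
#' @param D0_guess used only for the default band, nm.
#' @param iso_threshold modulation depth below which the pattern is called
#'   isotropic.
#' @param kappa minor-axis scale, degrees.
#' @param dot_fraction minor/major ratio used for isotropic dots.
#' @return An `orientation_result`: list with `angle` (deg in `[0, 180)`),
#'   `spread` (deg), `isotropic`, `modulation`, `ellipse = c(a, b, angle)`.
#' @export
orientation <- function(frame, q_band = NULL, D0_guess = 67,
                        iso_threshold = 0.1, kappa = 5,
                        dot_fraction = 0.1) {
  if (is.null(q_band)) {
    q5 <- 2 * pi / (D0_guess * 10 / 5)
    q_band <- q5 * c(0.96, 1.04)
  }
  az <- azimuthal_profile(frame, q_band)
  y <- az$intensity; chi <- az$chi
  ok <- !is.na(y)
  y <- y[ok]; chi <- chi[ok]
  if (length(y) < 30) stop("azimuthal band too empty for orientation")
  # modulation depth on a circularly smoothed profile: raw 1-degree bins at
  # moderate radii hold only a few pixels and are dominated by radial
  # sampling noise
  ys <- zoo::rollapply(c(tail(y, 4), y, head(y, 4)), 9, mean,
                       align = "center")
  mu_y <- mean(ys)
  modulation <- (max(ys) - min(ys)) / max(mu_y, .Machine$double.eps)
  if (!is.finite(modulation) || modulation < iso_threshold) {
    return(structure(list(angle = NA_real_, spread = Inf, isotropic = TRUE,
                          modulation = modulation,
                          ellipse = c(a = 1, b = dot_fraction, angle = NA)),
                     class = "orientation_result"))
  }
  # init: lobe at the maximum; sigma from circular mass around it
  mu0 <- chi[which.max(y)]
  d0 <- .axis_dist(chi, mu0)
  w <- pmax(y - min(y), 0)
  s0 <- sqrt(sum(w * d0^2) / sum(w))
  s0 <- min(max(s0, 2), 60)
  df <- data.frame(chi = chi, y = y)
  two_lobe <- function(chi, mu, s) {
    d <- .axis_dist(chi, mu)
    exp(-d^2 / (2 * s^2))
  }
  fit <- tryCatch(
    nlsLM(y ~ B + A * two_lobe(chi, mu, s), data = df,
          start = list(B = min(y), A = max(y) - min(y), mu = mu0, s = s0),
          control = nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) stop("orientation fit failed to converge")
  cf <- as.list(coef(fit))
  angle <- cf$mu %% 180
  spread <- abs(cf$s)
  b <- min(1, kappa / spread)
  structure(list(angle = angle, spread = spread, isotropic = FALSE,
                 modulation = modulation,
                 ellipse = c(a = 1, b = b, angle = angle)),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  if (x$isotropic)
    cat(sprintf("orientation_result: isotropic (modulation %.3f) -> dot\n",
                x$modulation))
  else
    cat(sprintf(
      "orientation_result: angle %.1f deg, spread %.1f deg, minor axis %.2f\n",
      x$angle, x$spread, x$ellipse["b"]))
  invisible(x)
}

#' Reduce and fit one scan frame
#'
#' Runs the standard per-frame analysis: meridional and equatorial sector
#' profiles, background subtraction, collagen 5th-order fit (D-period),
#' muscle (1,1) fit (absent in collagen-only tissue), and azimuthal
#' orientation. Returns a single fit-table row.
#'
#' @param frame a `diffraction_frame`.
#' @param point_id scan point identifier carried into the table.
#' @param D0_guess,d11_guess expected resting spacings, nm.
#' @param with_orientation fit the azimuthal orientation too?
#' @return one-row data frame with columns `point_id`, `position_mm`,
#'   `eng_strain_pct`, `D_nm`, `d11_nm`, `I5_area`, `I11_area`,
#'   `angle_deg`, `spread_deg`, `isotropic`.
#' @export
reduce_frame <- function(frame, point_id = NA_integer_, D0_guess = 67,
                         d11_guess = 24.5, with_orientation = TRUE) {
  mer <- subtract_background(sector_profile(frame, "meridional"))
  eqt <- subtract_background(sector_profile(frame, "equatorial"))
  D <- tryCatch(collagen_D(mer, D0_guess), error = function(e) NULL)
  m <- tryCatch(muscle_d11(eqt, d11_guess), error = function(e) NULL)
  o <- if (with_orientation)
    tryCatch(orientation(frame, D0_guess = D0_guess), error = function(e) NULL)
  else NULL
  data.frame(
    point_id = point_id,
    position_mm = frame$x_mm %||% NA_real_,
    eng_strain_pct = 100 * (frame$eng_strain %||% NA_real_),
    D_nm = if (!is.null(D)) D$D_nm else NA_real_,
    d11_nm = if (!is.null(m)) m$d11_nm else NA_real_,
    I5_area = if (!is.null(D)) D$fit$area else 0,
    I11_area = if (!is.null(m)) m$fit$area else 0,
    angle_deg = if (!is.null(o) && !o$isotropic) o$angle else NA_real_,
    spread_deg = if (!is.null(o)) o$spread else NA_real_,
    isotropic = if (!is.null(o)) o$isotropic else NA
  )
}
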