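#' Render a synthetic fiber-diffraction frame
#'
#' Phenomenological forward model of one scan point. The image contains:
#' meridional collagen arcs at orders 1..9 of the local D-period
#' `D(x) = D0 * (1 + c(x) * eng_strain)` (radial Gaussians, azimuthal
#' Gaussian spread `sigma_chi(x, eng_strain)` about the vertical fiber
#' axis); muscle equatorial (1,0) and (1,1) arcs with amplitude proportional
#' to the local muscle fraction `f_m(x)` and d-spacing shrinking with
#' strain; near the CT-LL junction a second collagen population rotated by
#' 90 degrees (its meridional arcs appear on the equator); and a smooth
#' power-law background. Arc radii follow the exact detector mapping
#' `r = (L/p) * tan(2 * asin(lambda / (2 d)))`. The collagen 5th-order and
#' muscle (1,1) amplitudes share one weight so that their fitted-area ratio
#' encodes `f_m : (1 - f_m)` for composition analysis with calibration
#' weight 1.
#'
#' Orders whose radius falls off the detector are silently omitted (a note
#' is kept in `meta$omitted_orders`). With `noise_seed` set, pixel values are
#' Poisson-sampled (photon counting); renders are otherwise exact.
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @param x scan position, mm from the PM end.
#' @param eng_strain overall engineering strain of the strip (fraction).
#' @param geometry a [detector_geometry()].
#' @param noise_seed integer seed; `NULL` renders noise-free.
#' @param peak_counts peak amplitude of the strongest arc, counts. The
#'   default puts the 5th-order peak signal-to-noise near 20 under Poisson
#'   noise.
#' @param radial_sigma_px radial Gaussian width of the arcs, px.
#' @return A `diffraction_frame`: list with `image` (rows x cols matrix of
#'   counts), `geometry`, `x_mm`, `eng_strain`, `meta`.
#' @export
render_diffraction <- function(phantom, x, eng_strain = 0,
                               geometry = detector_geometry(),
                               noise_seed = NULL,
                               peak_counts = 450, radial_sigma_px = 2) {
  .check_x(phantom, x)
  if (eng_strain < 0) stop("eng_strain must be >= 0")
  fm <- muscle_fraction(phantom, x)
  sig_chi <- orientation_spread(phantom, x, eng_strain)
  D <- phantom$D0_nm * (1 + strain_coupling(phantom, x) * eng_strain)   # nm
  d11 <- phantom$d11_0_nm * (1 - phantom$d11_gain * eng_strain)         # nm
  d10 <- d11 * sqrt(3)
  cross_w <- .cross_population(phantom, x)

  pc <- .polar_coords(geometry)
  img <- .background_image(pc$r)
  rmax <- max(pc$r)

  # collagen meridional orders; weights give the familiar strong 3rd/5th
  worder <- c(0.30, 0.10, 0.50, 0.15, 1.00, 0.20, 0.35, 0.10, 0.25)
  omitted <- integer(0)
  add_arc <- function(img, d_A, amp, chi0, sig) {
    if (amp <= 0) return(img)
    r0 <- radius_of_q(geometry, 2 * pi / d_A)
    if (r0 > rmax) return(structure(img, off = TRUE))
    idx <- which(abs(pc$r - r0) < 6 * radial_sigma_px)
    dchi <- .axis_dist(pc$chi[idx], chi0)
    img[idx] <- img[idx] + amp *
      exp(-(pc$r[idx] - r0)^2 / (2 * radial_sigma_px^2)) *
      exp(-dchi^2 / (2 * sig^2))
    img
  }
  camp <- peak_counts * (1 - fm)
  for (n in 1:9) {
    d_A <- D * 10 / n
    r0 <- radius_of_q(geometry, 2 * pi / d_A)
    if (r0 > rmax) { omitted <- c(omitted, n); next }
    img <- add_arc(img, d_A, camp * worder[n], 90, sig_chi)
    if (cross_w > 0)
      img <- add_arc(img, d_A, camp * worder[n] * cross_w, 0, sig_chi)
  }
  # muscle equatorial reflections; (1,1) shares the 5th-order weight
  img <- add_arc(img, d10 * 10, peak_counts * fm * 0.60, 0, sig_chi)
  img <- add_arc(img, d11 * 10, peak_counts * fm * worder[5], 0, sig_chi)

  # beamstop shadow
  img[pc$r < 8] <- 0

  if (!is.null(noise_seed)) {
    old <- .Random.seed_save()
    set.seed(noise_seed)
    img[] <- rpois(length(img), lambda = pmax(img, 0))
    .Random.seed_restore(old)
  }
  structure(list(image = img, geometry = geometry, x_mm = x,
                 eng_strain = eng_strain,
                 meta = list(D_true_nm = D, d11_true_nm = if (fm > 0) d11 else NA,
                             f_m = fm, sigma_chi = sig_chi,
                             cross_weight = cross_w,
                             omitted_orders = omitted,
                             noise_seed = noise_seed)),
            class = "diffraction_frame")
}

.background_image <- function(r, bg0 = 60, r_scale = 25, p = 1.5, bg1 = 3) {
  bg0 * (1 + r / r_scale)^(-p) + bg1
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' @export
print.diffraction_frame <- function(x, ...) {
  cat(sprintf(
    "diffraction_frame: x = %.2f mm, eng strain %.1f%%, %d x %d px, f_m = %.2f\n",
    x$x_mm, 100 * x$eng_strain, nrow(x$image), ncol(x$image), x$meta$f_m))
  invisible(x)
}

# --- fiducial-marker video -------------------------------------------------

# Lab y (mm, from the fixed PM grip) of material position x under per-region
# strains eps (named fractions).
.advect_position <- function(phantom, x, eps) {
  reg <- phantom$regions
  vapply(x, function(xi) {
    below <- pmin(pmax(xi - reg$x_lo, 0), reg$L0)
    xi + sum(eps[reg$region] * below)
  }, numeric(1))
}

#' Map material positions through the regional strain field
#'
#' Advects material positions (mm from the PM end) to their stretched lab
#' positions given per-region engineering strains, e.g. to report where a
#' tracked scan point sits at a higher strain level.
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @param x material positions, mm.
#' @param strains named per-region strain fractions (as from
#'   [solve_series_pull()]).
#' @return lab positions, mm.
#' @export
advect_positions <- function(phantom, x, strains) {
  .check_x(phantom, x)
  .advect_position(phantom, x, strains)
}

#' Render the fiducial-marker video of a pull
#'
#' Draws the strip's marker dots (dark Gaussian blobs on a light background)
#' at the positions implied by the per-region strain ground truth of a
#' simulated load trace, one frame per trace sample. The true marker
#' trajectories are returned alongside the frames so tracking can be tested
#' against ground truth.
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @param trace a `load_trace` from [simulate_pull()].
#' @param frames which trace rows to render (default all).
#' @param fps frame rate, Hz (metadata; the trace already samples at its
#'   own fps).
#' @param blob_sigma marker blob Gaussian sigma, px.
#' @param px_per_mm image scale.
#' @param width_px frame width.
#' @param pad_px margin above the first marker.
#' @param height_px fixed frame height; defaults to fitting the whole pull.
#' @param noise_sd Gaussian pixel noise sd (0 = clean).
#' @param noise_seed seed, required when `noise_sd > 0`.
#' @return list with `frames` (list of matrices, grey levels in `[0, 1]`),
#'   `truth` (data frame: frame, marker, x_px, y_px), `layout` (the marker
#'   material positions), `fps`.
#' @export
render_video_frames <- function(phantom, trace, frames = NULL, fps = 5,
                                blob_sigma = 3, px_per_mm = 12,
                                width_px = 128, pad_px = 24,
                                height_px = NULL,
                                noise_sd = 0, noise_seed = NULL) {
  if (noise_sd > 0 && is.null(noise_seed))
    stop("noise_seed is required when noise_sd > 0")
  if (is.null(frames)) frames <- seq_len(nrow(trace))
  eps_all <- attr(trace, "strain_truth")
  lay <- phantom$marker_layout
  if (is.null(height_px))
    height_px <- ceiling(pad_px * 2 +
      (diff(range(phantom$region_bounds)) + max(trace$displacement_mm)) *
        px_per_mm)
  out <- vector("list", length(frames))
  truth <- vector("list", length(frames))
  if (noise_sd > 0) { old <- .Random.seed_save(); set.seed(noise_seed) }
  for (j in seq_along(frames)) {
    i <- frames[j]
    eps <- eps_all[i, ]
    y_mm <- .advect_position(phantom, lay$x_mm, eps)
    y_px <- pad_px + y_mm * px_per_mm
    x_px <- rep(width_px / 2, length(y_px))
    if (any(y_px > height_px - 1) || any(y_px < 0))
      stop("marker left the field of view at frame ", i)
    img <- .draw_blobs(height_px, width_px, x_px, y_px, blob_sigma)
    if (noise_sd > 0)
      img <- pmin(pmax(img + matrix(rnorm(length(img), 0, noise_sd),
                                    nrow(img)), 0), 1)
    out[[j]] <- img
    truth[[j]] <- data.frame(frame = i, marker = lay$marker,
                             x_px = x_px, y_px = y_px)
  }
  if (noise_sd > 0) .Random.seed_restore(old)
  list(frames = out, truth = do.call(rbind, truth), layout = lay, fps = fps)
}

# Light background (0.85) with dark Gaussian dots; 0-based pixel centers.
.draw_blobs <- function(h, w, x_px, y_px, sigma, depth = 0.6, bg = 0.85) {
  img <- matrix(bg, h, w)
  R <- ceiling(5 * sigma)
  for (k in seq_along(x_px)) {
    r0 <- round(y_px[k]); c0 <- round(x_px[k])
    rows <- max(0, r0 - R):min(h - 1, r0 + R)
    cols <- max(0, c0 - R):min(w - 1, c0 + R)
    dy <- rows - y_px[k]; dx <- cols - x_px[k]
    g <- exp(-outer(dy^2, dx^2, "+") / (2 * sigma^2))
    img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] - depth * g
  }
  pmin(pmax(img, 0), 1)
}
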