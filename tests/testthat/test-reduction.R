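test_that("q <-> radius mapping is exact and matches an independent ray trace", {
  g <- detector_geometry()
  expect_equal(q_of_radius(g, 0), 0)
  r <- c(0.5, 20, 113.7, 200)
  expect_equal(radius_of_q(g, q_of_radius(g, r)), r, tolerance = 1e-9)
  # independent oracle: Bragg angle from d = 134 A, ray traced to the plane
  d <- 134
  theta <- asin(g$wavelength / (2 * d))
  r_oracle <- g$distance * tan(2 * theta) / g$pixel_size
  expect_equal(radius_of_q(g, 2 * pi / d), r_oracle, tolerance = 1e-6)
  expect_error(q_of_radius(g, -1))
  expect_error(detector_geometry(beam_center = c(600, 0)), "inside")
})

test_that("beam center is recovered within half a pixel", {
  ph <- cached_phantom("MV")
  g <- test_geometry()
  fr <- render_diffraction(ph, 15, 0, geometry = g)
  cc <- find_beam_center(fr)
  expect_lt(max(abs(cc - c(127.5, 127.5))), 0.5)
  # off-grid center
  g2 <- test_geometry(); g2$beam_center <- c(124.3, 130.7)
  fr2 <- render_diffraction(ph, 15, 0, geometry = g2)
  fr2$geometry$beam_center <- c(126, 129)   # analyst's wrong nominal center
  cc2 <- find_beam_center(fr2)
  expect_lt(max(abs(cc2 - c(124.3, 130.7))), 0.5)
  flat <- fr
  flat$image[] <- 7
  expect_error(find_beam_center(flat), "flat")
})

test_that("sector profiles separate meridional from equatorial reflections", {
  ph <- cached_phantom("MV")
  g <- test_geometry()
  # pure CT: collagen only, meridional
  fr <- render_diffraction(ph, 15, 0, geometry = g)
  mer <- subtract_background(sector_profile(fr, "meridional"))
  eqt <- subtract_background(sector_profile(fr, "equatorial"))
  q5 <- 2 * pi / (67 * 10 / 5)
  band <- which(mer$q > q5 * 0.97 & mer$q < q5 * 1.03)
  expect_gt(max(mer$intensity[band], na.rm = TRUE), 50)
  expect_lt(max(eqt$intensity[band], na.rm = TRUE), 3)
})

test_that("isotropic rings give equal sector profiles and flat azimuths", {
  ph <- make_phantom("MV", overrides = list(
    orientation = list(
      sigma0_knots = list(x = c(0, 30), sigma = c(1e4, 1e4)),
      align_gain = 0, min_factor = 1, cross_amp = 0, cross_sigma_mm = 0.8)))
  fr <- render_diffraction(ph, 15, 0, geometry = test_geometry())
  mer <- sector_profile(fr, "meridional")
  eqt <- sector_profile(fr, "equatorial")
  ok <- !is.na(mer$intensity) & !is.na(eqt$intensity)
  expect_lt(max(abs(mer$intensity[ok] - eqt$intensity[ok])) /
              max(mer$intensity[ok]), 0.02)
  q5 <- 2 * pi / 134
  az <- azimuthal_profile(fr, q5 * c(0.96, 1.04), subtract_annulus = FALSE)
  v <- az$intensity[!is.na(az$intensity)]
  expect_lt(sd(v) / mean(v), 0.05)
})

test_that("annular binning conserves total counts exactly", {
  ph <- cached_phantom("MV")
  fr <- render_diffraction(ph, 9.5, 0.04, geometry = test_geometry(),
                           noise_seed = 11)
  pr <- sector_profile(fr, "full", mask_radius = 10)
  binned <- sum(pr$intensity * pr$npix, na.rm = TRUE)
  pc <- valvescan:::.polar_coords(fr$geometry)
  total <- sum(fr$image[pc$r >= 10 & round(pc$r) <= max(pr$r_px)])
  expect_equal(binned, total, tolerance = 1e-12)
})

test_that("reduction is Friedel-symmetric (180-degree rotation invariant)", {
  ph <- cached_phantom("MV")
  fr <- render_diffraction(ph, 9.5, 0.06, geometry = test_geometry())
  rot <- fr
  rot$image <- fr$image[nrow(fr$image):1, ncol(fr$image):1]
  for (sec in c("meridional", "equatorial")) {
    a <- sector_profile(fr, sec)
    b <- sector_profile(rot, sec)
    expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
  }
})

test_that("sector means reproduce a brute-force pixel summation", {
  ph <- cached_phantom("MV")
  g <- test_geometry()
  fr <- render_diffraction(ph, 15, 0, geometry = g)
  pr <- sector_profile(fr, "meridional", half_angle = 15, mask_radius = 10)
  pc <- valvescan:::.polar_coords(g)
  sel <- pc$r >= 10 & valvescan:::.axis_dist(pc$chi, 90) <= 15
  # oracle: per-bin means by direct masking, bins at integer radii
  for (rb in c(30, 56, 101)) {
    m <- sel & round(pc$r) == rb
    expect_equal(pr$intensity[match(rb, pr$r_px)],
                 mean(fr$image[m]), tolerance = 1e-9)
  }
  # and the summed sector counts agree to well under 0.1%
  binned <- sum(pr$intensity * pr$npix, na.rm = TRUE)
  brute <- sum(fr$image[sel & round(pc$r) <= max(pr$r_px)])
  expect_lt(abs(binned - brute) / brute, 1e-3)
})

test_that("background subtraction leaves pure background near zero and peaks intact", {
  ph <- make_phantom("MV", overrides = list(
    muscle_fraction = list(pm_plateau = 0, ct_plateau = 0)))
  # collagen amplitude off: scale peaks to zero via peak_counts
  fr <- render_diffraction(ph, 15, 0, geometry = test_geometry(),
                           peak_counts = 0, noise_seed = 5)
  pr <- sector_profile(fr, "meridional")
  res <- subtract_background(pr)
  lam <- mean(pr$intensity, na.rm = TRUE)
  expect_lt(max(res$intensity, na.rm = TRUE), 3 * sqrt(lam) + 3)

  # Gaussian peak on a flat baseline: fitted area unchanged within 1%
  q <- seq(0.03, 0.06, length.out = 301)
  prof <- synthetic_profile(q, 0.0469, 0.001, 100, b0 = 40)
  win <- c(0.044, 0.050)
  a_raw <- fit_peak(prof, win)$area
  a_sub <- fit_peak(subtract_background(prof, window = 101), win)$area
  expect_equal(a_sub, a_raw, tolerance = 0.01)
  expect_equal(a_raw, 100, tolerance = 0.01)

  zero <- synthetic_profile(q, 0.0469, 0.001, 0)
  expect_true(all(subtract_background(zero, window = 51)$intensity == 0))
  expect_error(subtract_background(zero, window = 1000), "window")

  # lower-envelope line fit: removes a sloped baseline, keeps the peak area
  sloped <- synthetic_profile(q, 0.0469, 0.001, 100, b0 = 30, b1 = 400)
  lin <- subtract_background(sloped, method = "linear_local")
  expect_lt(median(lin$intensity[abs(q - 0.0469) > 0.005]), 0.5)
  expect_equal(fit_peak(lin, win)$area, 100, tolerance = 0.01)
})

test_that("azimuthal profiles locate arcs and reject empty bands", {
  ph <- cached_phantom("MV")
  fr <- render_diffraction(ph, 15, 0, geometry = test_geometry())
  q5 <- 2 * pi / 134
  az <- azimuthal_profile(fr, q5 * c(0.96, 1.04))
  pk <- az$chi[which.max(az$intensity)]
  expect_lt(min(abs(pk - c(90, 270))), 1)
  expect_error(azimuthal_profile(fr, c(10, 11)), "off the detector")
  expect_error(azimuthal_profile(fr, c(0.05, 0.04)), "q_lo < q_hi")
})
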