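# blob image helper: dark Gaussian dots on a light background, 0-based centers
blob_frame <- function(h, w, xy, sigma = 3) {
  img <- matrix(0.85, h, w)
  for (k in seq_len(nrow(xy))) {
    rows <- 0:(h - 1); cols <- 0:(w - 1)
    g <- exp(-outer((rows - xy[k, 2])^2, (cols - xy[k, 1])^2, "+") /
               (2 * sigma^2))
    img <- img - 0.6 * g
  }
  pmin(pmax(img, 0), 1)
}

test_that("blob detection finds sub-pixel centers and flags edge cases", {
  xy <- cbind(x = c(20.3, 40.0, 61.7, 25.4, 50.0, 70.2),
              y = c(15.6, 30.0, 45.2, 80.9, 95.5, 110.0))
  img <- blob_frame(128, 96, xy)
  det <- detect_markers(img)
  expect_equal(nrow(det), 6)
  ord <- order(det$y_px)
  truth_ord <- order(xy[, 2])
  err <- sqrt((det$x_px[ord] - xy[truth_ord, 1])^2 +
                (det$y_px[ord] - xy[truth_ord, 2])^2)
  expect_lt(max(err), 0.3)
  # blank frame: nothing to find
  expect_equal(nrow(detect_markers(matrix(0.85, 64, 64))), 0)
  # two blobs closer than 2 sigma: merged-detection warning
  close_img <- blob_frame(64, 64, cbind(c(30, 34), c(32, 32)))
  expect_warning(detect_markers(close_img), "merged")
  # count mismatch warns
  expect_warning(detect_markers(img, expected = 7), "expected 7")
})

test_that("static markers track as constant trajectories", {
  xy <- cbind(c(20, 40, 60), c(30, 60, 90))
  det <- replicate(5, data.frame(x_px = xy[, 1], y_px = xy[, 2]),
                   simplify = FALSE)
  tr <- track_markers(det)
  expect_true(all(tr$alive))
  expect_equal(tr$x, matrix(rep(xy[, 1], each = 5), 5))
  expect_equal(tr$y, matrix(rep(xy[, 2], each = 5), 5))
})

test_that("a marker leaving the frame terminates its track with a flag", {
  d1 <- data.frame(x_px = c(10, 10), y_px = c(10, 50))
  d2 <- data.frame(x_px = c(10, 10), y_px = c(12, 55))
  d3 <- data.frame(x_px = 10, y_px = 14)         # second marker gone
  tr <- track_markers(list(d1, d2, d3))
  expect_true(2 %in% tr$terminated)
  expect_true(is.na(tr$y[3, 2]))
  expect_false(is.na(tr$y[3, 1]))
})

test_that("ambiguous links resolve to the smaller displacement", {
  d1 <- data.frame(x_px = c(10, 10), y_px = c(10, 18))
  d2 <- data.frame(x_px = c(10, 10), y_px = c(11, 17))  # both inside gates
  tr <- track_markers(list(d1, d2), max_disp = 10)
  expect_gt(tr$n_ambiguous, 0)
  expect_equal(tr$y[2, ], c(11, 17))               # no identity swap
})

test_that("strain is invariant to rigid motion and linear in separation", {
  base <- data.frame(x_px = c(50, 50), y_px = c(20, 120))
  shift <- data.frame(x_px = c(58, 58), y_px = c(25, 125))
  ang <- 7 * pi / 180
  rot <- data.frame(
    x_px = 50 + cos(ang) * (base$x_px - 50) - sin(ang) * (base$y_px - 70),
    y_px = 70 + sin(ang) * (base$x_px - 50) + cos(ang) * (base$y_px - 70))
  tr <- track_markers(list(base, shift), max_disp = 20)
  eps <- regional_strain(tr, list(R = c(1, 2)))
  expect_equal(eps$R, c(0, 0), tolerance = 1e-12)
  tr2 <- track_markers(list(base, rot), max_disp = 20)
  eps2 <- regional_strain(tr2, list(R = c(1, 2)))
  expect_equal(eps2$R, c(0, 0), tolerance = 1e-10)
  # 100 -> 110 px is 10% strain
  a <- data.frame(x_px = c(50, 50), y_px = c(10, 110))
  b <- data.frame(x_px = c(50, 50), y_px = c(10, 120))
  tr3 <- track_markers(list(a, b), max_disp = 15)
  expect_equal(regional_strain(tr3, list(R = c(1, 2)))$R[2], 10)
})

test_that("stress conversion uses standard gravity exactly", {
  tr <- data.frame(load_g = c(0, 101.9716, 455))
  expect_equal(stress_series(tr, 1)[1], 0)
  expect_equal(stress_series(tr, 1)[2], 1.0, tolerance = 1e-6)
  # 455 g on 0.5 mm^2, independent arithmetic: 455 * 9.80665e-3 / 0.5
  expect_equal(stress_series(tr, 0.5)[3], 8.9240515, tolerance = 1e-7)
  # linear in load, inverse in area
  expect_equal(stress_series(tr, 0.25), 4 * stress_series(tr, 1))
  expect_error(stress_series(tr, 0), "positive")
})

test_that("bilinear curves yield both moduli exactly", {
  # toe slope 0.02 MPa/unit strain up to 4%, then 1.5 MPa/unit strain
  eps <- seq(0, 20, by = 0.25)        # percent
  sig <- ifelse(eps <= 4, 0.02 * eps / 100,
                0.02 * 0.04 + 1.5 * (eps - 4) / 100)
  cv <- stress_strain_curve("toy", eps, sig)
  ft <- extract_features(cv)
  expect_false(ft$failure_detected)
  expect_equal(ft$ultimate_stress, max(sig))
  expect_equal(ft$linear_modulus, 1.5, tolerance = 1e-6)
  expect_equal(ft$toe_modulus, 0.02, tolerance = 1e-6)
  expect_error(extract_features(stress_strain_curve("x", 0:5, 0:5 / 10)),
               "10 samples")
  expect_error(stress_strain_curve("x", 1:10, 1:10), "start at 0")
})

test_that("failure detection needs a sustained drop", {
  eps <- seq(0, 30, length.out = 61)
  sig <- c(seq(0, 1, length.out = 50), rep(0.8, 11))   # 20% sustained drop
  ft <- extract_features(stress_strain_curve("r", eps, sig))
  expect_true(ft$failure_detected)
  expect_equal(ft$ultimate_stress, 1)
  # a 2-sample glitch is not failure
  sig2 <- seq(0, 1, length.out = 61)
  sig2[30:31] <- sig2[30:31] * 0.8
  ft2 <- extract_features(stress_strain_curve("r", eps, sig2))
  expect_false(ft2$failure_detected)
})

test_that("failure locus follows the torn region, not the softest one", {
  ph <- cached_phantom("MV")
  tr <- simulate_pull(ph)
  ft <- lapply(truth_curves(ph, tr), extract_features)
  expect_equal(failure_locus(ft), "PM-CT")
  # single-region input
  expect_equal(failure_locus(ft["PM-CT"]), "PM-CT")
  # no failure at all
  short <- lapply(truth_curves(ph, simulate_pull(ph, max_displacement = 2)),
                  extract_features)
  expect_error(failure_locus(short), "no region failed")
})

test_that("random phantoms: ultimate stress of the torn region within 2%, locus = weakest", {
  hits <- 0
  for (s in 1:20) {
    ph <- jittered_phantom("MV", seed = s)
    tr <- simulate_pull(ph)
    ft <- lapply(truth_curves(ph, tr), extract_features)
    weak <- ph$regions$region[which.min(ph$regions$sigma_ult *
                                          ph$regions$area_mm2)]
    sig_w <- ph$regions$sigma_table[ph$regions$region == weak]
    expect_lt(abs(ft[[weak]]$ultimate_stress - sig_w) / sig_w, 0.02)
    if (identical(failure_locus(ft), weak)) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("the recovered ultimate-stress ordering matches the published pattern", {
  for (preset in c("MV", "TV")) {
    ph <- cached_phantom(preset)
    tr <- simulate_pull(ph)
    ft <- lapply(truth_curves(ph, tr), extract_features)
    u <- vapply(ft, `[[`, numeric(1), "ultimate_stress")
    expect_gt(u[["CT"]], 5 * u[["PM-CT"]])      # CT dominates by far
    expect_gt(u[["PM-CT"]], u[["LL"]])          # transitions above LL
    expect_gt(u[["PM-CT"]], u[["CT-LL"]])
    if (preset == "MV") expect_lt(u[["PM"]], u[["CT-LL"]])  # PM weakest (MV)
  }
})
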