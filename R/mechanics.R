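#' Detect fiducial markers in a video frame
#'
#' Dark-blob detection: the frame is inverted, smoothed with a Gaussian of
#' the expected blob scale (Laplacian-of-Gaussian style band-pass via
#' EBImage), local maxima above an adaptive threshold become candidates,
#' and each candidate is refined to sub-pixel precision by an iterated
#' Gaussian-weighted centroid. Detections closer than `2 * blob_sigma`
#' cannot be resolved and raise a merged-detection warning.
#'
#' @param img matrix of grey values in `[0, 1]` (rows = y, 0-based pixel
#'   convention in the returned coordinates).
#' @param blob_sigma expected blob Gaussian sigma, px.
#' @param threshold detection threshold on the smoothed inverted image,
#'   as a fraction of its (max - background); default 0.3.
#' @param expected expected marker count; a differing count warns.
#' @return data frame with `x_px` (col) and `y_px` (row), 0-based.
#' @export
detect_markers <- function(img, blob_sigma = 3, threshold = 0.3,
                           expected = NULL) {
  v <- max(img) - img
  sm <- EBImage::gblur(v, sigma = blob_sigma)
  bg <- median(sm)
  peak <- max(sm)
  if (peak - bg < 1e-6) {
    out <- data.frame(x_px = numeric(0), y_px = numeric(0))
    if (!is.null(expected) && expected > 0)
      warning("expected ", expected, " markers, found 0")
    return(out)
  }
  thr <- bg + threshold * (peak - bg)
  # 8-neighbour local maxima
  h <- nrow(sm); w <- ncol(sm)
  is_max <- sm >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    shifted[rs, cs] <- sm[rs - dr, cs - dc]
    is_max <- is_max & (sm >= shifted)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    if (!is.null(expected)) warning("expected ", expected, " markers, found 0")
    return(data.frame(x_px = numeric(0), y_px = numeric(0)))
  }
  # sub-pixel: iterated Gaussian-weighted centroid on the inverted image
  R <- ceiling(3 * blob_sigma)
  centers <- t(apply(idx, 1, function(rc) {
    cy <- rc[1] - 1; cx <- rc[2] - 1        # 0-based
    for (it in 1:3) {
      rows <- max(0, round(cy) - R):min(h - 1, round(cy) + R)
      cols <- max(0, round(cx) - R):min(w - 1, round(cx) + R)
      patch <- v[rows + 1, cols + 1] - bg
      patch[patch < 0] <- 0
      wgt <- patch * exp(-(outer((rows - cy)^2, (cols - cx)^2, "+")) /
                           (2 * (1.5 * blob_sigma)^2))
      s <- sum(wgt)
      if (s <= 0) break
      cy <- sum(rowSums(wgt) * rows) / s
      cx <- sum(colSums(wgt) * cols) / s
    }
    c(cx, cy)
  }))
  out <- data.frame(x_px = centers[, 1], y_px = centers[, 2])
  # deduplicate maxima that refined to the same blob
  if (nrow(out) > 1) {
    o <- order(out$y_px, out$x_px)
    out <- out[o, ]
    dmin <- 1.0
    keep <- rep(TRUE, nrow(out))
    for (i in 2:nrow(out)) {
      d <- sqrt((out$x_px[i] - out$x_px[i - 1])^2 +
                  (out$y_px[i] - out$y_px[i - 1])^2)
      if (d < dmin) keep[i] <- FALSE
    }
    out <- out[keep, ]
  }
  rownames(out) <- NULL
  merged <- FALSE
  if (nrow(out) > 1) {
    dm <- as.matrix(dist(out))
    diag(dm) <- Inf
    if (min(dm) < 2 * blob_sigma) merged <- TRUE
  }
  # a blob much more elongated than the marker scale is two unresolved dots
  for (k in seq_len(nrow(out))) {
    rows <- max(0, round(out$y_px[k]) - R):min(h - 1, round(out$y_px[k]) + R)
    cols <- max(0, round(out$x_px[k]) - R):min(w - 1, round(out$x_px[k]) + R)
    patch <- pmax(v[rows + 1, cols + 1] - bg, 0)
    s <- sum(patch)
    if (s <= 0) next
    my <- sum(rowSums(patch) * rows) / s
    mx <- sum(colSums(patch) * cols) / s
    vyy <- sum(rowSums(patch) * (rows - my)^2) / s
    vxx <- sum(colSums(patch) * (cols - mx)^2) / s
    vxy <- sum(patch * outer(rows - my, cols - mx)) / s
    eig_max <- (vyy + vxx) / 2 + sqrt(((vyy - vxx) / 2)^2 + vxy^2)
    if (sqrt(eig_max) > 1.15 * blob_sigma) merged <- TRUE
  }
  if (merged)
    warning("markers closer than 2*blob_sigma: detections may be merged")
  if (!is.null(expected) && nrow(out) != expected)
    warning("expected ", expected, " markers, found ", nrow(out))
  out
}

#' Link marker detections across frames
#'
#' Nearest-neighbour linking with a maximum per-frame displacement gate.
#' Identities are fixed by the first frame (sorted top to bottom). In each
#' subsequent frame every track is linked to the nearest unclaimed
#' detection inside the gate, processing the closest candidate pairs first
#' so that an ambiguous link (two candidates inside the gate) resolves to
#' the smaller displacement; such ties are counted in the result. A track
#' with no candidate inside the gate terminates and is flagged, never
#' interpolated silently.
#'
#' @param detections list of data frames as from [detect_markers()], one
#'   per frame, or a list of image matrices (detection is run per frame).
#' @param max_disp linking gate, px/frame.
#' @param blob_sigma used when detection must be run.
#' @return A `marker_track`: list with `x`, `y` (frames x markers matrices,
#'   `NA` after termination), `alive` (logical matrix), `n_ambiguous`,
#'   `fps`-agnostic frame index rows.
#' @export
track_markers <- function(detections, max_disp = 10, blob_sigma = 3) {
  if (length(detections) && is.matrix(detections[[1]]))
    detections <- lapply(detections, detect_markers, blob_sigma = blob_sigma)
  nf <- length(detections)
  if (!nf) stop("no frames")
  d0 <- detections[[1]]
  if (!nrow(d0)) stop("no markers detected in the reference frame")
  o <- order(d0$y_px, d0$x_px)
  nm <- nrow(d0)
  X <- matrix(NA_real_, nf, nm); Y <- matrix(NA_real_, nf, nm)
  alive <- matrix(FALSE, nf, nm)
  X[1, ] <- d0$x_px[o]; Y[1, ] <- d0$y_px[o]; alive[1, ] <- TRUE
  n_amb <- 0L
  for (f in if (nf >= 2) 2:nf else integer(0)) {
    det <- detections[[f]]
    prev <- which(alive[f - 1, ])
    if (!nrow(det) || !length(prev)) next
    # cost matrix of candidate links inside the gate
    dx <- outer(X[f - 1, prev], det$x_px, "-")
    dy <- outer(Y[f - 1, prev], det$y_px, "-")
    dd <- sqrt(dx^2 + dy^2)
    dd[dd > max_disp] <- Inf
    amb <- sum(rowSums(is.finite(dd)) > 1)
    n_amb <- n_amb + amb
    while (any(is.finite(dd))) {
      k <- arrayInd(which.min(dd), dim(dd))
      i <- prev[k[1]]; j <- k[2]
      X[f, i] <- det$x_px[j]; Y[f, i] <- det$y_px[j]; alive[f, i] <- TRUE
      dd[k[1], ] <- Inf; dd[, k[2]] <- Inf
    }
  }
  structure(list(x = X, y = Y, alive = alive, n_ambiguous = n_amb,
                 terminated = which(!alive[nf, ])),
            class = "marker_track")
}

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf("marker_track: %d markers x %d frames, %d terminated, %d ambiguous links\n",
              ncol(x$x), nrow(x$x), length(x$terminated), x$n_ambiguous))
  invisible(x)
}

#' Regional engineering strain from marker pairs
#'
#' For each region, strain is the percent change of the distance between
#' its two flanking markers relative to the first frame:
#' `eps(t) = 100 * (||p_a(t) - p_b(t)|| - L0) / L0`. Frames with a missing
#' marker yield `NA` for that region (dropped, not interpolated).
#'
#' @param track a [track_markers()] result.
#' @param pairs named list of length-2 integer vectors (marker column
#'   indices), one per region.
#' @return data frame of strain series (percent), one column per region.
#' @export
regional_strain <- function(track, pairs) {
  out <- lapply(pairs, function(pr) {
    d <- sqrt((track$x[, pr[1]] - track$x[, pr[2]])^2 +
                (track$y[, pr[1]] - track$y[, pr[2]])^2)
    100 * (d - d[1]) / d[1]
  })
  as.data.frame(out, check.names = FALSE)
}

#' Stress series from a load trace
#'
#' `sigma = load_g * g0 * 1e-3 / area` with `g0 = 9.80665 m/s^2`, giving
#' N/mm^2 = MPa.
#'
#' @param trace a `load_trace` (or any data frame with `load_g`).
#' @param area cross-sectional area, mm^2.
#' @return numeric vector, MPa.
#' @export
stress_series <- function(trace, area) {
  if (area <= 0) stop("area must be positive")
  trace$load_g * .g0 * 1e-3 / area
}

#' Assemble a regional stress-strain curve
#'
#' @param region region label.
#' @param strain_pct strain series, percent (first frame is the reference,
#'   so it must start at 0).
#' @param stress_mpa stress series, MPa.
#' @param area_mm2 provenance: area used for the stress conversion.
#' @return a `stress_strain_curve`.
#' @export
stress_strain_curve <- function(region, strain_pct, stress_mpa,
                                area_mm2 = NA_real_) {
  if (length(strain_pct) != length(stress_mpa))
    stop("strain and stress series must have equal length")
  first <- strain_pct[!is.na(strain_pct)][1]
  if (is.na(first) || abs(first) > 1e-9)
    stop("strain must start at 0 (first frame is the reference)")
  structure(list(region = region, strain_pct = strain_pct,
                 stress_mpa = stress_mpa, area_mm2 = area_mm2),
            class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("stress_strain_curve [%s]: %d samples, peak %.4g MPa at %.3g%% strain\n",
              x$region, length(x$strain_pct), max(x$stress_mpa, na.rm = TRUE),
              x$strain_pct[which.max(x$stress_mpa)]))
  invisible(x)
}

#' Extract mechanical features from a stress-strain curve
#'
#' Failure is the first frame where stress stays below
#' `(1 - drop_frac) * running_max` for at least `m` consecutive samples;
#' the ultimate stress is the running maximum at that point (or the global
#' maximum with `failure_detected = FALSE`). The linear modulus is the
#' steepest sustained sliding-window least-squares slope before the
#' ultimate point; the toe modulus is the initial-window slope. Soft-tissue
#' curves may show several low-slope plateaus before the linear rise
#' (fiber re-arrangement); all toe intervals with slope below
#' `toe_slope_frac` of the linear modulus are reported.
#'
#' Moduli are expressed in MPa per unit strain (strain as a fraction), the
#' conventional units for elastic moduli.
#'
#' @param curve a [stress_strain_curve()].
#' @param drop_frac relative stress drop that defines failure.
#' @param m consecutive samples required below the drop line.
#' @param window_frac sliding-window width as a fraction of the pre-failure
#'   series (at least 5 samples).
#' @param toe_slope_frac slope fraction below which a window counts as toe.
#' @return A `mechanical_features`: list with `toe_modulus`,
#'   `linear_modulus` (MPa), `ultimate_stress` (MPa), `strain_at_ultimate`
#'   (percent), `failure_detected`, `failure_frame`, `toe_intervals`,
#'   `multi_toe`, and the `curve`.
#' @export
extract_features <- function(curve, drop_frac = 0.10, m = 3,
                             window_frac = 0.2, toe_slope_frac = 0.3) {
  stress <- curve$stress_mpa
  strain <- curve$strain_pct
  n <- length(stress)
  if (n < 10) stop("need at least 10 samples")
  rmax <- cummax(stress)
  below <- stress < (1 - drop_frac) * rmax
  fail_frame <- NA_integer_
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- which(r$values & r$lengths >= m)
  if (length(k)) fail_frame <- as.integer(starts[k[1]])
  failure_detected <- !is.na(fail_frame)
  i_ult <- if (failure_detected) which.max(stress[1:fail_frame])
           else which.max(stress)
  ultimate <- stress[i_ult]

  pre <- seq_len(i_ult)
  eps <- strain[pre] / 100           # fractions for moduli
  sig <- stress[pre]
  ok <- !is.na(eps) & !is.na(sig)
  eps <- eps[ok]; sig <- sig[ok]
  np <- length(eps)
  wlen <- max(5L, floor(window_frac * np))
  wlen <- min(wlen, np)
  slope_at <- function(i0) {
    ii <- i0:(i0 + wlen - 1)
    x <- eps[ii]; y <- sig[ii]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  if (np >= wlen && np >= 2) {
    starts_w <- seq_len(np - wlen + 1)
    slopes <- vapply(starts_w, slope_at, numeric(1))
    linear_modulus <- max(slopes, na.rm = TRUE)
    toe_modulus <- slopes[1]
    i_lin <- which.max(slopes)
    toe_w <- slopes < toe_slope_frac * linear_modulus
    toe_w[i_lin:length(toe_w)] <- FALSE
    ti <- rle(toe_w)
    te <- cumsum(ti$lengths); ts <- te - ti$lengths + 1
    kk <- which(ti$values)
    toe_intervals <- lapply(kk, function(ix)
      c(strain_lo = strain[ts[ix]], strain_hi = strain[te[ix] + wlen - 1]))
  } else {
    linear_modulus <- toe_modulus <- NA_real_
    toe_intervals <- list()
  }
  structure(list(
    region = curve$region,
    toe_modulus = toe_modulus,
    linear_modulus = linear_modulus,
    ultimate_stress = ultimate,
    strain_at_ultimate = strain[i_ult],
    failure_detected = failure_detected,
    failure_frame = fail_frame,
    toe_intervals = toe_intervals,
    multi_toe = length(toe_intervals) >= 2,
    curve = curve
  ), class = "mechanical_features")
}

#' @export
print.mechanical_features <- function(x, ...) {
  cat(sprintf(
    "mechanical_features [%s]: ultimate %.4g MPa @ %.3g%%, E_toe %.3g, E %.3g MPa, failure %s\n",
    x$region %||% "?", x$ultimate_stress, x$strain_at_ultimate,
    x$toe_modulus, x$linear_modulus,
    if (x$failure_detected) paste0("@ frame ", x$failure_frame) else "none"))
  invisible(x)
}

#' Localize the failing region
#'
#' The failure locus is the region whose failure frame is earliest. Under a
#' series pull the one recorded force makes every region's stress series
#' drop at the same frame, so frame ties are the rule; they are broken by
#' the post-drop strain direction -- the torn region keeps extending while
#' intact regions unload elastically and their strain recedes -- and only
#' then by lower ultimate stress.
#'
#' @param features named list of [extract_features()] results (each carries
#'   its curve).
#' @param trend_window frames after the failure frame used for the strain
#'   trend.
#' @return the region label.
#' @export
failure_locus <- function(features, trend_window = 8) {
  failed <- Filter(function(f) isTRUE(f$failure_detected), features)
  if (!length(failed)) stop("no region failed")
  frames <- vapply(failed, `[[`, numeric(1), "failure_frame")
  cand <- failed[frames == min(frames)]
  if (length(cand) > 1) {
    trend <- vapply(cand, function(f) {
      i0 <- f$failure_frame
      ii <- i0:min(i0 + trend_window, length(f$curve$strain_pct))
      s <- f$curve$strain_pct[ii]
      t <- seq_along(s)
      ok <- !is.na(s)
      if (sum(ok) < 2) return(-Inf)
      sum((t[ok] - mean(t[ok])) * (s[ok] - mean(s[ok]))) /
        sum((t[ok] - mean(t[ok]))^2)
    }, numeric(1))
    extending <- cand[trend > 0]
    if (length(extending) == 1) return(extending[[1]]$region)
    if (length(extending) > 1) cand <- extending
    ult <- vapply(cand, `[[`, numeric(1), "ultimate_stress")
    return(cand[[which.min(ult)]]$region)
  }
  cand[[1]]$region
}
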