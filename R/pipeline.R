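#' Run a scanning-XRD series over a phantom
#'
#' Renders one diffraction frame per (tracked point, engineering-strain
#' level), reduces and fits each, and returns the combined fit table. By
#' default ten points are tracked along the strip and levels run 0-10% in
#' 2% increments, mirroring the scan protocol of the strain experiments.
#' Tracked points are material points: the beam follows them, so the table
#' carries their material (resting) position.
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @param positions material scan positions, mm; default 10 equally spaced
#'   points.
#' @param levels engineering-strain levels, percent.
#' @param geometry a [detector_geometry()].
#' @param noise_seed integer for Poisson-noised frames; `NULL` renders
#'   noise-free.
#' @param with_orientation fit azimuthal orientation per frame?
#' @param ... passed to [render_diffraction()].
#' @return fit table (see [reduce_frame()]), one row per rendered frame.
#' @export
run_xrd_scan <- function(phantom, positions = NULL, levels = seq(0, 10, 2),
                         geometry = detector_geometry(), noise_seed = NULL,
                         with_orientation = TRUE, ...) {
  if (is.null(positions)) {
    L <- diff(range(phantom$region_bounds))
    positions <- phantom$region_bounds[1] + (seq_len(10) - 0.5) * L / 10
  }
  rows <- list()
  k <- 0L
  for (j in seq_along(levels)) {
    for (i in seq_along(positions)) {
      k <- k + 1L
      seed_k <- if (is.null(noise_seed)) NULL else noise_seed + k
      fr <- render_diffraction(phantom, positions[i], levels[j] / 100,
                               geometry = geometry, noise_seed = seed_k, ...)
      rows[[k]] <- reduce_frame(fr, point_id = i,
                                D0_guess = phantom$D0_nm,
                                d11_guess = phantom$d11_0_nm,
                                with_orientation = with_orientation)
    }
  }
  do.call(rbind, rows)
}

#' Full video-extensometry mechanics pipeline
#'
#' Simulates (or takes) a displacement-ramp pull, renders the fiducial
#' marker video frame by frame, detects and tracks the markers, computes
#' regional strains from the boundary marker pairs, converts the logged
#' load to per-region stress with the region cross-sections, and extracts
#' mechanical features and the failure locus.
#'
#' Frames are rendered and detected streamingly (never held as a full
#' stack) so long pulls stay memory-light.
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @param trace optional `load_trace`; simulated at `rate`/`fps` when
#'   missing.
#' @param rate,fps passed to [simulate_pull()].
#' @param blob_sigma,px_per_mm,width_px,pad_px video rendering parameters
#'   (see [render_video_frames()]).
#' @param noise_sd,noise_seed optional Gaussian pixel noise on the video.
#' @param areas named per-region cross-sections, mm^2; default the phantom
#'   truth.
#' @return list with `trace`, `track`, `strains` (percent, per region),
#'   `curves`, `features`, `failure_locus`, `pairs`.
#' @export
run_mechanics_pipeline <- function(phantom, trace = NULL, rate = 0.05,
                                   fps = 5, blob_sigma = 3, px_per_mm = 12,
                                   width_px = 128, pad_px = 24,
                                   noise_sd = 0, noise_seed = NULL,
                                   areas = NULL) {
  if (is.null(trace)) trace <- simulate_pull(phantom, rate = rate, fps = fps)
  nf <- nrow(trace)
  detections <- vector("list", nf)
  for (i in seq_len(nf)) {
    vf <- render_video_frames(phantom, trace, frames = i, fps = fps,
                              blob_sigma = blob_sigma,
                              px_per_mm = px_per_mm, width_px = width_px,
                              pad_px = pad_px, noise_sd = noise_sd,
                              noise_seed = if (is.null(noise_seed)) NULL
                                           else noise_seed + i)
    detections[[i]] <- detect_markers(vf$frames[[1]],
                                      blob_sigma = blob_sigma,
                                      expected = nrow(phantom$marker_layout))
  }
  track <- track_markers(detections)
  pairs <- marker_pairs(phantom)
  strains <- regional_strain(track, pairs)
  reg <- phantom$regions
  if (is.null(areas)) areas <- setNames(reg$area_mm2, reg$region)
  curves <- lapply(reg$region, function(rg)
    stress_strain_curve(rg, strains[[rg]],
                        stress_series(trace, areas[[rg]]),
                        area_mm2 = areas[[rg]]))
  names(curves) <- reg$region
  features <- lapply(curves, extract_features)
  locus <- tryCatch(failure_locus(features), error = function(e) NA_character_)
  list(trace = trace, track = track, strains = strains, curves = curves,
       features = features, failure_locus = locus, pairs = pairs)
}

#' Boundary marker pairs per region
#'
#' Marker indices (columns of a [track_markers()] result, which sorts
#' markers top to bottom like the layout) flanking each region: the strip
#' layout places markers at every region boundary, so region `i` is framed
#' by boundary markers `2i - 1` and `2i + 1`.
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @return named list of index pairs.
#' @export
marker_pairs <- function(phantom) {
  lay <- phantom$marker_layout
  b_idx <- which(lay$at_boundary)
  reg <- phantom$regions$region
  out <- lapply(seq_along(reg), function(i) c(b_idx[i], b_idx[i + 1]))
  names(out) <- reg
  out
}

#' Stress-strain curves from solver ground truth
#'
#' Builds per-region curves directly from a simulated trace's strain ground
#' truth and the logged load (no video): the fast path used for large
#' replicate studies where the video stage is exercised elsewhere.
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @param trace a `load_trace` from [simulate_pull()].
#' @return named list of [stress_strain_curve()] objects.
#' @export
truth_curves <- function(phantom, trace) {
  eps <- attr(trace, "strain_truth")
  reg <- phantom$regions
  out <- lapply(seq_len(nrow(reg)), function(i)
    stress_strain_curve(reg$region[i], 100 * eps[, reg$region[i]],
                        stress_series(trace, reg$area_mm2[i]),
                        area_mm2 = reg$area_mm2[i]))
  names(out) <- reg$region
  out
}
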