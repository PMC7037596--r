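#' Write / read diffraction frames as TIFF with a JSON geometry sidecar
#'
#' Frames are stored as 32-bit float TIFF, scaled to `[0, 1]` with the
#' count scale recorded in the sidecar (`<path>.json`) together with the
#' detector geometry, scan position and strain level. File names are
#' expected to encode scan index and strain percent
#' (`scan_<i>_strain_<s>.tif`, see [frame_filename()]).
#'
#' @param frame a `diffraction_frame`.
#' @param path TIFF file path.
#' @return `read_frame_tiff()` returns a `diffraction_frame`.
#' @export
write_frame_tiff <- function(frame, path) {
  scale <- max(frame$image, 1)
  tiff::writeTIFF(frame$image / scale, path, bits.per.sample = 32)
  side <- list(geometry = unclass(frame$geometry),
               x_mm = frame$x_mm, eng_strain = frame$eng_strain,
               count_scale = scale, meta = frame$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- side$geometry
  geom <- detector_geometry(g$wavelength, g$distance, g$pixel_size,
                            g$beam_center, g$image_shape)
  structure(list(image = img * side$count_scale, geometry = geom,
                 x_mm = side$x_mm, eng_strain = side$eng_strain,
                 meta = side$meta),
            class = "diffraction_frame")
}

#' @rdname write_frame_tiff
#' @param scan_index,strain_pct encoded into the name.
#' @export
frame_filename <- function(scan_index, strain_pct) {
  sprintf("scan_%03d_strain_%03d.tif", scan_index, round(strain_pct))
}

#' Write / read a load trace as CSV
#'
#' Column layout `time_s,displacement_mm,load_g`, matching the strain rig's
#' text-file logging. The hidden strain ground truth of a simulated trace
#' is not serialized: the CSV is what the instrument would produce.
#'
#' @param trace a `load_trace` (or compatible data frame).
#' @param path CSV path.
#' @export
write_load_trace <- function(trace, path) {
  write.csv(trace[, c("time_s", "displacement_mm", "load_g")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_load_trace
#' @param fps frame rate to attach on read.
#' @export
read_load_trace <- function(path, fps = NULL) {
  tr <- read.csv(path)
  need <- c("time_s", "displacement_mm", "load_g")
  if (!all(need %in% names(tr)))
    stop("load trace must have columns ", paste(need, collapse = ","))
  if (is.null(fps)) {
    dt <- median(diff(tr$time_s))
    fps <- if (is.finite(dt) && dt > 0) 1 / dt else NA_real_
  }
  attr(tr, "fps") <- fps
  class(tr) <- c("load_trace", "data.frame")
  tr
}

#' Write a radial profile as CSV with a JSON provenance header file
#'
#' @param profile a `radial_profile`.
#' @param path CSV path (`q_invA,intensity`); provenance goes to
#'   `<path>.json`.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(data.frame(q_invA = profile$q, intensity = profile$intensity),
            path, row.names = FALSE, quote = FALSE)
  prov <- list(sector = profile$sector, half_angle = profile$half_angle,
               mask_radius = profile$mask_radius,
               geometry = unclass(profile$geometry),
               provenance = profile$provenance)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write / read the per-frame fit table as TSV
#'
#' @param fit_table data frame from [run_xrd_scan()].
#' @param path TSV path.
#' @export
write_fit_table <- function(fit_table, path) {
  write.table(fit_table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fit_table
#' @export
read_fit_table <- function(path) {
  read.delim(path)
}

#' Write video frames as a numbered PNG sequence
#'
#' @param frames list of grey matrices in `[0, 1]`.
#' @param dir output directory (created).
#' @param prefix file name prefix.
#' @export
write_video_png <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames))
    png::writePNG(frames[[i]],
                  file.path(dir, sprintf("%s_%05d.png", prefix, i)))
  invisible(dir)
}

#' Export a phantom's configuration as YAML
#'
#' @param phantom a [tissue_phantom][make_phantom].
#' @param path YAML path.
#' @export
phantom_to_yaml <- function(phantom, path) {
  cfg <- list(
    name = phantom$preset,
    region_bounds = phantom$region_bounds,
    sigma_table = as.list(setNames(phantom$regions$sigma_table,
                                   phantom$regions$region)),
    tear_force_N = phantom$tear_force_N,
    capacity_margin = phantom$capacity_margin,
    weak_region = phantom$weak_region,
    eps_cap = as.list(setNames(phantom$regions$eps_ult,
                               phantom$regions$region)),
    drop_width = phantom$regions$drop_width[1],
    residual = phantom$regions$residual[1],
    muscle_fraction = phantom$muscle_fraction_params,
    thickness_knots = list(x = phantom$thickness_knots$x,
                           t = phantom$thickness_knots$t),
    D0_nm = phantom$D0_nm, d11_0_nm = phantom$d11_0_nm,
    d11_gain = phantom$d11_gain,
    strain_coupling = list(baseline = phantom$strain_coupling$baseline,
                           amp = phantom$strain_coupling$amp,
                           sigma_mm = phantom$strain_coupling$sigma),
    orientation = phantom$orientation,
    sensor_max_g = phantom$sensor_max_g
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
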