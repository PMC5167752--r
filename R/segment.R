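#' Detect spatiotemporal ERP peaks
#'
#' A peak is a voxel whose amplitude is strictly greater (positive peaks) or
#' strictly smaller (negative peaks) than all of its 26 spatiotemporal
#' neighbours inside the head mask.  Plateaus of exactly equal values count
#' as a single peak (at the earliest-time, lowest-index voxel) only when the
#' whole plateau strictly dominates its surroundings.  Boundary voxels use
#' only their existing neighbours.
#'
#' @param volume a [band_volume()].
#' @param min_abs_amplitude minimum absolute amplitude (microvolt) for a
#'   voxel to qualify, or `"auto"` for half the volume's robust noise
#'   estimate (`0.5 * mad`, median absolute deviation scaled by 1.4826).
#' @return data.frame with columns `x`, `y`, `t_idx` (1-based grid indices),
#'   `t_ms`, `amplitude`, `polarity` (+1/-1), sorted by time then
#'   decreasing absolute amplitude.
#' @export
detect_peaks <- function(volume, min_abs_amplitude = "auto") {
  stopifnot(inherits(volume, "bna_volume"))
  min_abs <- resolve_min_abs(volume, min_abs_amplitude)
  res <- cpp_local_extrema(volume$data, dim(volume$data), min_abs)
  idx <- res$idx  # 0-based
  nx <- dim(volume$data)[1]; ny <- dim(volume$data)[2]
  x <- idx %% nx + 1L
  y <- (idx %/% nx) %% ny + 1L
  t_idx <- idx %/% (nx * ny) + 1L
  pk <- data.frame(x = x, y = y, t_idx = t_idx,
                   t_ms = volume$times_ms[t_idx],
                   amplitude = volume$data[idx + 1L],
                   polarity = res$polarity)
  pk <- pk[order(pk$t_idx, -abs(pk$amplitude), pk$x, pk$y), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

resolve_min_abs <- function(volume, min_abs_amplitude) {
  if (identical(min_abs_amplitude, "auto")) {
    vals <- volume$data[!is.na(volume$data)]
    0.5 * stats::mad(vals)
  } else {
    stopifnot(is.numeric(min_abs_amplitude), min_abs_amplitude >= 0)
    min_abs_amplitude
  }
}

#' Extract the spatiotemporal parcel (STEP) around a peak
#'
#' The STEP is the 26-connected component containing the peak within the set
#' of voxels that share the peak's polarity and whose absolute amplitude is
#' at least half the peak's absolute amplitude.  The rise time is the
#' earliest time sample covered by the parcel.
#'
#' @param volume a [band_volume()].
#' @param peak one row of the data.frame returned by [detect_peaks()].
#' @param subject_id,condition,visit_id tags carried on the parcel.
#' @return An object of class `bna_step`.
#' @export
extract_step <- function(volume, peak,
                         subject_id = NA, condition = NA, visit_id = NA) {
  stopifnot(inherits(volume, "bna_volume"))
  nx <- dim(volume$data)[1]; ny <- dim(volume$data)[2]
  peak_idx0 <- (peak$x - 1L) + nx * ((peak$y - 1L) + ny * (peak$t_idx - 1L))
  comp0 <- cpp_half_component(volume$data, dim(volume$data), peak_idx0)
  vx <- cbind(x = comp0 %% nx + 1L,
              y = (comp0 %/% nx) %% ny + 1L,
              t_idx = comp0 %/% (nx * ny) + 1L)
  o <- order(vx[, "t_idx"], vx[, "y"], vx[, "x"])
  vx <- vx[o, , drop = FALSE]
  amp <- volume$data[comp0[o] + 1L]
  structure(list(
    band = volume$band,
    peak = list(x = peak$x, y = peak$y, t_idx = peak$t_idx,
                t_ms = peak$t_ms, amplitude = peak$amplitude,
                polarity = peak$polarity),
    voxels = vx, amplitudes = amp,
    rise_time_ms = volume$times_ms[min(vx[, "t_idx"])],
    times_ms = volume$times_ms,
    geometry = volume$geometry,
    subject_id = as.character(subject_id),
    condition = as.character(condition),
    visit_id = as.character(visit_id)),
    class = "bna_step")
}

#' @export
print.bna_step <- function(x, ...) {
  cat(sprintf(
    "<bna_step> %s %s peak %.2f uV @ (%d, %d, %.0f ms), %d voxels, rise %.0f ms\n",
    x$band, if (x$peak$polarity > 0) "+" else "-", x$peak$amplitude,
    x$peak$x, x$peak$y, x$peak$t_ms, nrow(x$voxels), x$rise_time_ms))
  invisible(x)
}

#' Segment one subject's band volumes into STEPs
#'
#' Runs [detect_peaks()] and [extract_step()] on every band volume and
#' returns the union of parcels.  STEPs from different peaks may overlap in
#' voxels.
#'
#' @param volumes named list of [band_volume()] objects (one per band).
#' @param min_abs_amplitude as in [detect_peaks()]; additionally the
#'   fraction `min_abs_frac_max` of the volume's absolute maximum is
#'   enforced as a floor, restricting segmentation to major events.
#' @param min_abs_frac_max fraction of the per-volume absolute maximum used
#'   as an amplitude floor (default 0: spec'd noise floor only).
#' @param min_voxels drop parcels smaller than this voxel count.
#' @param subject_id,condition,visit_id tags applied to all parcels.
#' @return list of `bna_step` objects.
#' @export
segment_subject <- function(volumes, min_abs_amplitude = "auto",
                            min_abs_frac_max = 0, min_voxels = 1,
                            subject_id = NA, condition = NA, visit_id = NA) {
  steps <- list()
  for (vol in volumes) {
    min_abs <- resolve_min_abs(vol, min_abs_amplitude)
    if (min_abs_frac_max > 0) {
      vmax <- max(abs(vol$data), na.rm = TRUE)
      min_abs <- max(min_abs, min_abs_frac_max * vmax)
    }
    pk <- detect_peaks(vol, min_abs)
    for (i in seq_len(nrow(pk))) {
      st <- extract_step(vol, pk[i, ], subject_id, condition, visit_id)
      if (nrow(st$voxels) >= min_voxels) steps[[length(steps) + 1L]] <- st
    }
  }
  steps
}
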