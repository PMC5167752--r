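BNA_STEPS_SCHEMA <- "bna-steps-1"

#' Write / read a list of STEPs as JSON
#'
#' One document per observation (subject-visit-condition): grid geometry
#' and time axis stored once, voxel sets run-length encoded exactly as in
#' the model format.
#'
#' @param steps list of [extract_step()] results sharing one grid.
#' @param path file path.
#' @return `read_steps` returns the list of steps; `write_steps` returns
#'   `path` invisibly.
#' @export
write_steps <- function(steps, path) {
  stopifnot(length(steps) >= 1)
  geom <- steps[[1]]$geometry
  doc <- list(
    schema = BNA_STEPS_SCHEMA,
    geometry = list(n_lr = geom$n_lr, n_ap = geom$n_ap),
    times_ms = steps[[1]]$times_ms,
    subject_id = steps[[1]]$subject_id,
    visit_id = steps[[1]]$visit_id,
    condition = steps[[1]]$condition,
    steps = lapply(steps, function(s) {
      lin <- voxels_to_linear(s$voxels, geom)
      o <- order(lin)
      list(band = s$band, peak = s$peak,
           voxels_rle = rle_encode(lin),
           amplitudes = s$amplitudes[o],
           rise_time_ms = s$rise_time_ms)
    }))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 12,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_steps
#' @export
read_steps <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                     simplifyDataFrame = FALSE),
                  error = function(e)
                    bna_stop("bna_parse_error",
                             sprintf("cannot parse steps file '%s'", path)))
  if (!identical(doc$schema, BNA_STEPS_SCHEMA))
    bna_stop("bna_unknown_schema",
             sprintf("unknown steps schema '%s'", doc$schema))
  geom <- grid_geometry(doc$geometry$n_lr, doc$geometry$n_ap)
  times <- as.numeric(unlist(doc$times_ms))
  lapply(doc$steps, function(s) {
    enc <- list(start = as.integer(unlist(s$voxels_rle$start)),
                length = as.integer(unlist(s$voxels_rle$length)))
    vox <- linear_to_voxels(rle_decode(enc), geom)
    o <- order(vox[, "t_idx"], vox[, "y"], vox[, "x"])
    amps <- as.numeric(unlist(s$amplitudes))
    structure(list(
      band = s$band,
      peak = list(x = as.integer(s$peak$x), y = as.integer(s$peak$y),
                  t_idx = as.integer(s$peak$t_idx),
                  t_ms = as.numeric(s$peak$t_ms),
                  amplitude = as.numeric(s$peak$amplitude),
                  polarity = as.integer(s$peak$polarity)),
      voxels = vox[o, , drop = FALSE],
      amplitudes = amps[o],
      rise_time_ms = as.numeric(s$rise_time_ms),
      times_ms = times,
      geometry = geom,
      subject_id = as.character(doc$subject_id),
      condition = as.character(doc$condition),
      visit_id = as.character(doc$visit_id)),
      class = "bna_step")
  })
}
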