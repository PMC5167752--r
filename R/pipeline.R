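#' Segment a cohort of ERP records into STEP sets
#'
#' Preprocesses every record (band decomposition + grid interpolation) and
#' segments it into STEPs.  The default amplitude floor keeps only major
#' events: besides the robust noise floor, a voxel must reach
#' `min_abs_frac_max` of its volume's absolute maximum before it can seed a
#' peak.  This suppresses the band-overlap images of components whose
#' carrier lives in a neighbouring band (see the methods vignette) and is
#' the operational reading of segmenting "major" spatiotemporal events.
#'
#' @param records list of [erp_record()].
#' @param m a projected [montage()].
#' @param bands band names to analyse.
#' @param geometry a [grid_geometry()].
#' @param min_abs_amplitude per-volume noise floor rule ([detect_peaks()]).
#' @param min_abs_frac_max fraction of the per-volume absolute maximum used
#'   as an additional amplitude floor (default 0.6, above the relative
#'   amplitude of band-limited filter ringing; see the methods vignette).
#' @param min_voxels minimum parcel size.
#' @return list of step sets: `subject_id`, `visit_id`, `condition`,
#'   `steps`.
#' @export
segment_cohort <- function(records, m, bands = c("delta", "theta"),
                           geometry = grid_geometry(),
                           min_abs_amplitude = "auto",
                           min_abs_frac_max = 0.6,
                           min_voxels = 1) {
  if (is.null(m$pos2d)) m <- project_montage(m)
  lapply(records, function(rec) {
    vols <- preprocess_erp(rec, m, bands, geometry)
    steps <- segment_subject(vols, min_abs_amplitude, min_abs_frac_max,
                             min_voxels,
                             subject_id = rec$subject_id,
                             condition = rec$condition,
                             visit_id = rec$visit_id)
    list(subject_id = rec$subject_id, visit_id = rec$visit_id,
         condition = rec$condition, steps = steps)
  })
}

#' Flatten step sets into one list for model building
#'
#' @param step_sets output of [segment_cohort()].
#' @return list of steps.
#' @export
steps_flat <- function(step_sets) {
  do.call(c, lapply(step_sets, function(ss) ss$steps))
}

#' Build per-condition reference models from segmented step sets
#'
#' @param step_sets output of [segment_cohort()].
#' @param conditions conditions to model (default Target and Novel).
#' @param ... passed to [build_model()].
#' @return named list of [build_model()] results.
#' @export
build_condition_models <- function(step_sets,
                                   conditions = c("Target", "Novel"), ...) {
  out <- lapply(conditions, function(cond) {
    sel <- Filter(function(ss) ss$condition == cond, step_sets)
    build_model(steps_flat(sel), condition = cond,
                visit_id = if (length(sel)) sel[[1]]$visit_id else NA, ...)
  })
  names(out) <- conditions
  out
}

#' Score a segmented cohort against reference models
#'
#' Thin wrapper over [build_feature_table()] restricted to the conditions
#' the models were built for.
#'
#' @param step_sets output of [segment_cohort()].
#' @param models named list of models (e.g. Target and Novel).
#' @param conditions which observations to score (default: the model
#'   conditions).
#' @param gfp_mode passed to [gfp()].
#' @return feature table.
#' @export
score_cohort <- function(step_sets, models, conditions = names(models),
                         gfp_mode = "mean_square") {
  sel <- Filter(function(ss) ss$condition %in% conditions, step_sets)
  build_feature_table(sel, models, gfp_mode)
}
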