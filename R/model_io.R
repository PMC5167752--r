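# Run-length encoding of sorted 1-based linear voxel indices.
rle_encode <- function(idx) {
  idx <- sort(as.integer(idx))
  if (!length(idx)) return(list(start = integer(), length = integer()))
  breaks <- c(TRUE, diff(idx) != 1L)
  start <- idx[breaks]
  grp <- cumsum(breaks)
  list(start = start, length = as.integer(tabulate(grp)))
}

rle_decode <- function(enc) {
  if (!length(enc$start)) return(integer())
  unlist(lapply(seq_along(enc$start), function(i)
    seq.int(enc$start[i], length.out = enc$length[i])))
}

voxels_to_linear <- function(vox, geom) {
  vox[, "x"] + geom$n_lr * ((vox[, "y"] - 1L) + geom$n_ap * (vox[, "t_idx"] - 1L))
}

linear_to_voxels <- function(idx, geom) {
  idx0 <- idx - 1L
  cbind(x = as.integer(idx0 %% geom$n_lr + 1L),
        y = as.integer((idx0 %/% geom$n_lr) %% geom$n_ap + 1L),
        t_idx = as.integer(idx0 %/% (geom$n_lr * geom$n_ap) + 1L))
}

BNA_MODEL_SCHEMA <- "bna-model-1"

#' Write / read a BNA model as JSON
#'
#' The document is self-describing: it records the schema version, grid
#' geometry, band list and time axis alongside the group STEPs (voxel sets
#' stored as run-length-encoded linear index lists) and edges.  Writing is
#' deterministic (fixed key order, fixed float formatting) and
#' `read_model(write_model(m))` reproduces every field.
#'
#' @param model a [build_model()] result.
#' @param path file path.
#' @return `read_model` returns a `bna_model`; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "bna_model"))
  geom <- model$geometry
  doc <- list(
    schema = BNA_MODEL_SCHEMA,
    condition = model$condition,
    bands = as.list(model$bands),
    geometry = list(n_lr = geom$n_lr, n_ap = geom$n_ap),
    times_ms = model$times_ms,
    parameters = model$parameters,
    provenance = model$provenance,
    group_steps = lapply(model$group_steps, function(g) {
      lin <- voxels_to_linear(g$voxels, geom)
      o <- order(lin)
      list(id = g$id, band = g$band, polarity = g$polarity,
           peak = g$peak,
           voxels_rle = rle_encode(lin),
           amplitudes = g$amplitudes[o],
           rise_time_ms = g$rise_time_ms,
           coverage = g$coverage,
           members = as.list(g$members[c("subject_id", "peak_x", "peak_y",
                                         "peak_t_ms", "rise_time_ms")]))
    }),
    edges = as.list(model$edges))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 12,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                     simplifyDataFrame = FALSE),
                  error = function(e)
                    bna_stop("bna_parse_error",
                             sprintf("cannot parse model file '%s': %s",
                                     path, conditionMessage(e))))
  if (!identical(doc$schema, BNA_MODEL_SCHEMA))
    bna_stop("bna_unknown_schema",
             sprintf("unknown model schema '%s'", doc$schema))
  geom <- grid_geometry(doc$geometry$n_lr, doc$geometry$n_ap)
  times <- as.numeric(unlist(doc$times_ms))
  group_steps <- lapply(doc$group_steps, function(g) {
    enc <- list(start = as.integer(unlist(g$voxels_rle$start)),
                length = as.integer(unlist(g$voxels_rle$length)))
    lin <- rle_decode(enc)
    vox <- linear_to_voxels(lin, geom)
    o <- order(vox[, "t_idx"], vox[, "y"], vox[, "x"])
    amps <- as.numeric(unlist(g$amplitudes))
    structure(list(
      id = g$id, band = g$band, polarity = as.integer(g$polarity),
      peak = list(x = as.integer(g$peak$x), y = as.integer(g$peak$y),
                  t_idx = as.integer(g$peak$t_idx),
                  t_ms = as.numeric(g$peak$t_ms),
                  amplitude = as.numeric(g$peak$amplitude),
                  polarity = as.integer(g$peak$polarity)),
      voxels = vox[o, , drop = FALSE],
      amplitudes = amps[o],
      rise_time_ms = as.numeric(g$rise_time_ms),
      times_ms = times,
      geometry = geom,
      coverage = as.numeric(g$coverage),
      members = data.frame(
        subject_id = as.character(unlist(g$members$subject_id)),
        peak_x = as.numeric(unlist(g$members$peak_x)),
        peak_y = as.numeric(unlist(g$members$peak_y)),
        peak_t_ms = as.numeric(unlist(g$members$peak_t_ms)),
        rise_time_ms = as.numeric(unlist(g$members$rise_time_ms)))),
      class = "bna_group_step")
  })
  edges <- if (length(doc$edges$id)) {
    data.frame(id = as.character(unlist(doc$edges$id)),
               step_a = as.character(unlist(doc$edges$step_a)),
               step_b = as.character(unlist(doc$edges$step_b)),
               kind = as.character(unlist(doc$edges$kind)),
               delta_t_ms = as.numeric(unlist(doc$edges$delta_t_ms)),
               coverage = as.numeric(unlist(doc$edges$coverage)),
               n_common = as.integer(unlist(doc$edges$n_common)))
  } else {
    data.frame(id = character(), step_a = character(), step_b = character(),
               kind = character(), delta_t_ms = numeric(),
               coverage = numeric(), n_common = integer())
  }
  structure(list(
    condition = as.character(doc$condition),
    bands = as.character(unlist(doc$bands)),
    geometry = geom,
    times_ms = times,
    group_steps = group_steps,
    edges = edges,
    parameters = lapply(doc$parameters, as.numeric),
    provenance = list(n_subjects = as.integer(doc$provenance$n_subjects),
                      visit_id = as.character(doc$provenance$visit_id))),
    class = "bna_model")
}
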