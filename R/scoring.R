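# Linear voxel keys of a step in its grid (geometry shared across steps).
step_keys <- function(st) voxels_to_linear(st$voxels, st$geometry)

#' Spatiotemporal covariance between two STEPs
#'
#' Sum over the voxels valid in *both* STEPs of the product of amplitude
#' deviations, each STEP centred on the mean over its own voxel set.
#' Disjoint voxel sets give 0.
#'
#' @param st_s,st_g two steps (subject and group) on the same grid.
#' @return scalar covariance (microvolt squared).
#' @export
topo_cov <- function(st_s, st_g) {
  ks <- step_keys(st_s); kg <- step_keys(st_g)
  i <- match(ks, kg)
  ov <- !is.na(i)
  if (!any(ov)) return(0)
  as_ <- st_s$amplitudes[ov] - mean(st_s$amplitudes)
  ag <- st_g$amplitudes[i[ov]] - mean(st_g$amplitudes)
  sum(as_ * ag)
}

# Overlap variances share the centring convention of topo_cov.
topo_overlap_var <- function(st_s, st_g) {
  ks <- step_keys(st_s); kg <- step_keys(st_g)
  i <- match(ks, kg)
  ov <- !is.na(i)
  if (!any(ov)) return(c(0, 0))
  c(sum((st_s$amplitudes[ov] - mean(st_s$amplitudes))^2),
    sum((st_g$amplitudes[i[ov]] - mean(st_g$amplitudes))^2))
}

#' Topographic correlation coefficient between two STEPs
#'
#' The spatiotemporal covariance normalised by the square root of the
#' product of the two overlap variances; always in `[-1, 1]`.  Returns
#' exactly 0 when the subject peak violates the spatiotemporal windows
#' relative to the group peak, when the voxel sets do not overlap, or when
#' either overlap variance vanishes.
#'
#' @param st_s subject step; `st_g` group step.
#' @param temporal_ms,spatial_px matching windows; `NULL` disables the
#'   window check.
#' @return scalar in `[-1, 1]`.
#' @export
topo_corr <- function(st_s, st_g, temporal_ms = NULL, spatial_px = NULL) {
  if (!is.null(temporal_ms)) {
    dt <- abs(st_s$peak$t_ms - st_g$peak$t_ms)
    dpx <- max(abs(st_s$peak$x - st_g$peak$x),
               abs(st_s$peak$y - st_g$peak$y))
    if (dt > temporal_ms || dpx > spatial_px) return(0)
  }
  v <- topo_overlap_var(st_s, st_g)
  if (any(v == 0)) return(0)
  topo_cov(st_s, st_g) / sqrt(v[1] * v[2])
}

#' Global field power of a STEP
#'
#' Mean of the squared voxel amplitudes over the STEP (`mean_square`, the
#' default), or its square root (`rms`).  An empty STEP gives 0.
#'
#' @param st a step.
#' @param mode `"mean_square"` or `"rms"`.
#' @return scalar (microvolt squared, or microvolt for `rms`).
#' @export
gfp <- function(st, mode = c("mean_square", "rms")) {
  mode <- match.arg(mode)
  if (!length(st$amplitudes)) return(0)
  ms <- mean(st$amplitudes^2)
  if (mode == "rms") sqrt(ms) else ms
}

#' Match a group STEP to a subject's STEPs
#'
#' Among the subject's STEPs of the same band and polarity whose peaks
#' satisfy the spatiotemporal windows relative to the group peak, selects
#' the one maximising the topographic correlation.  If none qualifies the
#' match is empty with topo score and GFP both 0.
#'
#' @param subject_steps list of subject steps.
#' @param group_step a group step.
#' @param temporal_ms,spatial_px matching windows (the model's clustering
#'   windows).
#' @param gfp_mode passed to [gfp()].
#' @return list with `group_step_id`, `subject_step` (or `NULL`),
#'   `topo_score`, `gfp`.
#' @export
match_step <- function(subject_steps, group_step,
                       temporal_ms = 50, spatial_px = 4,
                       gfp_mode = "mean_square") {
  pol_g <- group_step$polarity
  if (is.null(pol_g)) pol_g <- group_step$peak$polarity
  id_g <- group_step$id
  if (is.null(id_g)) id_g <- NA_character_
  best <- NULL; best_corr <- -Inf; best_nd <- Inf
  for (st in subject_steps) {
    if (st$band != group_step$band || st$peak$polarity != pol_g) next
    dt <- abs(st$peak$t_ms - group_step$peak$t_ms)
    dpx <- max(abs(st$peak$x - group_step$peak$x),
               abs(st$peak$y - group_step$peak$y))
    if (dt > temporal_ms || dpx > spatial_px) next
    r <- topo_corr(st, group_step, temporal_ms, spatial_px)
    nd <- norm_dist(dt, dpx, temporal_ms, spatial_px)
    if (r > best_corr + 1e-12 ||
        (abs(r - best_corr) <= 1e-12 && nd < best_nd)) {
      best <- st; best_corr <- r; best_nd <- nd
    }
  }
  if (is.null(best))
    list(group_step_id = id_g, subject_step = NULL,
         topo_score = 0, gfp = 0)
  else
    list(group_step_id = id_g, subject_step = best,
         topo_score = best_corr, gfp = gfp(best, gfp_mode))
}

#' Connection synchronization features for one subject
#'
#' For each model edge whose two endpoint STEPs were both matched, the
#' subject's signed peak-time and rise-time differences (ordered by the
#' edge's (a, b)); 0 when either endpoint is unmatched.
#'
#' @param matches named list of [match_step()] results, keyed by group-STEP
#'   id.
#' @param edges the model's edge data.frame.
#' @return data.frame with `edge_id`, `dt_peak_ms`, `dt_rise_ms` (one row
#'   per unique STEP pair).
#' @export
connection_features <- function(matches, edges) {
  pairs <- unique(edges[c("step_a", "step_b")])
  if (!nrow(pairs))
    return(data.frame(edge_id = character(), dt_peak_ms = numeric(),
                      dt_rise_ms = numeric()))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- matches[[pairs$step_a[i]]]; b <- matches[[pairs$step_b[i]]]
    if (is.null(a$subject_step) || is.null(b$subject_step)) {
      dtp <- 0; dtr <- 0
    } else {
      dtp <- b$subject_step$peak$t_ms - a$subject_step$peak$t_ms
      dtr <- b$subject_step$rise_time_ms - a$subject_step$rise_time_ms
    }
    data.frame(edge_id = sprintf("%s-%s", pairs$step_a[i], pairs$step_b[i]),
               dt_peak_ms = dtp, dt_rise_ms = dtr)
  })
  do.call(rbind, out)
}

#' Score one subject's STEPs against a reference model
#'
#' @param subject_steps list of subject steps.
#' @param model a [build_model()] result.
#' @param gfp_mode passed to [gfp()].
#' @return named numeric feature vector: per group STEP `<id>.topo` and
#'   `<id>.gfp`, per connected STEP pair `<a>-<b>.dt_peak` and
#'   `<a>-<b>.dt_rise`.
#' @export
score_subject <- function(subject_steps, model, gfp_mode = "mean_square") {
  tw <- model$parameters$temporal_ms
  sw <- model$parameters$spatial_px
  matches <- list()
  feats <- numeric()
  for (g in model$group_steps) {
    mres <- match_step(subject_steps, g, tw, sw, gfp_mode)
    matches[[g$id]] <- mres
    feats[[paste0(g$id, ".topo")]] <- mres$topo_score
    feats[[paste0(g$id, ".gfp")]] <- mres$gfp
  }
  cf <- connection_features(matches, model$edges)
  for (i in seq_len(nrow(cf))) {
    feats[[paste0(cf$edge_id[i], ".dt_peak")]] <- cf$dt_peak_ms[i]
    feats[[paste0(cf$edge_id[i], ".dt_rise")]] <- cf$dt_rise_ms[i]
  }
  feats
}

#' Build the feature table for a set of scored observations
#'
#' One row per subject-condition ERP; columns are the concatenation, over
#' the supplied reference models (conventionally Target and Novel), of the
#' per-STEP topographic and GFP scores and the per-connection timing
#' features, prefixed by the model name.
#'
#' @param step_sets list of observations, each a list with `subject_id`,
#'   `visit_id`, `condition` and `steps` (the observation's STEPs).
#' @param models named list of [build_model()] results.
#' @param gfp_mode passed to [gfp()].
#' @return data.frame: `subject_id`, `visit_id`, `condition`, then one
#'   numeric column per feature.
#' @export
build_feature_table <- function(step_sets, models, gfp_mode = "mean_square") {
  stopifnot(length(models) >= 1, !is.null(names(models)))
  geoms <- lapply(models, function(mo) mo$geometry)
  for (ss in step_sets) {
    for (st in ss$steps) {
      for (geom in geoms) {
        if (st$geometry$n_lr != geom$n_lr || st$geometry$n_ap != geom$n_ap)
          bna_stop("bna_geometry_mismatch",
                   "subject STEP grid does not match the model grid")
      }
    }
  }
  rows <- lapply(step_sets, function(ss) {
    feats <- unlist(lapply(names(models), function(nm) {
      f <- score_subject(ss$steps, models[[nm]], gfp_mode)
      names(f) <- paste(nm, names(f), sep = ".")
      f
    }))
    cbind(data.frame(subject_id = ss$subject_id, visit_id = ss$visit_id,
                     condition = ss$condition),
          as.data.frame(as.list(feats), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "visit_id", "condition"))
}

#' Scale features with training-set statistics
#'
#' Per column: subtract the training mean and divide by the training
#' population standard deviation (denominator n).  Columns with zero
#' training variance are set to 0 and flagged.  Rows outside
#' `training_rows` are scaled with the training statistics.
#'
#' @param table a [build_feature_table()] result.
#' @param training_rows integer or logical index of the training rows
#'   (default: all rows).
#' @return The scaled table, with attribute `"scaling"` (a data.frame of
#'   per-column `mean`, `sd`, `zero_variance`).
#' @export
scale_features <- function(table, training_rows = seq_len(nrow(table))) {
  cols <- feature_columns(table)
  tr <- table[training_rows, , drop = FALSE]
  scaling <- data.frame(column = cols, mean = NA_real_, sd = NA_real_,
                        zero_variance = FALSE)
  for (i in seq_along(cols)) {
    x <- tr[[cols[i]]]
    mu <- mean(x)
    sdp <- sqrt(mean((x - mu)^2))  # population sd, denominator n
    scaling$mean[i] <- mu
    scaling$sd[i] <- sdp
    if (sdp == 0) {
      scaling$zero_variance[i] <- TRUE
      table[[cols[i]]] <- rep(0, nrow(table))
    } else {
      table[[cols[i]]] <- (table[[cols[i]]] - mu) / sdp
    }
  }
  attr(table, "scaling") <- scaling
  table
}

#' Write / read a feature table as TSV
#'
#' @param table a feature table.
#' @param path file path.
#' @export
write_features <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
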