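# Compact per-step attribute table used by the clustering stage.
steps_meta <- function(steps) {
  if (!length(steps))
    return(data.frame(idx = integer(), band = character(),
                      polarity = integer(), x = integer(), y = integer(),
                      t_idx = integer(), t_ms = numeric(),
                      amplitude = numeric(), rise_time_ms = numeric(),
                      subject_id = character()))
  df <- data.frame(
    idx = seq_along(steps),
    band = vapply(steps, function(s) s$band, ""),
    polarity = vapply(steps, function(s) s$peak$polarity, 0L),
    x = vapply(steps, function(s) as.integer(s$peak$x), 0L),
    y = vapply(steps, function(s) as.integer(s$peak$y), 0L),
    t_idx = vapply(steps, function(s) as.integer(s$peak$t_idx), 0L),
    t_ms = vapply(steps, function(s) s$peak$t_ms, 0),
    amplitude = vapply(steps, function(s) s$peak$amplitude, 0),
    rise_time_ms = vapply(steps, function(s) s$rise_time_ms, 0),
    subject_id = vapply(steps, function(s) s$subject_id, ""))
  # canonical order makes the procedure invariant to input order
  df[order(df$band, df$polarity, df$t_ms, df$x, df$y,
           -abs(df$amplitude), df$subject_id), , drop = FALSE]
}

# Normalised spatiotemporal distance between peaks: the larger of the
# temporal and spatial (Chebyshev pixel) distances, each relative to its
# clustering window.
norm_dist <- function(dt_ms, dpx_cheb, temporal_ms, spatial_px) {
  pmax(abs(dt_ms) / temporal_ms, dpx_cheb / spatial_px)
}

#' Enumerate candidate STEP clusters
#'
#' For every step (the seed), collects from each subject the step of the
#' same band and polarity whose peak lies within the temporal window and
#' within the spatial window (Chebyshev pixel distance) of the seed's peak,
#' taking the closest by normalised spatiotemporal distance when several
#' qualify.  Candidates covering fewer than `coverage_threshold` of the
#' cohort are discarded.
#'
#' @param steps list of [extract_step()] results, tagged with subject ids.
#' @param temporal_ms,spatial_px clustering windows (defaults 50 ms, 4 px).
#' @param coverage_threshold minimum fraction of subjects (default 0.7).
#' @param n_subjects cohort size; defaults to the number of distinct
#'   subject ids present.
#' @return list of candidate clusters (member indices into `steps`, keyed
#'   by subject, plus coverage and spread diagnostics).
#' @export
enumerate_candidate_clusters <- function(steps, temporal_ms = 50,
                                         spatial_px = 4,
                                         coverage_threshold = 0.7,
                                         n_subjects = NULL) {
  stopifnot(temporal_ms > 0, spatial_px > 0)
  meta <- steps_meta(steps)
  subjects <- sort(unique(meta$subject_id))
  if (is.null(n_subjects)) n_subjects <- length(subjects)
  out <- list()
  for (r in seq_len(nrow(meta))) {
    seed <- meta[r, ]
    same <- meta[meta$band == seed$band & meta$polarity == seed$polarity, ,
                 drop = FALSE]
    dt <- same$t_ms - seed$t_ms
    dpx <- pmax(abs(same$x - seed$x), abs(same$y - seed$y))
    ok <- abs(dt) <= temporal_ms & dpx <= spatial_px
    if (!any(ok)) next
    cand <- same[ok, , drop = FALSE]
    cand$ndist <- norm_dist(dt[ok], dpx[ok], temporal_ms, spatial_px)
    cand <- cand[order(cand$ndist, abs(dt[ok]), cand$idx), , drop = FALSE]
    members <- cand[!duplicated(cand$subject_id), , drop = FALSE]
    coverage <- nrow(members) / n_subjects
    if (coverage < coverage_threshold) next
    out[[length(out) + 1L]] <- list(
      seed_idx = seed$idx,
      seed_t_ms = seed$t_ms,
      band = seed$band,
      polarity = seed$polarity,
      member_idx = stats::setNames(members$idx, members$subject_id),
      member_ndist = stats::setNames(members$ndist, members$subject_id),
      coverage = coverage,
      mean_ndist = mean(members$ndist))
  }
  out
}

#' Greedily select disjoint clusters
#'
#' Repeatedly picks the candidate with the highest coverage (ties broken by
#' smaller mean normalised spatiotemporal spread, then earlier seed peak
#' time), claims its member steps, removes those steps from all remaining
#' candidates, re-evaluates coverages and stops when no candidate reaches
#' `coverage_threshold`.  Every step ends up in at most one cluster.
#'
#' @param candidates output of [enumerate_candidate_clusters()].
#' @param coverage_threshold minimum surviving coverage (default 0.7).
#' @param n_subjects cohort size used to recompute coverages.
#' @return list of selected clusters.
#' @export
greedy_select_clusters <- function(candidates, coverage_threshold = 0.7,
                                   n_subjects) {
  selected <- list()
  pool <- candidates
  while (length(pool)) {
    cov <- vapply(pool, function(c) c$coverage, 0)
    spread <- vapply(pool, function(c) c$mean_ndist, 0)
    seed_t <- vapply(pool, function(c) c$seed_t_ms, 0)
    seed_i <- vapply(pool, function(c) c$seed_idx, 0L)
    best <- order(-cov, spread, seed_t, seed_i)[1]
    if (cov[best] < coverage_threshold) break
    chosen <- pool[[best]]
    selected[[length(selected) + 1L]] <- chosen
    used <- chosen$member_idx
    pool <- pool[-best]
    pool <- lapply(pool, function(c) {
      keep <- !(c$member_idx %in% used)
      c$member_idx <- c$member_idx[keep]
      c$member_ndist <- c$member_ndist[keep]
      c$coverage <- length(c$member_idx) / n_subjects
      c$mean_ndist <- if (length(c$member_ndist)) mean(c$member_ndist) else Inf
      c
    })
    pool <- Filter(function(c) c$coverage >= coverage_threshold, pool)
  }
  selected
}

#' Aggregate a cluster into a group STEP
#'
#' The group peak location and time are the member-wise medians (rounded to
#' the grid).  Each member's voxel set is aligned to the group peak by its
#' own peak offset; voxels present in at least half the members are kept,
#' with amplitudes averaged over the members contributing each voxel.  The
#' group rise time is the earliest time sample of the group voxel set.
#'
#' @param cluster one element of [greedy_select_clusters()] output.
#' @param steps the full step list the cluster indexes into.
#' @param id identifier for the group STEP.
#' @return An object of class `bna_group_step`.
#' @export
build_group_step <- function(cluster, steps, id = "S1") {
  members <- steps[cluster$member_idx]
  nm <- length(members)
  stopifnot(nm >= 1)
  geom <- members[[1]]$geometry
  times <- members[[1]]$times_ms
  px <- vapply(members, function(s) s$peak$x, 0)
  py <- vapply(members, function(s) s$peak$y, 0)
  pt <- vapply(members, function(s) s$peak$t_idx, 0)
  pa <- vapply(members, function(s) s$peak$amplitude, 0)
  gx <- as.integer(round_half_up(median(px)))
  gy <- as.integer(round_half_up(median(py)))
  gt <- as.integer(round_half_up(median(pt)))
  gt <- max(1L, min(length(times), gt))
  # align member voxels to the group peak, vote, then average amplitudes
  keys <- list()
  for (i in seq_len(nm)) {
    s <- members[[i]]
    vx <- s$voxels
    sh <- cbind(vx[, "x"] + (gx - s$peak$x),
                vx[, "y"] + (gy - s$peak$y),
                vx[, "t_idx"] + (gt - s$peak$t_idx))
    inb <- sh[, 1] >= 1 & sh[, 1] <= geom$n_lr &
      sh[, 2] >= 1 & sh[, 2] <= geom$n_ap &
      sh[, 3] >= 1 & sh[, 3] <= length(times)
    sh <- sh[inb, , drop = FALSE]
    keys[[i]] <- data.frame(
      key = sh[, 1] + geom$n_lr * ((sh[, 2] - 1) + geom$n_ap * (sh[, 3] - 1)),
      amp = s$amplitudes[inb])
  }
  all_keys <- do.call(rbind, keys)
  votes <- table(all_keys$key)
  kept <- as.numeric(names(votes))[votes / nm >= 0.5]
  kept_amp <- vapply(kept, function(k)
    mean(all_keys$amp[all_keys$key == k]), 0)
  kx <- as.integer((kept - 1) %% geom$n_lr + 1)
  ky <- as.integer(((kept - 1) %/% geom$n_lr) %% geom$n_ap + 1)
  kt <- as.integer((kept - 1) %/% (geom$n_lr * geom$n_ap) + 1)
  o <- order(kt, ky, kx)
  vox <- cbind(x = kx[o], y = ky[o], t_idx = kt[o])
  structure(list(
    id = id,
    band = cluster$band,
    polarity = cluster$polarity,
    peak = list(x = gx, y = gy, t_idx = gt, t_ms = times[gt],
                amplitude = stats::median(pa),
                polarity = cluster$polarity),
    voxels = vox,
    amplitudes = kept_amp[o],
    rise_time_ms = times[min(vox[, "t_idx"])],
    times_ms = times,
    geometry = geom,
    coverage = cluster$coverage,
    members = data.frame(
      subject_id = names(cluster$member_idx),
      step_idx = as.integer(cluster$member_idx),
      peak_x = px, peak_y = py,
      peak_t_ms = vapply(members, function(s) s$peak$t_ms, 0),
      rise_time_ms = vapply(members, function(s) s$rise_time_ms, 0),
      row.names = NULL)),
    class = "bna_group_step")
}

#' @export
print.bna_group_step <- function(x, ...) {
  cat(sprintf(
    "<bna_group_step> %s %s %s peak %.2f uV @ (%d, %d, %.0f ms), %d voxels, coverage %.2f\n",
    x$id, x$band, if (x$polarity > 0) "+" else "-", x$peak$amplitude,
    x$peak$x, x$peak$y, x$peak$t_ms, nrow(x$voxels), x$coverage))
  invisible(x)
}

#' Infer latency-synchronization edges between group STEPs
#'
#' For every unordered pair of group STEPs and both synchronization kinds
#' (`peak_sync`: member peak-time differences; `rise_sync`: member
#' rise-time differences), the per-subject time difference is computed over
#' the subjects contributing to both STEPs.  An edge is emitted when the
#' fraction of those subjects with `|dt| <= sync_window_ms` reaches
#' `coverage_threshold` *and* the common-subject count itself covers at
#' least `coverage_threshold` of the cohort.  The reported group `dt` is
#' the median over the within-window subjects.
#'
#' @param group_steps list of [build_group_step()] results.
#' @param n_subjects cohort size.
#' @param sync_window_ms synchronization window (default 30 ms).
#' @param coverage_threshold minimum subject fraction (default 0.7).
#' @return data.frame of edges (possibly 0 rows).
#' @export
infer_connections <- function(group_steps, n_subjects,
                              sync_window_ms = 30,
                              coverage_threshold = 0.70) {
  empty <- data.frame(id = character(), step_a = character(),
                      step_b = character(), kind = character(),
                      delta_t_ms = numeric(), coverage = numeric(),
                      n_common = integer())
  if (length(group_steps) < 2) return(empty)
  edges <- list()
  for (i in seq_len(length(group_steps) - 1)) {
    for (j in (i + 1):length(group_steps)) {
      a <- group_steps[[i]]; b <- group_steps[[j]]
      common <- intersect(a$members$subject_id, b$members$subject_id)
      if (length(common) / n_subjects < coverage_threshold) next
      ia <- match(common, a$members$subject_id)
      ib <- match(common, b$members$subject_id)
      for (kind in c("peak_sync", "rise_sync")) {
        dt <- if (kind == "peak_sync")
          b$members$peak_t_ms[ib] - a$members$peak_t_ms[ia]
        else
          b$members$rise_time_ms[ib] - a$members$rise_time_ms[ia]
        ok <- abs(dt) <= sync_window_ms
        frac <- mean(ok)
        if (frac < coverage_threshold) next
        edges[[length(edges) + 1L]] <- data.frame(
          id = sprintf("%s-%s-%s", a$id, b$id, kind),
          step_a = a$id, step_b = b$id, kind = kind,
          delta_t_ms = stats::median(dt[ok]), coverage = frac,
          n_common = length(common))
      }
    }
  }
  if (length(edges)) do.call(rbind, edges) else empty
}

#' Build the reference BNA model from a cohort's STEPs
#'
#' Runs candidate enumeration, greedy selection and group-STEP aggregation
#' per band and polarity, then infers synchronization edges over the full
#' group-STEP set (cross-band edges allowed).  An empty model (no group
#' STEP reaching coverage) is valid and returned with a warning.
#'
#' @param steps list of subject STEPs (each tagged with `subject_id`).
#' @param condition condition label carried on the model.
#' @param temporal_ms,spatial_px clustering windows (50 ms, 4 px).
#' @param coverage_threshold minimum subject fraction (0.7).
#' @param sync_window_ms synchronization window (30 ms).
#' @param visit_id provenance tag.
#' @return An object of class `bna_model`.
#' @export
build_model <- function(steps, condition = NA,
                        temporal_ms = 50, spatial_px = 4,
                        coverage_threshold = 0.70, sync_window_ms = 30,
                        visit_id = NA) {
  subjects <- sort(unique(vapply(steps, function(s) s$subject_id, "")))
  n_subjects <- length(subjects)
  if (n_subjects < 2)
    bna_stop("bna_too_few_subjects", "model building needs at least 2 subjects")
  meta <- steps_meta(steps)
  group_steps <- list()
  for (band in unique(meta$band)) {
    for (pol in unique(meta$polarity[meta$band == band])) {
      sel <- meta$idx[meta$band == band & meta$polarity == pol]
      cand <- enumerate_candidate_clusters(
        steps[sel], temporal_ms, spatial_px, coverage_threshold, n_subjects)
      # re-index candidate member ids back into the full step list
      cand <- lapply(cand, function(c) {
        c$seed_idx <- sel[c$seed_idx]
        c$member_idx <- stats::setNames(sel[c$member_idx],
                                        names(c$member_idx))
        c
      })
      chosen <- greedy_select_clusters(cand, coverage_threshold, n_subjects)
      for (cl in chosen)
        group_steps[[length(group_steps) + 1L]] <-
          build_group_step(cl, steps, id = "pending")
    }
  }
  if (length(group_steps)) {
    o <- order(vapply(group_steps, function(g) g$peak$t_ms, 0),
               vapply(group_steps, function(g) g$band, ""),
               -vapply(group_steps, function(g) g$coverage, 0))
    group_steps <- group_steps[o]
    for (i in seq_along(group_steps)) group_steps[[i]]$id <- sprintf("S%d", i)
  } else {
    warning("no group STEP reached the coverage threshold; model is empty")
  }
  edges <- infer_connections(group_steps, n_subjects,
                             sync_window_ms, coverage_threshold)
  geom <- if (length(steps)) steps[[1]]$geometry else grid_geometry()
  times <- if (length(steps)) steps[[1]]$times_ms else numeric()
  structure(list(
    condition = as.character(condition),
    bands = sort(unique(meta$band)),
    geometry = geom,
    times_ms = times,
    group_steps = group_steps,
    edges = edges,
    parameters = list(temporal_ms = temporal_ms, spatial_px = spatial_px,
                      coverage_threshold = coverage_threshold,
                      sync_window_ms = sync_window_ms),
    provenance = list(n_subjects = n_subjects,
                      visit_id = as.character(visit_id))),
    class = "bna_model")
}

#' @export
print.bna_model <- function(x, ...) {
  cat(sprintf("<bna_model> condition %s: %d group STEPs, %d edges (n = %d)\n",
              x$condition, length(x$group_steps), nrow(x$edges),
              x$provenance$n_subjects))
  for (g in x$group_steps) print(g)
  invisible(x)
}
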