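# Shared fixtures, built in code at test time.

# Montage symmetric about the sphere centre (centroid exactly at the
# origin), so projection arc angles equal the true polar angles.
fixture_montage_sym <- function() {
  ang <- pi / 4
  pos <- rbind(
    c(0, 0, 1), c(0, 0, -1),
    c(sin(ang), 0, cos(ang)), c(-sin(ang), 0, cos(ang)),
    c(0, sin(ang), cos(ang)), c(0, -sin(ang), cos(ang)),
    c(sin(ang), 0, -cos(ang)), c(-sin(ang), 0, -cos(ang)),
    c(0, sin(ang), -cos(ang)), c(0, -sin(ang), -cos(ang)),
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  montage(sprintf("E%d", 1:14), pos)
}

# Deterministic masked random volume for segmentation tests.
fixture_volume <- function(seed, nx = 8, ny = 8, nt = 20) {
  set.seed(seed)
  g <- grid_geometry(nx, ny)
  arr <- array(rnorm(nx * ny * nt), c(nx, ny, nt))
  arr[rep(!g$mask, nt)] <- NA
  band_volume("delta", arr, (seq_len(nt) - 1) * 4, g)
}

# Separable 3-D Gaussian bump volume (no mask) with known argmax and sds.
fixture_bump_volume <- function(nx = 21, ny = 23, nt = 41,
                                c0 = c(11, 12, 21),
                                sds = c(2.5, 3, 4), amp = 10) {
  g <- grid_geometry(nx, ny)
  g$mask[] <- TRUE
  arr <- amp * outer(outer(exp(-(seq_len(nx) - c0[1])^2 / (2 * sds[1]^2)),
                           exp(-(seq_len(ny) - c0[2])^2 / (2 * sds[2]^2))),
                     exp(-(seq_len(nt) - c0[3])^2 / (2 * sds[3]^2)))
  band_volume("delta", arr, (seq_len(nt) - 1) * 4, g)
}

# Hand-built step on a tiny grid: voxel coordinates + amplitudes.
fixture_step <- function(vox, amps, band = "delta", peak_row = which.max(abs(amps)),
                         geometry = grid_geometry(8, 8), times = (0:19) * 4,
                         subject_id = "S01") {
  vox <- as.matrix(vox)
  colnames(vox) <- c("x", "y", "t_idx")
  structure(list(
    band = band,
    peak = list(x = vox[peak_row, 1], y = vox[peak_row, 2],
                t_idx = vox[peak_row, 3],
                t_ms = times[vox[peak_row, 3]],
                amplitude = amps[peak_row],
                polarity = if (amps[peak_row] > 0) 1L else -1L),
    voxels = vox, amplitudes = amps,
    rise_time_ms = times[min(vox[, 3])],
    times_ms = times, geometry = geometry,
    subject_id = subject_id, condition = "Target", visit_id = "V1"),
    class = "bna_step")
}

# Negate a step's amplitudes (same voxels).
step_negate <- function(st) {
  st$amplitudes <- -st$amplitudes
  st$peak$amplitude <- -st$peak$amplitude
  st$peak$polarity <- -st$peak$polarity
  st
}

# Brute-force 26-neighbour extrema scan; the independent oracle for
# detect_peaks (strict inequality, NA-aware, min-amplitude gated).
brute_force_peaks <- function(vol, min_abs = 0) {
  arr <- vol$data
  d <- dim(arr)
  hits <- NULL
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (t in seq_len(d[3])) {
    v <- arr[x, y, t]
    if (is.na(v) || v == 0 || abs(v) < min_abs) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dt in -1:1) {
      if (dx == 0 && dy == 0 && dt == 0) next
      xx <- x + dx; yy <- y + dy; tt <- t + dt
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
          tt < 1 || tt > d[3]) next
      w <- arr[xx, yy, tt]
      if (!is.na(w)) nb <- c(nb, w)
    }
    if (length(nb) && (all(v > nb) || all(v < nb)))
      hits <- rbind(hits, c(x, y, t))
  }
  hits
}

# Component sets used by the simulation-based tests: three oddball-like
# events (theta N100/P200, delta P300) with configurable jitter.
fixture_components <- function(latency_jitter = 10, center_jitter = 2 / 33,
                               amp_jitter = 0.5) {
  list(
    component_spec("N100", 100, latency_jitter, c(0.5, 0.35), 0.12, -8,
                   amp_jitter, "theta", "Target", center_jitter),
    component_spec("P200", 180, latency_jitter, c(0.5, 0.40), 0.12, 7,
                   amp_jitter, "theta", "Target", center_jitter),
    component_spec("P300", 375, latency_jitter, c(0.5, 0.70), 0.14, 10,
                   amp_jitter, "delta", "Target", center_jitter))
}

# Target/Novel component sets for the classification study.  The
# conditions differ only in the P300: 40 ms earlier and 4 pixels anterior
# for Novel.  With `identical_templates = TRUE` the two conditions share
# one P300 component outright (identical realizations), so Target and
# Novel records of a subject differ by trial noise alone - the
# exchangeable null for the end-to-end classifier.
study_components <- function(identical_templates = FALSE) {
  shared <- list(
    component_spec("N100", 100, 10, c(0.5, 0.35), 0.12, -8, 0.5, "theta",
                   c("Target", "Novel"), 2 / 33),
    component_spec("P200", 180, 10, c(0.5, 0.40), 0.12, 7, 0.5, "theta",
                   c("Target", "Novel"), 2 / 33))
  if (identical_templates)
    c(shared, list(
      component_spec("P300", 375, 10, c(0.5, 0.70), 0.14, 10, 0.5,
                     "delta", c("Target", "Novel"), 2 / 33)))
  else
    c(shared, list(
      component_spec("P300t", 375, 10, c(0.5, 0.70), 0.14, 10, 0.5,
                     "delta", "Target", 2 / 33),
      component_spec("P300n", 335, 10, c(0.5, 0.70 - 4 / 37), 0.14, 10,
                     0.5, "delta", "Novel", 2 / 33)))
}

# Train-on-V3, test-on-V1/V2 classification study; returns per-visit AUCs.
run_classification_study <- function(seed, identical_templates = FALSE,
                                     n = 30) {
  m <- demo_montage()
  comps <- study_components(identical_templates)
  cfg <- sim_config(n_subjects = n, n_visits = 3, n_trials = 600,
                    noise_sd_uv = 2.5 * sqrt(60), seed = seed)
  sim <- simulate_dataset(cfg, comps, m)
  seg <- function(visit) segment_cohort(
    sim_records(sim, condition = c("Target", "Novel"), visit_id = visit),
    m, bands = c("delta", "theta"))
  ss3 <- seg("V3"); ss1 <- seg("V1"); ss2 <- seg("V2")
  models <- build_condition_models(ss3)
  ft3 <- score_cohort(ss3, models)
  ft1 <- score_cohort(ss1, models)
  ft2 <- score_cohort(ss2, models)
  all_ft <- rbind(ft3, ft1, ft2)
  tr_rows <- seq_len(nrow(ft3))
  scaled <- scale_features(all_ft, tr_rows)
  svm <- train_svm(scaled[tr_rows, ], C = 10^-3.5)
  key <- interaction(all_ft$subject_id, all_ft$visit_id, all_ft$condition)
  auc_of <- function(ft) {
    rows <- scaled[match(interaction(ft$subject_id, ft$visit_id,
                                     ft$condition), key), ]
    roc_auc(decision_scores(svm, rows), rows$condition)$auc
  }
  list(models = models,
       aucs = c(V1 = auc_of(ft1), V2 = auc_of(ft2)))
}

# Map a planted component to the closest group STEP of matching band and
# polarity (by peak latency); NULL when none exists.
match_planted <- function(model, band, polarity, latency_ms) {
  cand <- Filter(function(g) g$band == band && g$polarity == polarity,
                 model$group_steps)
  if (!length(cand)) return(NULL)
  cand[[which.min(vapply(cand, function(g) abs(g$peak$t_ms - latency_ms),
                         0))]]
}
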