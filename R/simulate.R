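#' Specify a simulated ERP component
#'
#' A component is a spatiotemporal kernel: a Gaussian-windowed cosine at the
#' carrier band's centre frequency in time, multiplied by a 2-D Gaussian
#' over the projected electrode positions in space.  The temporal envelope
#' sd is one third of the carrier period, which keeps side lobes of the
#' cosine far below the half-amplitude threshold so each component produces
#' a single dominant spatiotemporal extremum in its band.
#'
#' @param name component label (e.g. `"P300"`).
#' @param latency_ms nominal peak latency, ms post-stimulus.
#' @param latency_jitter_sd_ms sd of the per-subject-visit latency draw.
#' @param center_2d length-2 vector, grid-fraction coordinates in `[0,1]^2`
#'   (left-right, anterior-posterior).
#' @param spatial_sd spatial Gaussian sd, grid-fraction units.
#' @param amplitude_uv signed peak amplitude, microvolt (sign = polarity).
#' @param amplitude_jitter_sd_uv sd of the per-visit additive amplitude
#'   jitter, microvolt.
#' @param carrier_band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @param conditions character vector of conditions the component occurs in.
#' @param center_jitter_sd sd of the per-subject spatial displacement of the
#'   component centre, grid-fraction units (default 0).
#' @return An object of class `bna_component`.
#' @export
component_spec <- function(name, latency_ms, latency_jitter_sd_ms = 0,
                           center_2d = c(0.5, 0.5), spatial_sd = 0.12,
                           amplitude_uv = 10, amplitude_jitter_sd_uv = 0,
                           carrier_band = "delta",
                           conditions = "Target",
                           center_jitter_sd = 0) {
  check_band(carrier_band)
  stopifnot(spatial_sd > 0, length(center_2d) == 2,
            all(center_2d >= 0 & center_2d <= 1),
            latency_jitter_sd_ms >= 0, amplitude_jitter_sd_uv >= 0,
            center_jitter_sd >= 0, amplitude_uv != 0)
  structure(list(name = name, latency_ms = latency_ms,
                 latency_jitter_sd_ms = latency_jitter_sd_ms,
                 center_2d = as.numeric(center_2d), spatial_sd = spatial_sd,
                 amplitude_uv = amplitude_uv,
                 amplitude_jitter_sd_uv = amplitude_jitter_sd_uv,
                 carrier_band = carrier_band,
                 conditions = as.character(conditions),
                 center_jitter_sd = center_jitter_sd),
            class = "bna_component")
}

#' Default oddball component set
#'
#' Components resembling the classical auditory-oddball ERP complex: a
#' fronto-central Target N100 (~100 ms) and P200 (~180 ms) in the theta
#' band, a posterior Target P300 (~375 ms) in the delta band, plus a Novel
#' N100 (~145 ms, theta) and a more central, earlier Novel P300 (~335 ms,
#' delta).  Frequent trials carry no planted component (background noise
#' only).
#'
#' @return list of [component_spec()] objects.
#' @export
oddball_components <- function() {
  list(
    component_spec("Target_N100", 100, 10, c(0.5, 0.35), 0.12, -8, 0.5,
                   "theta", "Target", 0.03),
    component_spec("Target_P200", 180, 10, c(0.5, 0.40), 0.12, 7, 0.5,
                   "theta", "Target", 0.03),
    component_spec("Target_P300", 375, 10, c(0.5, 0.70), 0.14, 10, 0.5,
                   "delta", "Target", 0.03),
    component_spec("Novel_N100", 145, 10, c(0.5, 0.35), 0.12, -8, 0.5,
                   "theta", "Novel", 0.03),
    component_spec("Novel_P300", 335, 10, c(0.5, 0.55), 0.14, 10, 0.5,
                   "delta", "Novel", 0.03)
  )
}

#' Simulation configuration
#'
#' @param n_subjects,n_visits,n_trials cohort and session sizes.  The
#'   default 600 trials at proportions 0.8/0.1/0.1 reflect a standard
#'   3-stimulus oddball session.
#' @param condition_proportions named fractions summing to 1.
#' @param sampling_rate_hz sampling rate (default 256 Hz).
#' @param epoch_window_ms `c(start, end)` relative to stimulus onset,
#'   `start < 0 < end` (default -200..800 ms).
#' @param noise_sd_uv per-trial additive white-noise sd, microvolt.
#' @param between_subject_amp_sd_uv sd of the stable per-subject amplitude
#'   deviation, microvolt (scales each component's amplitude once per
#'   subject).
#' @param artifact_fraction fraction of trials receiving a 150 microvolt
#'   square excursion on one random channel (epochs mode only).
#' @param seed integer RNG seed.
#' @return An object of class `bna_sim_config`.
#' @export
sim_config <- function(n_subjects = 20, n_visits = 1, n_trials = 600,
                       condition_proportions = c(Frequent = 0.8,
                                                 Target = 0.1, Novel = 0.1),
                       sampling_rate_hz = 256,
                       epoch_window_ms = c(-200, 800),
                       noise_sd_uv = 20,
                       between_subject_amp_sd_uv = 1,
                       artifact_fraction = 0,
                       seed = 1) {
  if (abs(sum(condition_proportions) - 1) > 1e-9 ||
      any(condition_proportions < 0) ||
      is.null(names(condition_proportions)))
    bna_stop("bna_invalid_proportions",
             "condition_proportions must be named, non-negative and sum to 1")
  if (n_trials < 1)
    bna_stop("bna_invalid_config", "n_trials must be positive")
  if (!(epoch_window_ms[1] < 0 && epoch_window_ms[2] > 0))
    bna_stop("bna_invalid_config", "epoch window must satisfy start < 0 < end")
  structure(list(n_subjects = n_subjects, n_visits = n_visits,
                 n_trials = n_trials,
                 condition_proportions = condition_proportions,
                 sampling_rate_hz = sampling_rate_hz,
                 epoch_window_ms = as.numeric(epoch_window_ms),
                 noise_sd_uv = noise_sd_uv,
                 between_subject_amp_sd_uv = between_subject_amp_sd_uv,
                 artifact_fraction = artifact_fraction,
                 seed = as.integer(seed)),
            class = "bna_sim_config")
}

# Integer trial counts per condition by largest remainder, so the printed
# proportions are honoured exactly (600 * 0.8/0.1/0.1 -> 480/60/60).
trial_counts <- function(n_trials, proportions) {
  exact <- n_trials * proportions
  counts <- floor(exact)
  rem <- n_trials - sum(counts)
  if (rem > 0) {
    o <- order(exact - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  counts
}

epoch_times_ms <- function(config) {
  dt <- 1000 / config$sampling_rate_hz
  k0 <- round(config$epoch_window_ms[1] / dt)
  k1 <- round(config$epoch_window_ms[2] / dt)
  (k0:k1) * dt
}

#' Deterministic spatiotemporal template of one component
#'
#' The channels x time matrix contributed by a component at a given realized
#' latency, amplitude and centre (no noise).
#'
#' @param comp a [component_spec()].
#' @param m a projected [montage()].
#' @param times_ms sample times, ms.
#' @param latency_ms,amplitude_uv,center_2d realized parameters (defaults:
#'   the component's nominal values).
#' @return channels x time numeric matrix (microvolt).
#' @export
component_template <- function(comp, m, times_ms,
                               latency_ms = comp$latency_ms,
                               amplitude_uv = comp$amplitude_uv,
                               center_2d = comp$center_2d) {
  f <- BNA_BAND_CENTER[[comp$carrier_band]]
  period_ms <- 1000 / f
  env_sd <- period_ms / 3
  tt <- times_ms - latency_ms
  temporal <- cos(2 * pi * tt / period_ms) * exp(-tt^2 / (2 * env_sd^2))
  d2 <- (m$pos2d[, 1] - center_2d[1])^2 + (m$pos2d[, 2] - center_2d[2])^2
  spatial <- exp(-d2 / (2 * comp$spatial_sd^2))
  amplitude_uv * outer(spatial, temporal)
}

#' Simulate a multi-subject, multi-visit oddball ERP dataset
#'
#' Each trial is the sum, over the components applicable to its condition,
#' of a spatiotemporal kernel plus white noise.  Latency is drawn once per
#' subject-visit (`Normal(latency_ms, latency_jitter_sd_ms)`), a stable
#' amplitude scale once per subject
#' (`Normal(1, between_subject_amp_sd_uv / |amplitude_uv|)`), an additive
#' amplitude jitter once per visit, and a spatial centre displacement once
#' per subject.  With `return_epochs = FALSE` (default) the per-condition
#' trial average is generated directly (noise sd scaled by
#' `1/sqrt(n_trials_condition)`); with `return_epochs = TRUE` raw trials are
#' returned and `artifact_fraction` of them receive a 150 microvolt square
#' excursion on one random channel.
#'
#' @param config a [sim_config()].
#' @param components list of [component_spec()].
#' @param m a [montage()] (projected automatically if needed), >= 16
#'   electrodes.
#' @param return_epochs return raw trials instead of averages.
#' @return An object of class `bna_simdata`: `montage`, `records` (list of
#'   [erp_record()], averaged mode), `epochs` (epochs mode), and
#'   `ground_truth` (data.frame of realized per-subject-visit-component
#'   latency, amplitude and centre).
#' @export
simulate_dataset <- function(config, components = oddball_components(),
                             m = demo_montage(), return_epochs = FALSE) {
  stopifnot(inherits(config, "bna_sim_config"))
  if (length(m$labels) < 16)
    bna_stop("bna_too_few_electrodes",
             "simulation needs a montage with at least 16 electrodes")
  if (is.null(m$pos2d)) m <- project_montage(m)
  times <- epoch_times_ms(config)
  for (comp in components)
    if (comp$latency_ms <= times[1] || comp$latency_ms >= times[length(times)])
      bna_stop("bna_component_outside_window",
               sprintf("component '%s' latency %g ms outside epoch window",
                       comp$name, comp$latency_ms))
  conds <- names(config$condition_proportions)
  counts <- trial_counts(config$n_trials, config$condition_proportions)
  n_ch <- length(m$labels)
  n_t <- length(times)
  set.seed(config$seed)

  records <- list()
  epochs <- list()
  gt <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    # subject-level draws (stable across visits), fixed order
    scale_s <- vapply(components, function(comp)
      rnorm(1, 1, config$between_subject_amp_sd_uv / abs(comp$amplitude_uv)),
      0)
    center_s <- lapply(components, function(comp)
      comp$center_2d + rnorm(2, 0, comp$center_jitter_sd))
    for (v in seq_len(config$n_visits)) {
      vid <- sprintf("V%d", v)
      lat_v <- vapply(components, function(comp)
        rnorm(1, comp$latency_ms, comp$latency_jitter_sd_ms), 0)
      ampjit_v <- vapply(components, function(comp)
        rnorm(1, 0, comp$amplitude_jitter_sd_uv), 0)
      amp_v <- vapply(seq_along(components), function(i)
        components[[i]]$amplitude_uv * scale_s[i] + ampjit_v[i], 0)
      for (ci in seq_along(conds)) {
        cond <- conds[ci]
        tmpl <- matrix(0, n_ch, n_t)
        for (i in seq_along(components)) {
          comp <- components[[i]]
          if (!cond %in% comp$conditions) next
          tmpl <- tmpl + component_template(comp, m, times,
                                            latency_ms = lat_v[i],
                                            amplitude_uv = amp_v[i],
                                            center_2d = center_s[[i]])
          gt[[length(gt) + 1L]] <- data.frame(
            subject_id = sid, visit_id = vid, condition = cond,
            component = comp$name, band = comp$carrier_band,
            latency_ms = lat_v[i], amplitude_uv = amp_v[i],
            center_u = center_s[[i]][1], center_v = center_s[[i]][2])
        }
        rownames(tmpl) <- m$labels
        if (return_epochs) {
          n_tr <- counts[ci]
          ep <- array(0, dim = c(n_tr, n_ch, n_t))
          for (tr in seq_len(n_tr))
            ep[tr, , ] <- tmpl +
              matrix(rnorm(n_ch * n_t, 0, config$noise_sd_uv), n_ch, n_t)
          if (config$artifact_fraction > 0 && n_tr > 0) {
            n_art <- round(config$artifact_fraction * n_tr)
            if (n_art > 0) {
              art_tr <- sample(n_tr, n_art)
              for (tr in art_tr) {
                ch <- sample(n_ch, 1)
                span <- seq(max(1, floor(n_t / 3)), min(n_t, floor(2 * n_t / 3)))
                ep[tr, ch, span] <- ep[tr, ch, span] + 150
              }
            }
          }
          epochs[[length(epochs) + 1L]] <- list(
            subject_id = sid, visit_id = vid, condition = cond,
            epochs = ep, times_ms = times,
            sampling_rate_hz = config$sampling_rate_hz)
        } else {
          noise_sd <- config$noise_sd_uv / sqrt(max(1, counts[ci]))
          dat <- tmpl + matrix(rnorm(n_ch * n_t, 0, noise_sd), n_ch, n_t)
          records[[length(records) + 1L]] <- erp_record(
            dat, times, config$sampling_rate_hz, sid, vid, cond)
        }
      }
    }
  }
  structure(list(montage = m,
                 records = if (!return_epochs) records,
                 epochs = if (return_epochs) epochs,
                 ground_truth = do.call(rbind, gt),
                 config = config,
                 components = components,
                 times_ms = times),
            class = "bna_simdata")
}

#' @export
print.bna_simdata <- function(x, ...) {
  n <- if (!is.null(x$records)) length(x$records) else length(x$epochs)
  cat(sprintf("<bna_simdata> %d subjects x %d visits, %d %s\n",
              x$config$n_subjects, x$config$n_visits, n,
              if (!is.null(x$records)) "averaged records" else "epoch sets"))
  invisible(x)
}

#' Pick records from a simulated dataset
#'
#' @param sim a `bna_simdata` (averaged mode).
#' @param condition,visit_id optional filters.
#' @return list of [erp_record()].
#' @export
sim_records <- function(sim, condition = NULL, visit_id = NULL) {
  stopifnot(inherits(sim, "bna_simdata"), !is.null(sim$records))
  keep <- vapply(sim$records, function(r) {
    (is.null(condition) || r$condition %in% condition) &&
      (is.null(visit_id) || r$visit_id %in% visit_id)
  }, TRUE)
  sim$records[keep]
}
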