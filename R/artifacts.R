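#' Reject artifact-contaminated channels and epochs
#'
#' Two-stage cleaning of raw epochs (trials x channels x time, microvolt):
#'
#' 1. *Channels* are marked bad when the fraction of their samples with
#'    absolute amplitude above `amp_limit_uv` exceeds `bad_channel_frac`, or
#'    when the median across trials of their per-trial correlation with the
#'    mean of their `k_neighbors` nearest neighbours (3-D electrode
#'    distance) falls below `neighbor_corr_min`.
#'    Bad channels are replaced by the average of their nearest good
#'    neighbours.
#' 2. *Epochs* are dropped when any sample (after channel repair) lies
#'    outside the range `±amp_limit_uv` (a sample at exactly the limit is
#'    retained), or deviates from that channel's across-trial mean by more
#'    than `sd_limit` channel standard deviations.
#'
#' @param epochs numeric array, trials x channels x time.
#' @param m a [montage()] matching the channel dimension.
#' @param amp_limit_uv absolute amplitude limit (default 100).
#' @param bad_channel_frac fraction of out-of-range samples that condemns a
#'   channel (default 0.2).
#' @param neighbor_corr_min minimum correlation with the neighbour mean
#'   (default 0.4).
#' @param k_neighbors neighbours used for the dissimilarity test and for
#'   repairing bad channels (default 4).
#' @param sd_limit deviation limit in channel standard deviations
#'   (default 7).
#' @return list with `epochs` (cleaned array), `bad_channels` (indices),
#'   and `log` (data.frame recording every removal and its triggering rule).
#' @export
reject_artifacts <- function(epochs, m,
                             amp_limit_uv = 100, bad_channel_frac = 0.2,
                             neighbor_corr_min = 0.4, k_neighbors = 4,
                             sd_limit = 7) {
  stopifnot(length(dim(epochs)) == 3)
  n_tr <- dim(epochs)[1]; n_ch <- dim(epochs)[2]; n_t <- dim(epochs)[3]
  if (n_tr < 2)
    bna_stop("bna_too_few_trials", "artifact rejection needs at least 2 trials")
  stopifnot(inherits(m, "bna_montage"), n_ch == length(m$labels))
  log <- list()
  dmat <- as.matrix(stats::dist(m$pos3d))
  diag(dmat) <- Inf
  neighbors <- lapply(seq_len(n_ch), function(c)
    order(dmat[c, ])[seq_len(min(k_neighbors, n_ch - 1))])

  # stage 1: channel screening
  bad <- logical(n_ch)
  for (c in seq_len(n_ch)) {
    x <- epochs[, c, ]
    frac_out <- mean(abs(x) > amp_limit_uv)
    if (frac_out > bad_channel_frac) {
      bad[c] <- TRUE
      log[[length(log) + 1L]] <- data.frame(
        kind = "channel", index = c, label = m$labels[c],
        rule = sprintf("amplitude_fraction %.3f > %.2f", frac_out,
                       bad_channel_frac))
      next
    }
    nb_mean <- apply(epochs[, neighbors[[c]], , drop = FALSE], c(1, 3), mean)
    # median of per-trial correlations: robust against a minority of
    # artifact epochs, sensitive to a genuinely dissimilar channel
    r_tr <- suppressWarnings(vapply(seq_len(n_tr), function(tr)
      stats::cor(x[tr, ], nb_mean[tr, ]), 0))
    r <- stats::median(r_tr, na.rm = TRUE)
    if (!is.na(r) && r < neighbor_corr_min) {
      bad[c] <- TRUE
      log[[length(log) + 1L]] <- data.frame(
        kind = "channel", index = c, label = m$labels[c],
        rule = sprintf("neighbor_correlation %.3f < %.2f", r,
                       neighbor_corr_min))
    }
  }
  if (any(bad)) {
    good <- which(!bad)
    if (length(good) == 0)
      bna_stop("bna_all_channels_rejected", "every channel was marked bad")
    for (c in which(bad)) {
      nb_good <- good[order(dmat[c, good])][seq_len(min(k_neighbors,
                                                        length(good)))]
      epochs[, c, ] <- apply(epochs[, nb_good, , drop = FALSE], c(1, 3), mean)
    }
  }

  # stage 2: epoch screening
  keep <- rep(TRUE, n_tr)
  ch_mean <- apply(epochs, c(2, 3), mean)          # channels x time
  dev <- sweep(epochs, c(2, 3), ch_mean)
  ch_sd <- sqrt(apply(dev^2, 2, mean))             # pooled per channel
  ch_sd[ch_sd == 0] <- Inf
  for (tr in seq_len(n_tr)) {
    x <- epochs[tr, , ]
    if (any(abs(x) > amp_limit_uv)) {
      keep[tr] <- FALSE
      log[[length(log) + 1L]] <- data.frame(
        kind = "epoch", index = tr, label = NA_character_,
        rule = sprintf("amplitude outside +-%g uV", amp_limit_uv))
      next
    }
    z <- abs(dev[tr, , ]) / ch_sd
    if (any(z > sd_limit)) {
      keep[tr] <- FALSE
      log[[length(log) + 1L]] <- data.frame(
        kind = "epoch", index = tr, label = NA_character_,
        rule = sprintf("deviation > %g channel SDs", sd_limit))
    }
  }
  if (!any(keep))
    bna_stop("bna_all_epochs_rejected", "every epoch was rejected")
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(kind = character(), index = integer(), label = character(),
               rule = character())
  list(epochs = epochs[keep, , , drop = FALSE],
       bad_channels = which(bad), log = log_df)
}

#' Average epochs into an ERP record
#'
#' Pointwise mean across trials with optional baseline correction (subtract
#' the pre-stimulus mean per channel; on by default).
#'
#' @param epochs trials x channels x time array.
#' @param times_ms time axis, ms.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param subject_id,visit_id,condition record metadata.
#' @param baseline_correct subtract per-channel pre-stimulus mean.
#' @param channel_labels optional electrode labels for the rows.
#' @return A [erp_record()].
#' @export
average_epochs <- function(epochs, times_ms, sampling_rate_hz,
                           subject_id = NA, visit_id = NA, condition = NA,
                           baseline_correct = TRUE, channel_labels = NULL) {
  stopifnot(length(dim(epochs)) == 3, dim(epochs)[1] >= 1)
  avg <- apply(epochs, c(2, 3), mean)
  if (baseline_correct) {
    pre <- times_ms < 0
    if (any(pre)) avg <- avg - rowMeans(avg[, pre, drop = FALSE])
  }
  if (!is.null(channel_labels)) rownames(avg) <- channel_labels
  erp_record(avg, times_ms, sampling_rate_hz, subject_id, visit_id, condition)
}

#' Preprocess an ERP record into band volumes
#'
#' Convenience composition of [bandpass_decompose()] and
#' [interpolate_grid()]: one high-resolution scalp volume per requested
#' band.
#'
#' @param rec a [erp_record()].
#' @param m a projected [montage()].
#' @param bands band names.
#' @param geometry a [grid_geometry()].
#' @param filter_length optional FIR length override.
#' @return named list of [band_volume()] objects.
#' @export
preprocess_erp <- function(rec, m, bands = names(BNA_BANDS),
                           geometry = grid_geometry(), filter_length = NULL) {
  if (is.null(m$pos2d)) m <- project_montage(m)
  if (!identical(rownames(rec$data), m$labels) &&
      !is.null(rownames(rec$data)))
    if (!setequal(rownames(rec$data), m$labels))
      bna_stop("bna_channel_mismatch",
               "ERP channel labels do not match the montage")
    else
      rec$data <- rec$data[m$labels, , drop = FALSE]
  mats <- bandpass_decompose(rec, bands, filter_length)
  interpolate_grid(mats, m, geometry, rec$times_ms)
}
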