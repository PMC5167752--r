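test_that("artifact rejection drops exactly the contaminated epochs", {
  m <- demo_montage()
  n_ch <- length(m$labels); n_t <- 64
  set.seed(1)
  # spatially coherent background (shared waveform, per-channel gain ~ 1)
  # plus small sensor noise; max |amp| stays well below 40 uV
  base <- matrix(sin(seq(0, 6 * pi, length.out = n_t)) * 15, n_ch, n_t,
                 byrow = TRUE) * runif(n_ch, 0.8, 1.2)
  clean <- array(0, c(60, n_ch, n_t))
  for (tr in 1:60) clean[tr, , ] <- base + rnorm(n_ch * n_t, 0, 3)

  # clean case: zero removals
  res <- reject_artifacts(clean, m)
  expect_identical(dim(res$epochs), dim(clean))
  expect_identical(nrow(res$log), 0L)

  # 5 planted 150 uV epochs among 60: exactly those dropped, and the
  # outcome matches a direct threshold scan
  bad <- clean
  planted <- c(3L, 17L, 29L, 44L, 58L)
  for (tr in planted) bad[tr, 5, 10:20] <- 150
  res2 <- reject_artifacts(bad, m)
  dropped <- setdiff(seq_len(60), seq_len(60)[-planted])
  oracle <- which(apply(bad, 1, function(e) any(abs(e) > 100)))
  expect_identical(oracle, planted)
  expect_identical(res2$log$index[res2$log$kind == "epoch"], planted)
  expect_identical(dim(res2$epochs)[1], 55L)

  # an epoch at exactly +-100 uV is retained (rule is "outside the range");
  # background sd 16 keeps the boundary sample inside the 7-SD envelope,
  # and the neighbour-dissimilarity rule is disabled so no repair masks it
  set.seed(5)
  edge <- array(rnorm(60 * n_ch * n_t, 0, 16), c(60, n_ch, n_t))
  edge[7, 3, 12] <- 100
  edge[8, 3, 12] <- -100
  res3 <- reject_artifacts(edge, m, neighbor_corr_min = -1)
  expect_identical(nrow(res3$log), 0L)

  # all epochs rejected is a named error (the excursion is common to all
  # channels, so no channel is singled out as dissimilar and repaired)
  allbad <- clean; allbad[, , 5] <- 500
  expect_error(reject_artifacts(allbad, m),
               class = "bna_all_epochs_rejected")
})

test_that("bad channels are detected and repaired from neighbours", {
  m <- demo_montage()
  n_ch <- length(m$labels)
  set.seed(2)
  base <- sin(seq(0, 4 * pi, length.out = 64)) * 20
  ep <- array(rep(rep(base, each = n_ch), 10), c(n_ch, 64, 10))
  ep <- aperm(ep, c(3, 1, 2)) + rnorm(10 * n_ch * 64, 0, 1)
  ep[, 4, ] <- rnorm(10 * 64, 0, 1)  # decorrelated channel
  res <- reject_artifacts(ep, m)
  expect_true(4 %in% res$bad_channels)
  # repaired channel now tracks its neighbours
  expect_gt(cor(as.vector(res$epochs[, 4, ]), rep(base, each = 10)), 0.8)
})

test_that("epoch averaging is exact for identity and symmetry cases", {
  times <- ((-10):20) * 4
  one <- matrix(rnorm(5 * 31), 5, 31)
  ep <- array(rep(one, each = 3), c(3, 5, 31))
  for (i in 1:3) ep[i, , ] <- one
  avg <- average_epochs(ep, times, 250, "s", "v", "Target",
                        baseline_correct = FALSE)
  expect_equal(avg$data, one, ignore_attr = TRUE)

  two <- array(0, c(2, 5, 31))
  two[1, , ] <- 1; two[2, , ] <- -1
  avg2 <- average_epochs(two, times, 250, "s", "v", "Target",
                         baseline_correct = FALSE)
  expect_true(all(avg2$data == 0))

  # 60 noisy epochs: average within 3 * noise_sd / sqrt(60) of template
  set.seed(3)
  noise_sd <- 5
  tmpl <- matrix(rnorm(5 * 31, 0, 10), 5, 31)
  noisy <- array(0, c(60, 5, 31))
  for (i in 1:60) noisy[i, , ] <- tmpl + rnorm(5 * 31, 0, noise_sd)
  avg3 <- average_epochs(noisy, times, 250, "s", "v", "Target",
                         baseline_correct = FALSE)
  expect_lt(max(abs(avg3$data - tmpl)), 4.5 * noise_sd / sqrt(60))
  # 3 standard errors bound holds for ~99.7 % of samples
  expect_gt(mean(abs(avg3$data - tmpl) < 3 * noise_sd / sqrt(60)), 0.98)
})

test_that("band decomposition is zero-phase with the stated band edges", {
  fs <- 256
  # linearity: zero in, zero out, in all four bands
  zrec <- erp_record(matrix(0, 3, 300), (0:299) * 1000 / fs, fs,
                     "s", "v", "Target")
  out0 <- bandpass_decompose(zrec)
  expect_identical(sort(names(out0)),
                   sort(c("delta", "theta", "alpha", "beta")))
  for (b in out0) expect_true(all(b == 0))

  # a 5 Hz unit sinusoid passes theta (within 5 %) and is strongly
  # attenuated by delta; expected amplitudes derived from the designed
  # filter's frequency response evaluated at 5 Hz (squared: two passes)
  t <- seq(0, 4, by = 1 / fs)
  x <- matrix(sin(2 * pi * 5 * t), 1)
  rec <- erp_record(x, (seq_along(t) - 1) * 1000 / fs, fs, "s", "v", "T")
  out <- bandpass_decompose(rec, c("delta", "theta"), filter_length = 255)
  mid <- 300:700
  h_theta <- bna:::design_fir_bandpass(255, 3, 8, fs)
  h_delta <- bna:::design_fir_bandpass(255, 0.5, 4, fs)
  expect_equal(max(abs(out$theta[1, mid])),
               bna:::fir_response(h_theta, 5, fs)^2, tolerance = 0.01)
  expect_lt(max(abs(out$theta[1, mid]) - 1), 0.05)
  expect_lt(max(abs(out$delta[1, mid])),
            max(0.15, 2 * bna:::fir_response(h_delta, 5, fs)^2))

  # zero net phase: no lag between band-limited input and output
  cc <- stats::ccf(out$theta[1, mid], x[1, mid], lag.max = 8, plot = FALSE)
  expect_equal(as.numeric(cc$lag)[which.max(cc$acf)], 0)

  # guard rails
  expect_error(bandpass_decompose(rec, "beta", filter_length = 2000),
               class = "bna_filter_too_long")
  lowrate <- erp_record(matrix(0, 1, 100), (0:99) * 1000 / 50, 50,
                        "s", "v", "T")
  expect_error(bandpass_decompose(lowrate, "beta"),
               class = "bna_filter_band")
})

test_that("montage projection maps the vertex to centre and preserves arcs", {
  m <- project_montage(fixture_montage_sym())
  # vertex at grid centre
  expect_equal(unname(m$pos2d["E1", ]), c(0.5, 0.5), tolerance = 1e-12)
  # mirror-symmetric electrodes symmetric about u = 0.5
  expect_equal(m$pos2d["E3", "u"] - 0.5, 0.5 - m$pos2d["E4", "u"],
               tolerance = 1e-9)
  expect_equal(m$pos2d["E3", "v"], m$pos2d["E4", "v"], tolerance = 1e-9)
  # azimuthal-equidistant arcs: the equator electrode (90 degrees) maps to
  # radius (pi/2) * scale, the 45-degree ring to exactly half of that
  r_eq <- sqrt(sum((m$pos2d["E11", ] - 0.5)^2))
  r_mid <- sqrt(sum((m$pos2d["E3", ] - 0.5)^2))
  scale <- 0.45 / (3 * pi / 4)  # outermost arc: the 135-degree lower ring
  expect_equal(r_eq, (pi / 2) * scale, tolerance = 1e-9)
  expect_equal(r_mid / r_eq, 0.5, tolerance = 1e-9)

  expect_error(project_montage(montage(c("a", "b", "c", "d"),
                                       cbind(c(1, -1, 2, -2), 0, 0))),
               class = "bna_degenerate_montage")
})

test_that("grid interpolation reproduces constants, electrodes and is linear", {
  m <- demo_montage()
  geom <- grid_geometry()
  times <- (0:3) * 4
  const <- matrix(2.5, length(m$labels), 4)
  vols <- interpolate_grid(list(delta = const), m, geom, times)
  v <- vols$delta
  expect_identical(dim(v$data), c(33L, 37L, 4L))
  expect_equal(max(abs(v$data[!is.na(v$data)] - 2.5)), 0, tolerance = 1e-9)
  expect_true(all(is.na(v$data[rep(!geom$mask, 4)])))

  # a pixel coincident with an electrode's projected position takes that
  # electrode's value (demo montage vertex projects to the exact centre
  # pixel of the odd-sized grid)
  set.seed(4)
  vals <- matrix(rnorm(length(m$labels)), ncol = 1)
  vv <- interpolate_grid(list(delta = vals), m, geom, 0)$delta
  expect_equal(vv$data[17, 19, 1], vals[1], tolerance = 1e-6)

  # linearity in the data
  v1 <- matrix(rnorm(length(m$labels) * 2), ncol = 2)
  v2 <- matrix(rnorm(length(m$labels) * 2), ncol = 2)
  ga <- interpolate_grid(list(d = v1), m, geom, (0:1) * 4)$d$data
  gb <- interpolate_grid(list(d = v2), m, geom, (0:1) * 4)$d$data
  gc <- interpolate_grid(list(d = 2 * v1 - 3 * v2), m, geom,
                         (0:1) * 4)$d$data
  expect_equal(gc[!is.na(gc)], (2 * ga - 3 * gb)[!is.na(gc)],
               tolerance = 1e-9)

  expect_error(interpolate_grid(list(d = matrix(0, 3, 1)),
                                montage(c("a", "b", "c"),
                                        diag(3), pos2d = diag(3)[, 1:2]),
                                geom, 0),
               class = "bna_too_few_electrodes")
})

test_that("full preprocessing preserves a planted component's peak latency", {
  m <- demo_montage()
  comps <- fixture_components(latency_jitter = 0, center_jitter = 0,
                              amp_jitter = 0)
  cfg <- sim_config(n_subjects = 1, n_trials = 1,
                    condition_proportions = c(Target = 1),
                    noise_sd_uv = 0, between_subject_amp_sd_uv = 0, seed = 1)
  sim <- simulate_dataset(cfg, comps, m)
  rec <- sim_records(sim, condition = "Target")[[1]]
  vols <- preprocess_erp(rec, m, c("delta", "theta"))
  dt <- 1000 / cfg$sampling_rate_hz
  pk_d <- detect_peaks(vols$delta, 3)
  p300 <- pk_d[which.max(pk_d$amplitude), ]
  expect_lte(abs(p300$t_ms - 375), dt + 1e-9)
  pk_t <- detect_peaks(vols$theta, 3)
  n100 <- pk_t[which.min(pk_t$amplitude), ]
  expect_lte(abs(n100$t_ms - 100), 2 * dt + 1e-9)
})
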