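test_that("spatiotemporal covariance matches direct arithmetic", {
  vox <- rbind(c(3, 3, 5), c(4, 3, 5))
  s <- fixture_step(vox, c(1, 3))   # mean 2
  g <- fixture_step(vox, c(2, 6))   # mean 4
  # (1-2)(2-4) + (3-2)(6-4) = 4
  expect_equal(topo_cov(s, g), 4)

  # self-covariance is N times the variance (the defining identity)
  st <- fixture_step(rbind(c(2, 2, 3), c(3, 2, 3), c(2, 3, 3)), c(1, 5, 9))
  expect_equal(topo_cov(st, st), sum((c(1, 5, 9) - 5)^2))

  # disjoint voxel sets give zero
  s2 <- fixture_step(rbind(c(6, 6, 10)), 4)
  expect_identical(topo_cov(st, s2), 0)
})

test_that("topographic correlation is bounded with exact limit cases", {
  st <- fixture_step(rbind(c(2, 2, 3), c(3, 2, 3), c(2, 3, 3)),
                     c(2, 6, 7))
  expect_equal(topo_corr(st, st), 1, tolerance = 1e-12)
  expect_equal(topo_corr(st, step_negate(st)), -1, tolerance = 1e-12)

  # windows violation returns exactly zero: peaks 120 ms apart, 50 ms window
  far <- fixture_step(rbind(c(2, 2, 18), c(3, 2, 18), c(2, 3, 18)),
                      c(2, 6, 7), times = (0:19) * 8)
  near <- fixture_step(rbind(c(2, 2, 3), c(3, 2, 3), c(2, 3, 3)),
                       c(2, 6, 7), times = (0:19) * 8)
  expect_identical(topo_corr(far, near, temporal_ms = 50, spatial_px = 4), 0)

  # zero overlap variance returns zero
  flat <- fixture_step(rbind(c(2, 2, 3), c(3, 2, 3)), c(4, 4))
  expect_identical(topo_corr(flat, flat), 0)

  # bounded on random overlapping supports
  set.seed(6)
  for (i in 1:20) {
    a <- fixture_step(rbind(c(2, 2, 3), c(3, 2, 3), c(2, 3, 3), c(3, 3, 3)),
                      rnorm(4, 3, 2))
    b <- fixture_step(rbind(c(2, 2, 3), c(3, 2, 3), c(2, 3, 3), c(4, 4, 3)),
                      rnorm(4, 3, 2))
    r <- topo_corr(a, b)
    expect_gte(r, -1); expect_lte(r, 1)
  }
})

test_that("GFP follows the mean-square definition", {
  const <- fixture_step(rbind(c(2, 2, 3), c(3, 2, 3)), c(2, 2))
  expect_equal(gfp(const), 4)
  expect_equal(gfp(const, "rms"), 2)
  two <- fixture_step(rbind(c(2, 2, 3), c(3, 2, 3)), c(3, 4))
  expect_equal(gfp(two), 12.5)
  # homogeneity: scaling amplitudes by c scales mean-square gfp by c^2
  two5 <- fixture_step(rbind(c(2, 2, 3), c(3, 2, 3)), 5 * c(3, 4))
  expect_equal(gfp(two5), 25 * gfp(two))
})

test_that("matching picks the best-correlated in-window subject STEP", {
  vox <- rbind(c(4, 4, 8), c(5, 4, 8), c(4, 5, 8))
  group <- fixture_step(vox, c(8, 5, 4))
  # identical subject step: perfect match
  res <- match_step(list(group), group)
  expect_equal(res$topo_score, 1, tolerance = 1e-12)
  expect_equal(res$gfp, mean(c(8, 5, 4)^2))

  # of two candidates the better-correlated one is chosen (brute force
  # over the candidate list is just the max)
  good <- fixture_step(vox, c(7.5, 5.2, 4.1))
  displaced <- fixture_step(sweep(vox, 2, c(2, 2, 0), "+"), c(8, 5, 4))
  cands <- list(displaced, good)
  res2 <- match_step(cands, group)
  corrs <- vapply(cands, topo_corr, 0, st_g = group,
                  temporal_ms = 50, spatial_px = 4)
  expect_equal(res2$topo_score, max(corrs))
  expect_identical(res2$subject_step$amplitudes, good$amplitudes)

  # no in-window candidate: explicit zero conventions
  none <- match_step(list(fixture_step(sweep(vox, 2, c(0, 0, 11), "+"),
                                       c(8, 5, 4))),
                     group, temporal_ms = 20)
  expect_null(none$subject_step)
  expect_identical(none$topo_score, 0)
  expect_identical(none$gfp, 0)

  # polarity and band filters apply
  res3 <- match_step(list(step_negate(group)), group)
  expect_null(res3$subject_step)
})

test_that("connection features are signed differences with zero fallback", {
  vox <- rbind(c(4, 4, 8))
  ga <- fixture_step(vox, 5); ga$id <- "S1"
  gb <- fixture_step(rbind(c(4, 4, 13)), 5); gb$id <- "S2"
  sa <- fixture_step(rbind(c(4, 4, 9)), 5)    # peak at 32 ms
  sb <- fixture_step(rbind(c(4, 4, 14)), 5)   # peak at 52 ms
  matches <- list(S1 = list(subject_step = sa),
                  S2 = list(subject_step = sb))
  edges <- data.frame(step_a = "S1", step_b = "S2", kind = "peak_sync")
  cf <- connection_features(matches, edges)
  expect_equal(cf$dt_peak_ms, 20)
  expect_equal(cf$dt_rise_ms, 20)

  matches$S2$subject_step <- NULL
  cf0 <- connection_features(matches, edges)
  expect_identical(c(cf0$dt_peak_ms, cf0$dt_rise_ms), c(0, 0))
})

test_that("feature tables have the expected layout and scaling", {
  m <- demo_montage()
  sim <- simulate_dataset(
    sim_config(n_subjects = 8, n_trials = 600,
               noise_sd_uv = 2.5 * sqrt(60), seed = 19),
    study_components(), m)
  ss <- segment_cohort(sim_records(sim, condition = c("Target", "Novel")),
                       m, bands = c("delta", "theta"))
  models <- build_condition_models(ss)
  ft <- score_cohort(ss, models)
  expect_identical(nrow(ft), 16L)  # 8 subjects x 2 conditions
  n_cols <- sum(vapply(models, function(mo)
    2 * length(mo$group_steps) +
      2 * nrow(unique(mo$edges[c("step_a", "step_b")])), 0))
  expect_identical(length(feature_columns(ft)), as.integer(n_cols))

  # row order follows the step sets; permuting inputs permutes rows only
  ft_perm <- score_cohort(rev(ss), models)
  expect_equal(ft_perm[nrow(ft_perm):1, ], ft, ignore_attr = TRUE)
})

test_that("feature scaling reproduces the z-scoring identities", {
  tb <- data.frame(subject_id = c("a", "b", "c"), visit_id = "V1",
                   condition = c("Target", "Novel", "Target"),
                   f1 = c(1, 2, 3), f2 = c(5, 5, 5), f3 = c(0, 3, 9))
  sc <- scale_features(tb)
  # population sd of {1,2,3} is sqrt(2/3): scaled values -1.2247, 0, 1.2247
  expect_equal(sc$f1, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # constant column zeroed and flagged
  expect_true(all(sc$f2 == 0))
  scal <- attr(sc, "scaling")
  expect_true(scal$zero_variance[scal$column == "f2"])
  # every scaled training column has mean 0, sd 1 (population)
  for (cl in c("f1", "f3")) {
    expect_equal(mean(sc[[cl]]), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(sc[[cl]]^2)), 1, tolerance = 1e-12)
  }
  # test rows use training statistics
  tb2 <- rbind(tb, data.frame(subject_id = "d", visit_id = "V1",
                              condition = "Novel", f1 = 4, f2 = 7, f3 = 3))
  sc2 <- scale_features(tb2, training_rows = 1:3)
  expect_equal(sc2$f1[4], (4 - 2) / sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(sc2$f2[4], 0)
  expect_equal(sc2$f1[1:3], sc$f1, tolerance = 1e-12)
})

test_that("scoring a cohort against its own model gives high topo scores", {
  m <- demo_montage()
  comps <- fixture_components(latency_jitter = 5, center_jitter = 0.01,
                              amp_jitter = 0.2)
  sim <- simulate_dataset(
    sim_config(n_subjects = 10, n_trials = 600, noise_sd_uv = 0,
               between_subject_amp_sd_uv = 0.5, seed = 23),
    comps, m)
  ss <- segment_cohort(sim_records(sim, condition = "Target"), m,
                       bands = c("delta", "theta"))
  models <- build_condition_models(ss, conditions = "Target")
  ft <- score_cohort(ss, models)
  topo_cols <- grep("\\.topo$", names(ft), value = TRUE)
  scores <- unlist(ft[topo_cols])
  expect_gte(mean(scores[scores != 0]), 0.8)
})
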