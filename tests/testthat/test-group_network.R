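# Identical single-voxel steps for n subjects, optionally time-shifted.
make_cohort_steps <- function(n, t_idx = 8, x = 4, y = 4, amp = 6,
                              shift = rep(0, n), times = (0:39) * 4) {
  lapply(seq_len(n), function(i)
    fixture_step(rbind(c(x, y, t_idx + shift[i])), amp, times = times,
                 subject_id = sprintf("S%02d", i)))
}

test_that("identical steps form one full-coverage candidate per seed", {
  steps <- make_cohort_steps(10)
  cand <- enumerate_candidate_clusters(steps)
  expect_length(cand, 10)  # every seed proposes the same full cluster
  for (c in cand) {
    expect_equal(c$coverage, 1.0)
    expect_length(c$member_idx, 10)
  }
  sel <- greedy_select_clusters(cand, 0.7, 10)
  expect_length(sel, 1)
})

test_that("candidates below the coverage threshold are discarded", {
  # 4 of 10 subjects displaced by +100 ms (25 samples at 4 ms): within a
  # 50 ms window the best candidate covers only 6/10 < 0.7
  steps <- c(make_cohort_steps(6),
             lapply(7:10, function(i)
               fixture_step(rbind(c(4, 4, 33)), 6,
                            times = (0:39) * 4,
                            subject_id = sprintf("S%02d", i))))
  for (i in 1:6) steps[[i]]$times_ms <- (0:39) * 4
  cand <- enumerate_candidate_clusters(steps, temporal_ms = 50,
                                       spatial_px = 4,
                                       coverage_threshold = 0.7)
  expect_length(cand, 0)
})

test_that("greedy selection keeps independent clusters and drops shared ones", {
  # two non-overlapping perfect clusters: both selected
  a <- make_cohort_steps(8, t_idx = 4)
  b <- make_cohort_steps(8, t_idx = 18)
  sel <- greedy_select_clusters(
    enumerate_candidate_clusters(c(a, b)), 0.7, 8)
  expect_length(sel, 2)

  # candidates sharing all members: exactly one survives
  sel2 <- greedy_select_clusters(
    enumerate_candidate_clusters(a), 0.7, 8)
  expect_length(sel2, 1)
})

test_that("group STEP aggregation takes medians and preserves polarity", {
  # identical members: the group step equals any member
  steps <- make_cohort_steps(5)
  cl <- greedy_select_clusters(enumerate_candidate_clusters(steps),
                               0.7, 5)[[1]]
  g <- build_group_step(cl, steps)
  expect_identical(g$peak$x, 4L)
  expect_identical(g$peak$t_idx, 8L)
  expect_equal(g$amplitudes, 6)
  expect_equal(unname(g$voxels[1, ]), c(4L, 4L, 8L))

  # member latencies 300/310/320 ms -> group peak at 310 ms
  times <- (0:99) * 10
  steps2 <- lapply(1:3, function(i)
    fixture_step(rbind(c(4, 4, 30 + i)), 6, times = times,
                 subject_id = sprintf("S%02d", i)))
  cl2 <- greedy_select_clusters(
    enumerate_candidate_clusters(steps2, temporal_ms = 50), 0.7, 3)[[1]]
  g2 <- build_group_step(cl2, steps2)
  expect_equal(g2$peak$t_ms, 310)

  # negative members give a negative group step
  steps3 <- lapply(make_cohort_steps(4), step_negate)
  cl3 <- greedy_select_clusters(enumerate_candidate_clusters(steps3),
                                0.7, 4)[[1]]
  g3 <- build_group_step(cl3, steps3)
  expect_identical(g3$polarity, -1L)
  expect_true(all(g3$amplitudes < 0))
})

test_that("edges require >= 70 % of subjects within the 30 ms window", {
  # one group STEP: no pairs, no edges
  steps <- make_cohort_steps(6)
  mod1 <- build_model(steps, condition = "Target")
  expect_identical(nrow(mod1$edges), 0L)

  # a consistent 20 ms lag (5 samples at 4 ms) yields peak and rise sync
  # edges with the planted delta-t
  a <- make_cohort_steps(8, t_idx = 10, x = 3, y = 3)
  b <- make_cohort_steps(8, t_idx = 15, x = 6, y = 6)
  mod2 <- build_model(c(a, b), condition = "Target", spatial_px = 2)
  expect_identical(length(mod2$group_steps), 2L)
  pe <- mod2$edges[mod2$edges$kind == "peak_sync", ]
  expect_identical(nrow(pe), 1L)
  expect_equal(pe$delta_t_ms, 20)
  expect_identical(nrow(mod2$edges[mod2$edges$kind == "rise_sync", ]), 1L)

  # a 60 ms lag (15 samples) violates the 30 ms synchronization window
  b60 <- make_cohort_steps(8, t_idx = 25, x = 6, y = 6)
  for (i in seq_along(b60)) b60[[i]]$times_ms <- (0:39) * 4
  a40 <- make_cohort_steps(8, t_idx = 10, x = 3, y = 3)
  for (i in seq_along(a40)) a40[[i]]$times_ms <- (0:39) * 4
  mod3 <- build_model(c(a40, b60), condition = "Target", spatial_px = 2)
  expect_identical(length(mod3$group_steps), 2L)
  expect_identical(nrow(mod3$edges), 0L)
})

test_that("the model is invariant to the order of the input steps", {
  set.seed(8)
  steps <- c(make_cohort_steps(7, t_idx = 5),
             make_cohort_steps(7, t_idx = 15, x = 6, y = 3, amp = -4))
  mod_a <- build_model(steps, condition = "Target")
  mod_b <- build_model(steps[sample(length(steps))], condition = "Target")
  expect_identical(length(mod_a$group_steps), length(mod_b$group_steps))
  for (i in seq_along(mod_a$group_steps)) {
    ga <- mod_a$group_steps[[i]]; gb <- mod_b$group_steps[[i]]
    expect_identical(ga$peak, gb$peak)
    expect_equal(ga$voxels, gb$voxels)
    expect_identical(sort(ga$members$subject_id),
                     sort(gb$members$subject_id))
  }
  expect_equal(mod_a$edges$delta_t_ms, mod_b$edges$delta_t_ms)
})

test_that("raising the coverage threshold never adds group STEPs or edges", {
  m <- demo_montage()
  sim <- simulate_dataset(
    sim_config(n_subjects = 8, n_trials = 600,
               noise_sd_uv = 2.5 * sqrt(60), seed = 17),
    fixture_components(), m)
  ss <- segment_cohort(sim_records(sim, condition = "Target"), m,
                       bands = c("delta", "theta"))
  steps <- steps_flat(ss)
  prev_steps <- Inf; prev_edges <- Inf
  for (thr in c(0.5, 0.7, 0.9)) {
    mod <- suppressWarnings(build_model(steps, condition = "Target",
                                        coverage_threshold = thr))
    expect_lte(length(mod$group_steps), prev_steps)
    expect_lte(nrow(mod$edges), prev_edges)
    prev_steps <- length(mod$group_steps)
    prev_edges <- nrow(mod$edges)
  }
})

test_that("a pure-noise cohort yields no spurious group STEPs", {
  # independent noise subjects: nothing should reach 70 % coverage with
  # the default windows (<= 1 spurious cluster allowed across 10 seeds)
  m <- demo_montage()
  spurious <- 0
  for (seed in 1:10) {
    cfg <- sim_config(n_subjects = 8, n_trials = 600,
                      condition_proportions = c(Frequent = 1),
                      noise_sd_uv = 2.5 * sqrt(60), seed = seed)
    sim <- simulate_dataset(cfg, components = list(), m = m)
    ss <- segment_cohort(sim_records(sim), m, bands = "delta")
    mod <- suppressWarnings(build_model(steps_flat(ss),
                                        condition = "Frequent"))
    spurious <- spurious + length(mod$group_steps)
  }
  expect_lte(spurious, 1)
})

test_that("recovered group latencies track planted latencies under jitter", {
  m <- demo_montage()
  jit <- 10
  comps <- fixture_components(latency_jitter = jit)
  sim <- simulate_dataset(
    sim_config(n_subjects = 20, n_trials = 600,
               noise_sd_uv = 2.5 * sqrt(60), seed = 13),
    comps, m)
  ss <- segment_cohort(sim_records(sim, condition = "Target"), m,
                       bands = c("delta", "theta"))
  mod <- build_model(steps_flat(ss), condition = "Target")
  for (comp in comps) {
    g <- match_planted(mod, comp$carrier_band,
                       if (comp$amplitude_uv > 0) 1L else -1L,
                       comp$latency_ms)
    expect_false(is.null(g))
    expect_lte(abs(g$peak$t_ms - comp$latency_ms), 1.5 * jit)
  }
})
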