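test_that("state covariance matrices have the prescribed structure", {
  cv <- build_state_covariances(4, 1, r_integrated = 0.6,
                                r_within_module = 0.6,
                                r_between_module = 0)
  expect_equal(cv$integrated, {
    m <- matrix(0.6, 4, 4); diag(m) <- 1; m
  })
  cv2 <- build_state_covariances(4, 2, 0.6, 0.6, 0)
  expect_equal(cv2$segregated, {
    m <- matrix(0, 4, 4)
    m[1:2, 1:2] <- 0.6; m[3:4, 3:4] <- 0.6; diag(m) <- 1; m
  })
  expect_equal(cv2$modules, c(1L, 1L, 2L, 2L))
  # symmetric, unit diagonal, positive definite
  for (m in list(cv$integrated, cv2$segregated)) {
    expect_equal(m, t(m))
    expect_equal(diag(m), rep(1, 4))
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("segregated regime is more modular than the integrated regime", {
  cv <- build_state_covariances(12, 3, 0.6, 0.6, 0.05)
  q_int <- graph_modularity(threshold_positive(matrix_to_edge(cv$integrated),
                                               12))$Q
  q_seg <- graph_modularity(threshold_positive(matrix_to_edge(cv$segregated),
                                               12))$Q
  expect_gt(q_seg, q_int)
})

test_that("non-positive-definite correlation levels are rejected by name", {
  expect_error(
    build_state_covariances(9, 3, 0.5, -0.9, 0.1),
    "not positive definite.*r_within_module = -0.9")
})

test_that("absorbing chains never leave their initial state", {
  lab <- sample_state_sequence(50, 1, 1, seed = 3)
  expect_length(lab, 50)
  expect_length(unique(lab), 1)
  expect_equal(sum(lab[-1] != lab[-50]), 0)
})

test_that("symmetric chains have prevalence near one half", {
  lab <- sample_state_sequence(10000, 0.9, 0.9, seed = 11)
  # stationary prevalence 0.5; 3 standard errors for autocorrelated
  # two-state chain with stay probability p: var ~ p/(n(1-p)) per run
  se <- sqrt(0.9 / (10000 * 0.1))
  expect_lt(abs(mean(lab == "S") - 0.5), 3 * se)
})

test_that("transition counts match the two-state chain closed form", {
  p_I <- 0.9; p_S <- 0.8; n <- 400
  pi_S <- (1 - p_I) / ((1 - p_I) + (1 - p_S))
  expected <- (n - 1) * ((1 - pi_S) * (1 - p_I) + pi_S * (1 - p_S))
  counts <- vapply(1:150, function(r) {
    lab <- sample_state_sequence(n, p_I, p_S, seed = 1000 + r)
    sum(lab[-1] != lab[-n])
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("cohort generation is deterministic and carries valid truth", {
  cfg <- cohort_config(n_subjects = 3, n_rois = 8, n_frames = 120,
                       n_modules = 2, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$timeseries[["sub002_B"]]$values,
                   b$timeseries[["sub002_B"]]$values)
  expect_equal(nrow(a$truth), 6)
  expect_true(all(a$truth$true_prev_S >= 0 & a$truth$true_prev_S <= 1))
  # realized prevalence and transitions agree with the stored frame labels
  for (key in names(a$frame_labels)) {
    lab <- a$frame_labels[[key]]
    row <- a$truth[paste0(a$truth$subject, "_", a$truth$session) == key, ]
    expect_equal(row$true_prev_S, mean(lab == "S"))
    expect_equal(row$true_transitions, sum(lab[-1] != lab[-length(lab)]))
  }
})

test_that("a noiseless locked-in cohort recovers its generating matrix", {
  cfg <- cohort_config(n_subjects = 1, n_rois = 10, n_frames = 5000,
                       n_modules = 2, p_stay_I = 1, p_stay_S = 1e-9,
                       subject_trait_sd = 0, static_offset_sd = 0,
                       noise_sd = 0, seed = 8)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$frame_labels[["sub001_A"]] == "I"))
  emp <- stats::cor(coh$timeseries[["sub001_A"]]$values)
  expect_lt(max(abs(emp - coh$covariances$integrated)), 0.05)
})

test_that("zero trait spread gives every subject identical chain dynamics", {
  cfg <- cohort_config(n_subjects = 6, n_rois = 6, n_frames = 60,
                       n_modules = 2, subject_trait_sd = 0, seed = 4)
  coh <- generate_cohort(cfg)
  expect_equal(unique(coh$truth$stationary_prev_S), 0.5)
  expect_equal(unique(coh$truth$trait), 0)
})

test_that("mean realized prevalence across many subjects is near one half", {
  cfg <- cohort_config(n_subjects = 80, n_rois = 4, n_frames = 600,
                       n_modules = 2, p_stay_I = 0.9, p_stay_S = 0.9,
                       noise_sd = 0.3, seed = 13)
  coh <- generate_cohort(cfg)
  expect_gte(mean(coh$truth$true_prev_S), 0.45)
  expect_lte(mean(coh$truth$true_prev_S), 0.55)
})

test_that("window truth labels follow majority vote with center-frame ties", {
  lab <- c("I", "I", "S", "S", "S", "I")
  # window 3, step 1: majorities S from the second window on
  expect_equal(window_truth_labels(lab, 3), c("I", "S", "S", "S"))
  # window 2 ties resolve to the center frame (offset floor(2/2) = 2nd)
  expect_equal(window_truth_labels(c("I", "S"), 2), "S")
  expect_equal(window_truth_labels(c("S", "I"), 2), "I")
  # step > 1 subsamples the window starts
  expect_equal(window_truth_labels(lab, 3, step_frames = 3), c("I", "S"))
})

test_that("cohorts round-trip through the TSV + sidecar layout", {
  cfg <- cohort_config(n_subjects = 2, n_rois = 5, n_frames = 40,
                       n_modules = 1, seed = 2)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  back <- read_cohort(dir)
  expect_setequal(names(back$timeseries), names(coh$timeseries))
  expect_equal(back$timeseries[["sub001_A"]]$values,
               coh$timeseries[["sub001_A"]]$values,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$timeseries[["sub002_B"]]$tr_seconds, cfg$tr_seconds)
  expect_equal(nrow(back$truth), 4)
})
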