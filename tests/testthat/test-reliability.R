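test_that("ICC hand cases from the one-way ANOVA definition hold", {
  # identical sessions with spread -> perfect reliability
  expect_equal(icc(c(1, 2, 5), c(1, 2, 5)), 1)
  # subjects (0,1) and (1,0): no between-subject variance
  expect_equal(icc(c(0, 1), c(1, 0)), -1)
  # subjects (1,2) and (3,4): MSbs = 4, MSws = 0.5
  expect_equal(icc(c(1, 3), c(2, 4)), 3.5 / 4.5)
  expect_error(icc(c(2, 2, 2), c(2, 2, 2)), "identical")
})

test_that("icc matches an independent ANOVA oracle on random tables", {
  set.seed(17)
  for (rep in 1:300) {
    n <- sample(3:12, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- x * runif(1, 0.2, 1.5) + rnorm(n, sd = runif(1, 0.1, 2))
    expect_equal(icc(x, y), oracle_icc(x, y), tolerance = 1e-10)
  }
})

test_that("ICC is invariant under common affine rescaling", {
  set.seed(23)
  x <- rnorm(20); y <- x + rnorm(20, sd = 0.7)
  base <- icc(x, y)
  for (r in 1:5) {
    a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 5)
    expect_equal(icc(a * x + b, a * y + b), base, tolerance = 1e-10)
  }
})

test_that("icc estimates the variance ratio on large known cohorts", {
  set.seed(7)
  n <- 500
  # sigma_s^2 = sigma_e^2 = 1 -> true ICC = 0.5; averaging over replicate
  # cohorts isolates estimator bias from single-cohort sampling noise
  estimates <- vapply(1:20, function(r) {
    subj <- rnorm(n, sd = 1)
    icc(subj + rnorm(n, sd = 1), subj + rnorm(n, sd = 1))
  }, numeric(1))
  expect_lt(abs(mean(estimates) - 0.5), 0.05)
  expect_true(all(abs(estimates - 0.5) < 0.2))
})

test_that("the ANOVA summary exposes consistent mean squares and an F test", {
  x <- c(1, 3, 6, 2); y <- c(2, 4, 5, 1)
  an <- icc_anova(x, y)
  expect_equal(an$icc, (an$ms_between - an$ms_within) /
                 (an$ms_between + an$ms_within))
  expect_equal(an$f, an$ms_between / an$ms_within)
  expect_equal(an$p, stats::pf(an$f, 3, 4, lower.tail = FALSE))
  expect_equal(an$n_used, 4)
})

test_that("spearman reliability follows exhaustive rank computation", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_reliability(x, exp(x))$rho, 1)
  expect_equal(spearman_reliability(x, -x)$rho, -1)
  y <- c(2, 7, 1, 8, 2.8)
  rho_brute <- stats::cor(rank(x), rank(y))
  expect_equal(spearman_reliability(x, y)$rho, rho_brute)
  expect_error(spearman_reliability(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("bootstrap CIs are ordered, deterministic and cover the median", {
  set.seed(41)
  x <- rnorm(25); y <- x + rnorm(25, sd = 0.6)
  ci1 <- bootstrap_ci(icc, x, y, n_boot = 300, seed = 5)
  ci2 <- bootstrap_ci(icc, x, y, n_boot = 300, seed = 5)
  expect_identical(ci1[c("lower", "upper")], ci2[c("lower", "upper")])
  expect_lte(ci1$lower, ci1$upper)
  med <- stats::median(ci1$replicates)
  expect_gte(med, ci1$lower)
  expect_lte(med, ci1$upper)
  # constant statistic -> degenerate point interval
  cc <- bootstrap_ci(function(a, b) 7, x, y, n_boot = 50, seed = 1)
  expect_equal(c(cc$lower, cc$upper), c(7, 7))
  # statistic that always fails -> error after the redraw cap
  expect_error(
    bootstrap_ci(function(a, b) stop("nope"), x, y, n_boot = 50, seed = 1),
    "degenerate")
})

test_that("centroid reliability mirrors its anchor cases", {
  c1 <- c(0.5, 0.2, 0.9, 0.4)
  out <- centroid_reliability(c1, c1)
  expect_equal(out$icc, 1)
  expect_equal(out$cd, 0)
  expect_equal(centroid_reliability(c1, -c1)$cd, 2)
  # with session-wise mean removal, matching states stay similar and
  # crossed states become anti-similar
  cI_A <- c(0.8, 0.7, 0.9, 0.75); cS_A <- c(0.3, 0.25, 0.35, 0.3)
  cI_B <- cI_A + c(0.02, -0.01, 0.01, 0)
  cS_B <- cS_A + c(-0.01, 0.02, 0, 0.01)
  match <- centroid_reliability(cI_A, cI_B, remove_mean = TRUE,
                                partner_A = cS_A, partner_B = cS_B)
  crossed <- centroid_reliability(cI_A, cS_B, remove_mean = TRUE,
                                  partner_A = cS_A, partner_B = cI_B)
  expect_gt(match$icc, 0.9)
  expect_lt(match$cd, 0.1)
  expect_lt(crossed$icc, 0)
  expect_gt(crossed$cd, 1.8)
  expect_error(centroid_reliability(c1, -c1, remove_mean = TRUE), "partner")
})

test_that("the reliability table reports per-parameter n and CIs", {
  set.seed(3)
  n <- 12
  pa <- data.frame(subject = sprintf("s%02d", 1:n),
                   prev_S = runif(n), prev_I = NA_real_,
                   mdt_S = c(rnorm(n - 4, 5), rep(NA, 4)))
  pa$prev_I <- 1 - pa$prev_S
  pb <- data.frame(subject = sprintf("s%02d", 1:n),
                   prev_S = pa$prev_S + rnorm(n, sd = 0.1),
                   prev_I = NA_real_,
                   mdt_S = c(rnorm(n - 2, 5), rep(NA, 2)))
  pb$prev_I <- 1 - pb$prev_S
  tab <- reliability_table(pa, pb, param_cols = c("prev_S", "prev_I", "mdt_S"),
                           n_boot = 100, seed = 9)
  expect_equal(tab$parameter, c("prev_S", "prev_I", "mdt_S"))
  expect_equal(tab$n_used, c(12, 12, 8))   # pairwise-complete counts
  expect_true(all(tab$icc_ci_low <= tab$icc, na.rm = TRUE))
  expect_true(all(tab$icc_ci_high >= tab$icc, na.rm = TRUE))
  # complement parameters share the same ICC
  expect_equal(tab$icc[1], tab$icc[2], tolerance = 1e-10)
})

test_that("cross-parameter correlations respect the complement identity", {
  set.seed(8)
  n <- 15
  params <- data.frame(prev_S = runif(n))
  params$prev_I <- 1 - params$prev_S
  params$mdt_S <- params$prev_S * 3 + rnorm(n, sd = 0.2)
  cc <- parameter_crosscorr(params)
  expect_equal(cc$rho["prev_S", "prev_I"], -1)
  expect_equal(diag(cc$rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc$rho, t(cc$rho))
  expect_true(all(cc$n == n))
  expect_gt(cc$rho["prev_S", "mdt_S"], 0)
})
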