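test_that("cosine distance honors its closed-form anchor cases", {
  a <- c(1, 2, 3)
  expect_equal(cosine_distance(a, a), 0)
  expect_equal(cosine_distance(a, -a), 2)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(a, 5 * a), 0)          # scale invariance
  expect_equal(cosine_distance(2 * a, c(3, 1, -2)),
               cosine_distance(a, c(3, 1, -2)))
  expect_error(cosine_distance(c(0, 0), a[1:2]), "zero vector")
})

test_that("within-subject centering removes the mean and keeps it around", {
  set.seed(1)
  inst <- matrix(rnorm(20 * 6), 20)
  d <- dfc_series(inst, 10, 1, tr_seconds = 2)
  out <- center_within_subject(d)
  expect_equal(colMeans(out$dfc$instances), rep(0, 6), tolerance = 1e-10)
  expect_equal(out$mean, colMeans(inst))
  expect_equal(out$dfc$centering, "centered")
  # two instances center to +/-(v - w)/2
  v <- c(1, 2, 3); w <- c(3, 0, 1)
  two <- center_within_subject(dfc_series(rbind(v, w), 5, 1, 1))
  expect_equal(two$dfc$instances[1, ], (v - w) / 2, ignore_attr = TRUE)
  expect_equal(two$dfc$instances[2, ], (w - v) / 2, ignore_attr = TRUE)
  # single instance centers to zero and is flagged degenerate
  one <- center_within_subject(dfc_series(rbind(v), 5, 1, 1))
  expect_equal(as.vector(one$dfc$instances), c(0, 0, 0))
  expect_true(isTRUE(attr(one$dfc, "degenerate")))
})

test_that("centroids are means of unit-normalized members", {
  v <- c(3, 4)
  expect_equal(compute_centroid(rbind(v)), v / 5)
  expect_equal(compute_centroid(rbind(v, 2 * v)), v / 5)
  expect_equal(compute_centroid(rbind(c(1, 0, 0), c(0, 1, 0))),
               c(0.5, 0.5, 0))
  expect_error(compute_centroid(rbind(v, c(0, 0))), "zero-norm")
})

test_that("spherical k-means recovers separable clouds exactly", {
  X <- two_cloud_instances(n_per = 25, sep = 2, noise = 0.05, seed = 3)
  km <- kmeans_cosine(X, 2, seed = 5, n_init = 10)
  truth <- rep(1:2, each = 25)
  agree <- max(mean(km$labels == truth), mean(km$labels == 3 - truth))
  expect_equal(agree, 1)
  expect_true(km$converged)
})

test_that("k-means objective descends monotonically", {
  X <- two_cloud_instances(n_per = 30, sep = 1, noise = 0.5, seed = 9)
  km <- kmeans_cosine(X, 3, seed = 2, n_init = 5)
  expect_true(all(diff(km$objective_trace) <= 1e-12))
})

test_that("k = 1 reduces to the normalized-mean centroid", {
  set.seed(4)
  X <- matrix(runif(8 * 5, 0.1, 1), 8)
  km <- kmeans_cosine(X, 1, seed = 1, n_init = 2)
  expect_equal(as.vector(km$centroids), compute_centroid(X))
  expect_equal(unique(km$labels), 1L)
})

test_that("duplicating every instance changes neither partition nor centroids", {
  X <- two_cloud_instances(n_per = 10, seed = 6)
  km1 <- kmeans_cosine(X, 2, seed = 11, n_init = 8)
  km2 <- kmeans_cosine(rbind(X, X), 2, seed = 11, n_init = 8)
  first <- km2$labels[seq_len(nrow(X))]
  expect_identical(first, km2$labels[nrow(X) + seq_len(nrow(X))])
  # same partition up to label permutation
  flip <- mean(first == km1$labels) < 0.5
  expect_equal(if (flip) 3L - first else first, km1$labels)
  cmp <- if (flip) km2$centroids[2:1, ] else km2$centroids
  expect_equal(cmp, km1$centroids, tolerance = 1e-9)
})

test_that("small k = 2 solutions attain the exhaustive-enumeration optimum", {
  set.seed(12)
  for (rep in 1:6) {
    X <- matrix(runif(10 * 4, -1, 1), 10)
    X <- X[rowSums(X^2) > 0.1, , drop = FALSE]
    km <- kmeans_cosine(X, 2, seed = rep, n_init = 40)
    expect_equal(km$objective, oracle_best_bipartition(X), tolerance = 1e-9)
  }
})

test_that("back-projection assigns nearest centroids with logged ties", {
  model <- state_model(rbind(c(1, 0, 0), c(0, 1, 0)), labels = c("I", "S"))
  d <- dfc_series(rbind(c(2, 0, 0), c(0, 3, 0), c(1, 1, 0)), 5, 1, 1)
  sq <- back_project(d, model)
  expect_equal(sq$labels, c("I", "S", "I"))  # tie -> lowest index
  expect_equal(sq$n_ties, 1)
  expect_equal(sq$step_seconds, 1)
  zero <- dfc_series(rbind(c(1, 0, 0)), 5, 1, 1)
  zero$instances[1, ] <- 0
  expect_error(back_project(zero, model), "window 1")
})

test_that("re-projecting a separated partition onto its own centroids is idempotent", {
  X <- two_cloud_instances(n_per = 20, sep = 2, noise = 0.1, seed = 8)
  km <- kmeans_cosine(X, 2, seed = 3, n_init = 10)
  model <- state_model(km$centroids)
  sq <- back_project(dfc_series(X, 5, 1, 1, n_rois = 5), model)
  expect_equal(sq$state_index, km$labels)
})

test_that("silhouette curve peaks at the generating cluster number", {
  set.seed(20)
  centers <- rbind(c(5, 0.2, 0.2, 0.2), c(0.2, 5, 0.2, 0.2),
                   c(0.2, 0.2, 5, 0.2))
  X <- do.call(rbind, lapply(1:3, function(i) {
    matrix(rep(centers[i, ], each = 30), 30) + matrix(rnorm(120, 0, 0.15), 30)
  }))
  sil <- silhouette_curve(X, k_min = 2, k_max = 5, seed = 2, n_init = 8)
  expect_equal(sil$k[which.max(sil$silhouette)], 3)
  # identical-up-to-scale instances are degenerate
  same <- rbind(c(1, 1, 1, 1), 2 * c(1, 1, 1, 1), 3 * c(1, 1, 1, 1),
                4 * c(1, 1, 1, 1), 5 * c(1, 1, 1, 1), 6 * c(1, 1, 1, 1),
                7 * c(1, 1, 1, 1))
  expect_error(silhouette_curve(same, k_min = 2, k_max = 2), "degenerate")
})

test_that("state labeling follows mean edge strength with add-back", {
  m <- state_model(rbind(rep(0.4, 6), rep(0.1, 6) + c(0.01, 0, 0, 0, 0, 0)))
  lab <- label_states(m)
  expect_equal(lab$labels, c("I", "S"))
  # centered centroids +/-d need the session mean to decide
  d <- c(0.2, -0.1, 0.05, 0, 0, 0)
  cm <- state_model(rbind(d, -d), centering_mode = "centered")
  expect_error(label_states(cm), "session_mean")
  lab2 <- label_states(cm, session_mean = rep(0.3, 6))
  expect_equal(lab2$labels, c("I", "S"))
  lab3 <- label_states(state_model(rbind(-d, d), centering_mode = "centered"),
                       session_mean = rep(0.3, 6))
  expect_equal(lab3$labels, c("S", "I"))
  tie <- state_model(rbind(c(0.3, 0.1), c(0.1, 0.3)))
  expect_error(label_states(tie), "identical mean")
})

test_that("state matching recovers permutations and flags greedy conflicts", {
  set.seed(2)
  A <- matrix(runif(12, 0.1, 1), 3)
  B <- A[c(3, 1, 2), ]
  m <- match_states(state_model(A), state_model(B))
  expect_equal(m$permutation, c(2L, 3L, 1L))
  expect_equal(m$total_cd, 0, tolerance = 1e-12)
  expect_false(m$greedy_conflict)
  # crossed two-state case swaps the assignment
  m2 <- match_states(state_model(rbind(c(1, 0), c(0, 1))),
                     state_model(rbind(c(0.1, 1), c(1, 0.1))))
  expect_equal(m2$permutation, c(2L, 1L))
  # both A1 and A2 are nearest B1, but the optimal matching disambiguates
  A3 <- rbind(c(1, 0, 0), c(0.98, 0.2, 0), c(0, 0, 1))
  B3 <- rbind(c(0.99, 0.1, 0), c(0.6, 0.8, 0), c(0, 0.1, 1))
  m3 <- match_states(state_model(A3), state_model(B3))
  expect_true(m3$greedy_conflict)
  expect_equal(sort(m3$permutation), 1:3)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  brute <- min(apply(perms, 1, function(p) sum(m3$cd_matrix[cbind(1:3, p)])))
  expect_equal(m3$total_cd, brute)
})

test_that("removing the pair mean makes centroids exactly antipodal", {
  out <- remove_centroid_mean(c(1, 1, 0), c(0, 0, 0.4))
  expect_equal(out$c1, -out$c2)
  expect_equal(cosine_distance(out$c1, out$c2), 2)
  set.seed(5)
  for (r in 1:10) {
    c1 <- rnorm(8); c2 <- rnorm(8)
    out <- remove_centroid_mean(c1, c2)
    expect_equal(cosine_distance(out$c1, out$c2), 2, tolerance = 1e-12)
  }
  expect_error(remove_centroid_mean(c(1, 2), c(1, 2)), "identical")
  # edge-wise ICC between antipodal outputs is -1
  out <- remove_centroid_mean(c(1, 4, 2, 0.5), c(2, 0, 1, 3))
  expect_equal(icc(out$c1, out$c2), -1)
})

test_that("empty clusters are reseeded rather than dropped", {
  # three near-identical points plus one outlier; k = 3 forces competition
  X <- rbind(c(1, 0.01), c(1, 0.012), c(1, 0.014), c(-1, 1))
  km <- kmeans_cosine(X, 3, seed = 4, n_init = 20)
  expect_length(unique(km$labels), 3)
})
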