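# Cosine-distance k-means over state instances, centroid definition,
# back-projection of held-out sessions, within-subject centering,
# silhouette-based choice of k, and state matching across clusterings.

#' Cosine distance between two edge vectors
#'
#' CD = 1 - cos(angle) between the vectors, in \[0, 2\]: 0 for parallel,
#' 1 for orthogonal, 2 for antiparallel. Scale-invariant.
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return Cosine distance in \[0, 2\].
#' @export
cosine_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine distance is undefined for a zero vector")
  }
  d <- 1 - sum(a * b) / (na * nb)
  min(max(d, 0), 2)
}

#' Subtract the within-subject-within-session mean connectivity
#'
#' Removes each subject-session's mean edge vector from its instances
#' (eliminating static-connectivity differences between subjects before
#' clustering); the removed mean is returned for optional add-back.
#'
#' @param dfc A [dfc_series()].
#' @return List with `dfc` (the centered series, `centering = "centered"`)
#'   and `mean` (the removed edge vector). If any centered instance has
#'   (near-)zero norm the returned series carries attribute
#'   `degenerate = TRUE`, as such instances have no defined direction for
#'   cosine distance.
#' @export
center_within_subject <- function(dfc) {
  stopifnot(inherits(dfc, "dfc_series"))
  m <- colMeans(dfc$instances)
  dfc$instances <- sweep(dfc$instances, 2, m)
  dfc$centering <- "centered"
  norms <- sqrt(rowSums(dfc$instances^2))
  if (any(norms < 1e-12)) attr(dfc, "degenerate") <- TRUE
  list(dfc = dfc, mean = m)
}

#' State centroid: mean of unit-normalized member instances
#'
#' Each member edge vector is divided by the root of the sum of squares of
#' its elements, then averaged.
#'
#' @param instances Members x edges matrix (>= 1 member, no zero rows).
#' @return Centroid edge vector.
#' @export
compute_centroid <- function(instances) {
  instances <- rbind(instances)   # tolerate a single vector
  if (nrow(instances) < 1) stop("need at least one member instance")
  norms <- sqrt(rowSums(instances^2))
  if (any(norms == 0)) stop("cannot normalize a zero-norm member instance")
  colMeans(instances / norms)
}

#' Spherical (cosine-distance) k-means
#'
#' Lloyd-style alternation in which assignment minimizes the cosine
#' distance to the centroids and the update step sets each centroid to the
#' mean of its members' unit-normalized vectors, so the in-loop objective
#' and the reported centroid definition coincide. Best of `n_init` seeded
#' restarts by total within-cluster cosine distance; deterministic given
#' `seed`. An emptied cluster is reseeded at the instance farthest (largest
#' CD) from that cluster's previous centroid.
#'
#' @param instances Instances x edges matrix; more instances than `k`, no
#'   zero rows.
#' @param k Number of clusters (>= 1).
#' @param seed Master seed for the restarts.
#' @param n_init Number of random restarts.
#' @param max_iter Iteration cap per restart; if reached without label
#'   convergence the best state is returned with `converged = FALSE`.
#' @return List with `labels` (integer cluster per instance), `centroids`
#'   (k x edges, recomputed by [compute_centroid()] on the final
#'   partition), `objective` (total within-cluster CD), `objective_trace`
#'   (per-iteration objective of the winning restart), `n_iter` and
#'   `converged`.
#' @export
kmeans_cosine <- function(instances, k, seed = 1L, n_init = 20L,
                          max_iter = 300L) {
  instances <- as.matrix(instances)
  k <- as.integer(k)
  n <- nrow(instances)
  stopifnot(k >= 1, n > k)
  norms <- sqrt(rowSums(instances^2))
  if (any(norms == 0)) stop("instances contain a zero vector")
  U <- instances / norms
  row_idx <- seq_len(n)
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      C <- U[sample.int(n, k), , drop = FALSE]
      labels_prev <- integer(n)
      labels <- integer(n)
      trace <- numeric(0)
      converged <- FALSE
      iters <- 0L
      for (it in seq_len(max_iter)) {
        iters <- it
        Cn <- C / sqrt(rowSums(C^2))
        sim <- U %*% t(Cn)
        labels <- max.col(sim, ties.method = "first")
        trace <- c(trace, sum(1 - sim[cbind(row_idx, labels)]))
        if (identical(labels, labels_prev)) {
          converged <- TRUE
          break
        }
        labels_prev <- labels
        counts <- tabulate(labels, k)
        if (all(counts > 0)) {
          C <- rowsum(U, labels) / counts
        } else {
          for (j in seq_len(k)) {
            members <- labels == j
            if (!any(members)) {
              # farthest instance from this cluster's current centroid
              far <- which.min(U %*% Cn[j, ])
              C[j, ] <- U[far, ]
              labels[far] <- j
            } else {
              C[j, ] <- colMeans(U[members, , drop = FALSE])
            }
          }
        }
      }
      obj <- trace[length(trace)]
      if (is.null(best) || obj < best$objective) {
        best <- list(labels = labels, objective = obj,
                     objective_trace = trace, n_iter = iters,
                     converged = converged)
      }
    }
  })
  if (!best$converged) {
    warning("kmeans_cosine did not fully converge within max_iter = ",
            max_iter)
  }
  best$centroids <- do.call(rbind, lapply(seq_len(k), function(j) {
    compute_centroid(instances[best$labels == j, , drop = FALSE])
  }))
  best
}

#' Bundle centroids into a state model
#'
#' @param centroids k x edges matrix of centroid vectors.
#' @param centering_mode `"uncentered"` or `"centered"` - the space the
#'   centroids live in.
#' @param labels Optional per-centroid labels (e.g. `"I"`/`"S"`; defaults
#'   to `State1..k`).
#' @param provenance Free-form description of which subject-sessions were
#'   clustered.
#' @param session_mean_added_back Whether the session-level mean has been
#'   added back to centered centroids.
#' @return Object of class `state_model`.
#' @export
state_model <- function(centroids, centering_mode = "uncentered",
                        labels = NULL, provenance = NULL,
                        session_mean_added_back = FALSE) {
  centroids <- rbind(centroids)
  k <- nrow(centroids)
  if (k < 2) stop("a state model needs k >= 2 centroids")
  centering_mode <- match.arg(centering_mode, c("uncentered", "centered"))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      if (cosine_distance(centroids[a, ], centroids[b, ]) <= 0) {
        stop("centroids ", a, " and ", b, " are not distinct")
      }
    }
  }
  labels <- labels %||% paste0("State", seq_len(k))
  stopifnot(length(labels) == k)
  structure(list(centroids = centroids, k = k,
                 centering_mode = centering_mode,
                 labels = labels,
                 provenance = provenance,
                 session_mean_added_back = session_mean_added_back),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("State model: k =", x$k, "(", x$centering_mode, ") labels:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a state sequence
#'
#' @param labels Ordered window labels (character).
#' @param step_seconds Time between consecutive windows (step x TR).
#' @param subject_id,session_label Identifiers.
#' @param state_index Optional integer centroid indices behind the labels.
#' @return Object of class `state_sequence`.
#' @export
state_sequence <- function(labels, step_seconds, subject_id = "sub001",
                           session_label = "A", state_index = NULL) {
  stopifnot(length(labels) >= 1, step_seconds > 0)
  structure(list(labels = as.character(labels),
                 step_seconds = as.numeric(step_seconds),
                 subject_id = subject_id,
                 session_label = session_label,
                 state_index = state_index),
            class = "state_sequence")
}

#' Assign instances to the nearest centroid (back-projection)
#'
#' Each window is labeled with the centroid of smallest cosine distance;
#' exact ties go to the lowest centroid index and are counted in the
#' returned sequence's `n_ties`.
#'
#' @param dfc A [dfc_series()] whose instances live in the same space
#'   (centered/uncentered) as the model centroids.
#' @param model A [state_model()].
#' @return A [state_sequence()] with the model's state labels.
#' @export
back_project <- function(dfc, model) {
  stopifnot(inherits(dfc, "dfc_series"), inherits(model, "state_model"))
  norms <- sqrt(rowSums(dfc$instances^2))
  if (any(norms < 1e-12)) {
    stop("zero-norm instance at window ", which(norms < 1e-12)[1],
         "; cannot back-project")
  }
  U <- dfc$instances / norms
  Cn <- model$centroids / sqrt(rowSums(model$centroids^2))
  sim <- U %*% t(Cn)
  idx <- max.col(sim, ties.method = "first")
  top <- sim[cbind(seq_len(nrow(U)), idx)]
  n_ties <- sum(rowSums(abs(sim - top) < 1e-15) > 1)
  seq <- state_sequence(model$labels[idx],
                        step_seconds = dfc$step_seconds,
                        subject_id = dfc$subject_id,
                        session_label = dfc$session_label,
                        state_index = idx)
  seq$n_ties <- n_ties
  seq
}

#' Mean silhouette versus number of clusters
#'
#' Runs [kmeans_cosine()] for each k and scores the partition with the mean
#' silhouette width under the same cosine distance used for clustering.
#' Optionally subsamples instances (seeded) to bound the distance-matrix
#' cost.
#'
#' @param instances Instances x edges matrix.
#' @param k_min,k_max Range of cluster numbers to evaluate.
#' @param seed Master seed (subsampling and clustering restarts).
#' @param n_init Restarts per k.
#' @param max_instances Optional cap on the number of instances entering
#'   the distance matrix.
#' @return data.frame with columns `k` and `silhouette`.
#' @export
silhouette_curve <- function(instances, k_min = 2L, k_max = 6L, seed = 1L,
                             n_init = 10L, max_instances = NULL) {
  instances <- as.matrix(instances)
  stopifnot(k_min >= 2, k_max >= k_min)
  with_seed(seed, {
    if (!is.null(max_instances) && nrow(instances) > max_instances) {
      keep <- sample.int(nrow(instances), max_instances)
      instances <- instances[keep, , drop = FALSE]
    }
    if (nrow(instances) <= k_max) {
      stop("not enough instances (", nrow(instances), ") for k_max = ", k_max)
    }
    norms <- sqrt(rowSums(instances^2))
    if (any(norms == 0)) stop("instances contain a zero vector")
    U <- instances / norms
    D <- 1 - tcrossprod(U)
    D <- pmin(pmax(D, 0), 2)
    if (max(D) < 1e-8) {
      stop("all instances are identical up to scale; silhouette is degenerate")
    }
    res <- lapply(k_min:k_max, function(k) {
      km <- kmeans_cosine(instances, k, seed = sample.int(2^30, 1),
                          n_init = n_init)
      sil <- cluster::silhouette(km$labels, dmatrix = D)
      data.frame(k = k, silhouette = mean(sil[, "sil_width"]))
    })
    do.call(rbind, res)
  })
}

#' Label the two states as integrated (I) and segregated (S)
#'
#' The centroid with the larger mean edge value is the integrated state.
#' For centered models the session-level mean connectivity must be added
#' back first, since centered centroids no longer reflect connectivity
#' strength.
#'
#' @param model A k = 2 [state_model()].
#' @param session_mean Edge vector to add back (required when
#'   `centering_mode == "centered"`).
#' @return The model with `labels` set to `c("I", "S")` accordingly.
#' @export
label_states <- function(model, session_mean = NULL) {
  stopifnot(inherits(model, "state_model"))
  if (model$k != 2) stop("I/S labeling is defined for k = 2 models only")
  eff <- model$centroids
  if (model$centering_mode == "centered") {
    if (is.null(session_mean)) {
      stop("centered model: session_mean is required to label states")
    }
    eff <- sweep(eff, 2, session_mean, `+`)
    model$session_mean_added_back <- TRUE
  }
  means <- rowMeans(eff)
  if (means[1] == means[2]) {
    stop("degenerate model: centroids have identical mean edge value")
  }
  model$labels <- if (means[1] > means[2]) c("I", "S") else c("S", "I")
  model
}

#' Match states across two independent clusterings
#'
#' Minimum-total-cosine-distance one-to-one assignment of model B's states
#' onto model A's (exact assignment over all permutations, equivalent to
#' the Hungarian solution for the small k used here). Also reports whether
#' a greedy per-row argmin would have assigned some B state to two A
#' states.
#'
#' @param model_A,model_B [state_model()]s with equal k (k <= 8).
#' @return List with `permutation` (index of B's state matched to each A
#'   state), `total_cd`, `greedy_conflict` (logical) and `cd_matrix`.
#' @export
match_states <- function(model_A, model_B) {
  stopifnot(inherits(model_A, "state_model"), inherits(model_B, "state_model"))
  k <- model_A$k
  if (model_B$k != k) stop("models have different k")
  if (k > 8) stop("exact matching implemented for k <= 8")
  D <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      D[a, b] <- cosine_distance(model_A$centroids[a, ],
                                 model_B$centroids[b, ])
    }
  }
  perms <- all_permutations(k)
  costs <- apply(perms, 1, function(p) sum(D[cbind(seq_len(k), p)]))
  bestp <- perms[which.min(costs), ]
  greedy <- apply(D, 1, which.min)
  list(permutation = as.integer(bestp),
       total_cd = min(costs),
       greedy_conflict = anyDuplicated(greedy) > 0,
       cd_matrix = D)
}

#' Remove the mean of two compared centroids
#'
#' Subtracts m = (c1 + c2)/2 from both, making them exactly antipodal
#' (CD = 2). Used before comparing uncentered centroids, which otherwise
#' appear similar even across non-matching states.
#'
#' @param c1,c2 Distinct centroid edge vectors of equal length.
#' @return List with `c1`, `c2` (mean-removed) and `mean`.
#' @export
remove_centroid_mean <- function(c1, c2) {
  stopifnot(length(c1) == length(c2))
  if (isTRUE(all.equal(c1, c2, tolerance = 1e-12))) {
    stop("centroids are identical; mean removal would produce zero vectors")
  }
  m <- (c1 + c2) / 2
  list(c1 = c1 - m, c2 = c2 - m, mean = m)
}
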