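# Graph-theoretic characterization of state centroids: positive-weight
# thresholding at Fisher z = 0, weighted Newman modularity and global
# efficiency, plus subject-level bootstrap clouds of (Q, E) per state.

#' Threshold a centroid at Fisher z = 0 into a weighted graph
#'
#' Reshapes the edge vector to a symmetric matrix and keeps only strictly
#' positive connections (Fisher z = 0 as the connection threshold);
#' negative and zero entries become absent edges. No self-loops.
#'
#' @param edges Centroid edge vector of length `n_rois * (n_rois - 1) / 2`.
#' @param n_rois Number of nodes.
#' @return Object of class `weighted_graph`: list with `n_nodes` and
#'   `weights` (symmetric nonnegative matrix, zero diagonal).
#' @export
threshold_positive <- function(edges, n_rois) {
  w <- edge_to_matrix(edges, n_rois)
  w[w <= 0] <- 0
  diag(w) <- 0
  structure(list(n_nodes = as.integer(n_rois), weights = w),
            class = "weighted_graph")
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted modularity of a given partition (e-matrix formula)
#'
#' Q = sum_i e_ii - sum_i (sum_j e_ij)^2, where e_ij is the fraction of
#' total edge weight linking module i to module j.
#'
#' @param g A [threshold_positive()] graph.
#' @param membership Integer module membership per node.
#' @return Modularity Q.
#' @export
partition_modularity <- function(g, membership) {
  stopifnot(inherits(g, "weighted_graph"),
            length(membership) == g$n_nodes)
  w <- g$weights
  total <- sum(w)                       # = 2m for an undirected graph
  if (total <= 0) stop("graph has no positive-weight edges")
  mods <- sort(unique(membership))
  e <- matrix(0, length(mods), length(mods))
  for (a in seq_along(mods)) {
    for (b in seq_along(mods)) {
      e[a, b] <- sum(w[membership == mods[a], membership == mods[b]]) / total
    }
  }
  sum(diag(e)) - sum(rowSums(e)^2)
}

#' Modularity and module partition of a weighted graph
#'
#' Partitions the graph with Newman's leading-eigenvector algorithm
#' (weighted) and evaluates Q of that partition with the e-matrix formula
#' ([partition_modularity()]).
#'
#' @param g A [threshold_positive()] graph with at least one edge.
#' @param binary Use binarized (0/1) weights instead of the weighted graph.
#' @return List with `Q` and `membership`.
#' @export
graph_modularity <- function(g, binary = FALSE) {
  stopifnot(inherits(g, "weighted_graph"))
  if (sum(g$weights) <= 0) {
    stop("modularity is undefined for a graph with no edges")
  }
  if (binary) {
    g$weights <- (g$weights > 0) + 0
  }
  ig <- as_igraph(g)
  cl <- igraph::cluster_leading_eigen(ig, weights = igraph::E(ig)$weight)
  mem <- as.integer(igraph::membership(cl))
  list(Q = partition_modularity(g, mem), membership = mem)
}

#' Global efficiency of a weighted graph
#'
#' Mean inverse shortest-path distance over ordered node pairs, with edge
#' length 1/weight on the positive connections; unreachable pairs
#' contribute 0 (the limit of infinite distance). An edgeless graph has
#' efficiency 0.
#'
#' @param g A [threshold_positive()] graph with at least 2 nodes.
#' @return Global efficiency (>= 0; equals 1 for a complete unit-weight
#'   graph).
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  n <- g$n_nodes
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  if (sum(g$weights) <= 0) return(0)
  ig <- as_igraph(g)
  D <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Bootstrap clouds of (Q, E) per state
#'
#' Draws subjects with replacement, pools their state instances, recomputes
#' each state's centroid ([compute_centroid()]), optionally adds back a
#' session-level mean (for centered pipelines), thresholds at z = 0 and
#' records modularity and global efficiency. Resamples in which a state has
#' no instances are redrawn and counted.
#'
#' @param instances Instances x edges matrix (pooled session instances).
#' @param labels State label per instance.
#' @param subject_ids Subject identifier per instance.
#' @param n_rois Number of nodes.
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param add_back Optional edge vector added to each centroid before
#'   thresholding (session-level mean for centered pipelines).
#' @return data.frame (state, resample, Q, E) with attribute `n_redrawn`.
#' @export
bootstrap_state_graphs <- function(instances, labels, subject_ids, n_rois,
                                   n_boot = 1000L, seed = 1L,
                                   add_back = NULL) {
  instances <- as.matrix(instances)
  stopifnot(nrow(instances) == length(labels),
            nrow(instances) == length(subject_ids))
  subjects <- unique(subject_ids)
  if (length(subjects) < 1) stop("no subjects to resample")
  if (length(subjects) < 3) {
    warning("fewer than 3 subjects: bootstrap cloud will be (near-)degenerate")
  }
  states <- sort(unique(labels))
  rows_by_subject <- split(seq_len(nrow(instances)), subject_ids)
  with_seed(seed, {
    out <- vector("list", n_boot)
    got <- 0L; redrawn <- 0L; draws <- 0L
    max_draws <- 2L * n_boot
    while (got < n_boot && draws < max_draws) {
      draws <- draws + 1L
      pick <- sample(subjects, length(subjects), replace = TRUE)
      rows <- unlist(rows_by_subject[pick], use.names = FALSE)
      lab <- labels[rows]
      if (!all(states %in% lab)) {
        redrawn <- redrawn + 1L
        next
      }
      got <- got + 1L
      res <- lapply(states, function(st) {
        centroid <- compute_centroid(instances[rows[lab == st], ,
                                               drop = FALSE])
        if (!is.null(add_back)) centroid <- centroid + add_back
        g <- threshold_positive(centroid, n_rois)
        data.frame(state = st, resample = got,
                   Q = graph_modularity(g)$Q,
                   E = global_efficiency(g),
                   stringsAsFactors = FALSE)
      })
      out[[got]] <- do.call(rbind, res)
    }
    if (got < n_boot) {
      stop("too many degenerate bootstrap resamples (", redrawn, " of ",
           draws, ")")
    }
    res <- do.call(rbind, out)
    attr(res, "n_redrawn") <- redrawn
    res
  })
}
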