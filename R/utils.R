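# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package functions do
#' not clobber the session stream. A NULL seed leaves the current stream in
#' place (used when a caller has already seeded an enclosing computation).
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic, keeps results inside the 32-bit integer range so the same
#' master seed reproduces the same sub-streams on any platform.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 1000003) * 69069 + as.double(offset) * 2017 + 1
  as.integer(s %% 2147483647)
}

#' Row-major upper-triangle edge index pairs
#'
#' Fixed vectorization order for connectivity matrices: (1,2), (1,3), ...,
#' (1,n), (2,3), ..., (n-1,n). All modules share this order.
#'
#' @param n_rois Number of nodes/ROIs.
#' @return Two-column integer matrix of (i, j) pairs with i < j.
#' @export
edge_pairs <- function(n_rois) {
  n_rois <- as.integer(n_rois)
  stopifnot(n_rois >= 2)
  i <- rep.int(seq_len(n_rois - 1L), (n_rois - 1L):1L)
  j <- unlist(lapply(seq_len(n_rois - 1L), function(a) (a + 1L):n_rois),
              use.names = FALSE)
  cbind(i = i, j = j)
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of the row-major upper-triangle vectorization; the diagonal is
#' set to `diag_value` (0 by default, as self-connectivity is never used).
#'
#' @param edges Edge vector of length `n_rois * (n_rois - 1) / 2`.
#' @param n_rois Number of nodes.
#' @param diag_value Value placed on the diagonal.
#' @return An `n_rois` x `n_rois` symmetric matrix.
#' @export
edge_to_matrix <- function(edges, n_rois, diag_value = 0) {
  n_rois <- as.integer(n_rois)
  n_edges <- n_rois * (n_rois - 1L) / 2L
  if (length(edges) != n_edges) {
    stop("edge vector has length ", length(edges), " but n_rois = ", n_rois,
         " requires ", n_edges)
  }
  ep <- edge_pairs(n_rois)
  m <- matrix(diag_value, n_rois, n_rois)
  m[ep] <- edges
  m[ep[, c(2, 1)]] <- edges
  diag(m) <- diag_value
  m
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' @param m Symmetric square matrix.
#' @return Edge vector in the package's fixed row-major order.
#' @export
matrix_to_edge <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[edge_pairs(nrow(m))]
}

#' All permutations of 1..n (internal, n <= 8)
#' @keywords internal
#' @noRd
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}
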