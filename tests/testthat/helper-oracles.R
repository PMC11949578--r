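# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's own code paths.

# Naive windowed Pearson + Fisher z, computed window by window with cor().
oracle_windowed_fc <- function(X, window, step = 1) {
  n <- nrow(X)
  n_win <- (n - window) %/% step + 1
  ep <- which(upper.tri(diag(ncol(X))), arr.ind = TRUE)
  ep <- ep[order(ep[, 1], ep[, 2]), , drop = FALSE]  # row-major order
  clip <- 1 - 1e-7
  t(vapply(seq_len(n_win), function(wi) {
    rows <- ((wi - 1) * step + 1):((wi - 1) * step + window)
    r <- stats::cor(X[rows, , drop = FALSE])
    atanh(pmin(pmax(r[ep], -clip), clip))
  }, numeric(nrow(ep))))
}

# One-way random-effects ICC via an independent ANOVA fit.
oracle_icc <- function(x, y) {
  n <- length(x)
  d <- data.frame(val = c(x, y), subj = factor(rep(seq_len(n), 2)))
  av <- stats::anova(stats::lm(val ~ subj, data = d))
  msb <- av["subj", "Mean Sq"]
  msw <- av["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}

# Dwell-time parameters by explicit segment walking (no rle).
oracle_dwell <- function(labels, step = 1) {
  segs <- list()
  cur <- labels[1]; len <- 1L
  for (t in seq_along(labels)[-1]) {
    if (labels[t] == cur) {
      len <- len + 1L
    } else {
      segs[[length(segs) + 1L]] <- list(state = cur, len = len)
      cur <- labels[t]; len <- 1L
    }
  }
  segs[[length(segs) + 1L]] <- list(state = cur, len = len)
  nt <- length(segs) - 1L
  interior <- if (length(segs) > 2) segs[2:(length(segs) - 1L)] else list()
  mdt <- function(st) {
    if (nt < 2L) return(NA_real_)
    lens <- unlist(lapply(interior, function(s) if (s$state == st) s$len))
    if (is.null(lens)) NA_real_ else mean(lens) * step
  }
  m_I <- mdt("I"); m_S <- mdt("S")
  iti <- if (nt < 3L || is.na(m_I) || is.na(m_S)) NA_real_ else (m_I + m_S) / 2
  list(n_transitions = nt, mdt_I = m_I, mdt_S = m_S, iti = iti)
}

# Weighted modularity of a partition by the direct double sum
# (1/2m) * sum_ij (w_ij - k_i k_j / 2m) [same module].
oracle_modularity <- function(w, membership) {
  two_m <- sum(w)
  k <- rowSums(w)
  same <- outer(membership, membership, `==`)
  sum(((w - outer(k, k) / two_m) * same)) / two_m
}

# Exhaustive best 2-way bipartition under the spherical k-means objective.
oracle_best_bipartition <- function(X) {
  U <- X / sqrt(rowSums(X^2))
  n <- nrow(U)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    side <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)))
    obj <- 0
    for (members in list(which(side), which(!side))) {
      cm <- colMeans(U[members, , drop = FALSE])
      nc <- sqrt(sum(cm^2))
      if (nc == 0) { obj <- Inf; break }
      obj <- obj + sum(1 - U[members, , drop = FALSE] %*% (cm / nc))
    }
    if (obj < best) best <- obj
  }
  best
}

# Small random weighted graph fixture (symmetric, nonnegative, no loops).
random_weighted_graph <- function(n, density = 0.7) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- stats::runif(sum(up))
  vals[stats::runif(sum(up)) > density] <- 0
  w[up] <- vals
  w <- w + t(w)
  threshold_positive(w[edge_pairs(n)], n)
}

# Tiny deterministic two-direction instance cloud for clustering tests.
two_cloud_instances <- function(n_per = 20, dim = 10, sep = 1, noise = 0.05,
                                seed = 1) {
  set.seed(seed)
  a <- c(rep(sep, dim %/% 2), rep(0.1, dim - dim %/% 2))
  b <- c(rep(0.1, dim %/% 2), rep(sep, dim - dim %/% 2))
  rbind(
    matrix(rep(a, each = n_per), n_per) + matrix(rnorm(n_per * dim, 0, noise), n_per),
    matrix(rep(b, each = n_per), n_per) + matrix(rnorm(n_per * dim, 0, noise), n_per))
}
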