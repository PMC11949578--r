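# Sliding-window connectivity: turn an ROI time series into the ordered
# sequence of windowed Fisher-z connectivity matrices (the state instances),
# with optional global-signal regression.

#' Construct a validated ROI time-series object
#'
#' @param values Numeric matrix, frames x ROIs; no missing values, every
#'   column must have nonzero variance over the full series.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id,session_label Identifiers carried through the pipeline.
#' @param roi_names Optional ROI names (defaults to column names or
#'   `ROI001`, ...).
#' @return Object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, tr_seconds, subject_id = "sub001",
                           session_label = "A", roi_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("time series contains missing values")
  if (nrow(values) < 2) stop("time series needs at least 2 frames")
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
  roi_names <- roi_names %||% colnames(values) %||%
    sprintf("ROI%03d", seq_len(ncol(values)))
  v <- apply(values, 2, stats::var)
  if (any(v == 0)) {
    stop("ROI column(s) with zero variance: ",
         paste(roi_names[v == 0], collapse = ", "))
  }
  colnames(values) <- roi_names
  structure(list(values = values,
                 tr_seconds = as.numeric(tr_seconds),
                 subject_id = subject_id,
                 session_label = session_label,
                 roi_names = roi_names,
                 gsr_applied = FALSE),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("ROI time series:", x$subject_id, "session", x$session_label, "-",
      nrow(x$values), "frames x", ncol(x$values), "ROIs @ TR =",
      x$tr_seconds, "s", if (x$gsr_applied) "(GSR applied)" else "", "\n")
  invisible(x)
}

#' Regress out the global signal
#'
#' Replaces every ROI column by its residual after ordinary least-squares
#' regression on an intercept and the mean signal across ROIs (the global
#' signal). Residual columns are orthogonal to the global regressor.
#'
#' @param ts A [roi_timeseries()].
#' @return The time series with residualized values and `gsr_applied` set.
#' @export
regress_global_signal <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  g <- rowMeans(ts$values)
  if (stats::var(g) < .Machine$double.eps) {
    # rank-deficient design: only the intercept is effective
    warning("global signal is constant; regression reduces to demeaning")
  }
  fit <- stats::lm.fit(cbind(1, g), ts$values)
  res <- fit$residuals
  dimnames(res) <- dimnames(ts$values)
  ts$values <- res
  ts$gsr_applied <- TRUE
  ts
}

#' Keep only the first frames of a run
#'
#' @param ts A [roi_timeseries()].
#' @param n_keep Number of leading frames to retain (>= 2).
#' @return The truncated time series with metadata preserved.
#' @export
truncate_frames <- function(ts, n_keep) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n_keep <- as.integer(n_keep)
  if (n_keep < 2) stop("n_keep must be at least 2 frames")
  if (n_keep > nrow(ts$values)) {
    stop("n_keep = ", n_keep, " exceeds the ", nrow(ts$values),
         " available frames")
  }
  ts$values <- ts$values[seq_len(n_keep), , drop = FALSE]
  ts
}

#' Sliding-window Fisher-z connectivity
#'
#' For each window position, Pearson correlation of every ROI pair over the
#' window, transformed by Fisher z = atanh(r) after clipping r to
#' +/-(1 - 1e-7), and vectorized in the fixed row-major upper-triangle
#' order (diagonal excluded). The window is rectangular (untapered); sums
#' are maintained by sliding updates so the cost per window is O(ROIs^2).
#'
#' @param ts A [roi_timeseries()].
#' @param window_length_frames Window length in frames (>= 2).
#' @param step_frames Step between consecutive window starts (>= 1).
#' @return Object of class `dfc_series`: list with `instances` (windows x
#'   edges matrix of Fisher-z values), window geometry, TR, identifiers and
#'   centering/GSR provenance.
#' @export
sliding_window_fc <- function(ts, window_length_frames, step_frames = 1L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  X <- ts$values
  n <- nrow(X); R <- ncol(X)
  w <- as.integer(window_length_frames)
  s <- as.integer(step_frames)
  if (w < 2) stop("window_length_frames must be at least 2")
  if (w > n) stop("window length ", w, " exceeds the ", n, " frames")
  if (s < 1) stop("step_frames must be at least 1")
  n_win <- (n - w) %/% s + 1L
  ep <- edge_pairs(R)
  lin <- (ep[, 2] - 1L) * R + ep[, 1]
  clip <- 1 - 1e-7
  out <- matrix(NA_real_, n_win, nrow(ep))
  S <- crossprod(X[seq_len(w), , drop = FALSE])
  m <- colSums(X[seq_len(w), , drop = FALSE])
  start <- 1L
  for (wi in seq_len(n_win)) {
    if (wi > 1L) {
      drop_rows <- start:(start + s - 1L)
      add_rows <- (start + w):(start + w + s - 1L)
      Xd <- X[drop_rows, , drop = FALSE]
      Xa <- X[add_rows, , drop = FALSE]
      S <- S - crossprod(Xd) + crossprod(Xa)
      m <- m - colSums(Xd) + colSums(Xa)
      start <- start + s
    }
    cv <- S - tcrossprod(m) / w
    v <- diag(cv)
    bad <- v <= w * 1e-12
    if (any(bad)) {
      stop("zero-variance ROI within window ", wi, " (frames ", start, "-",
           start + w - 1L, "): ",
           paste(ts$roi_names[bad], collapse = ", "))
    }
    r <- cv[lin] / sqrt(v[ep[, 1]] * v[ep[, 2]])
    out[wi, ] <- atanh(pmin(pmax(r, -clip), clip))
  }
  dfc_series(out, w, s, ts$tr_seconds, ts$subject_id, ts$session_label,
             n_rois = R, gsr_applied = isTRUE(ts$gsr_applied))
}

#' Construct a dFC series object
#'
#' Mostly used internally by [sliding_window_fc()]; exposed so serialized
#' series can be rebuilt.
#'
#' @param instances Windows x edges matrix of Fisher-z values (all finite).
#' @param window_length_frames,step_frames Window geometry.
#' @param tr_seconds Repetition time.
#' @param subject_id,session_label Identifiers.
#' @param n_rois Number of ROIs the edges were vectorized from.
#' @param gsr_applied,centering Provenance flags.
#' @return Object of class `dfc_series`.
#' @export
dfc_series <- function(instances, window_length_frames, step_frames,
                       tr_seconds, subject_id = "sub001", session_label = "A",
                       n_rois = NULL, gsr_applied = FALSE,
                       centering = "uncentered") {
  instances <- as.matrix(instances)
  if (!all(is.finite(instances))) stop("dFC instances must be finite")
  n_rois <- as.integer(n_rois %||%
                         ((1 + sqrt(1 + 8 * ncol(instances))) / 2))
  if (n_rois * (n_rois - 1L) / 2L != ncol(instances)) {
    stop("instance width ", ncol(instances),
         " is not a valid edge-vector length")
  }
  structure(list(instances = instances,
                 window_length_frames = as.integer(window_length_frames),
                 step_frames = as.integer(step_frames),
                 tr_seconds = as.numeric(tr_seconds),
                 window_seconds = window_length_frames * tr_seconds,
                 step_seconds = step_frames * tr_seconds,
                 n_rois = n_rois,
                 subject_id = subject_id,
                 session_label = session_label,
                 gsr_applied = gsr_applied,
                 centering = centering),
            class = "dfc_series")
}

#' @export
print.dfc_series <- function(x, ...) {
  cat("dFC series:", x$subject_id, "session", x$session_label, "-",
      nrow(x$instances), "instances x", ncol(x$instances),
      "edges (window", x$window_length_frames, "frames =",
      x$window_seconds, "s, step", x$step_frames, "frames,",
      x$centering, if (x$gsr_applied) ", GSR" else "", ")\n")
  invisible(x)
}
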