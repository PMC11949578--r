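# Plain-text interchange: TSV matrices with JSON sidecars for time series,
# cohorts, state models and state sequences.

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

#' Write one subject-session time series as TSV + JSON sidecar
#'
#' @param ts A [roi_timeseries()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the TSV path.
#' @export
write_timeseries <- function(ts, dir) {
  stopifnot(inherits(ts, "roi_timeseries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, paste0(ts$subject_id, "_", ts$session_label))
  tsv <- paste0(base, ".tsv")
  utils::write.table(ts$values, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(
    list(subject = ts$subject_id, session = ts$session_label,
         tr_seconds = ts$tr_seconds, n_frames = nrow(ts$values),
         n_rois = ncol(ts$values), gsr_applied = ts$gsr_applied),
    sidecar_path(tsv), auto_unbox = TRUE, digits = NA)
  invisible(tsv)
}

#' Read a subject-session time series (TSV + JSON sidecar)
#'
#' @param path Path to the TSV (frames x ROIs, header row of ROI names);
#'   a sidecar `<path>.json` with at least `tr_seconds`, `subject` and
#'   `session` must sit next to it.
#' @param tr_expected Optional TR to cross-check; on mismatch a warning is
#'   raised and the sidecar value wins.
#' @return A validated [roi_timeseries()].
#' @export
read_timeseries <- function(path, tr_expected = NULL) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) stop("missing JSON sidecar: ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  vals <- suppressWarnings(
    vapply(raw, as.numeric, numeric(nrow(raw))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing cell at line ", bad[1] + 1L, ", column ",
         bad[2], " of ", path)
  }
  tr <- as.numeric(sc$tr_seconds)
  if (!is.null(tr_expected) && !isTRUE(all.equal(tr, tr_expected))) {
    warning("sidecar TR (", tr, " s) differs from expected (", tr_expected,
            " s); the sidecar value is used")
  }
  roi_names <- colnames(raw)
  v <- apply(vals, 2, stats::var)
  if (any(v == 0)) {
    stop("constant ROI column in ", path, ": ",
         paste(roi_names[v == 0], collapse = ", "))
  }
  roi_timeseries(vals, tr, sc$subject %||% "sub001", sc$session %||% "A",
                 roi_names)
}

#' Write a cohort to a directory
#'
#' One TSV + JSON sidecar per subject-session, a ground-truth TSV
#' (subject, session, true_prev_S, true_transitions) and the generator
#' configuration as JSON.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dfc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ts in cohort$timeseries) write_timeseries(ts, dir)
  utils::write.table(
    cohort$truth[, c("subject", "session", "true_prev_S",
                     "true_transitions")],
    file.path(dir, "ground_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory back into time series
#'
#' @param dir Directory produced by [write_cohort()] (or hand-assembled in
#'   the same layout).
#' @return List with `timeseries` (named list of [roi_timeseries()]) and
#'   `truth` (data.frame or NULL when no ground-truth file is present).
#' @export
read_cohort <- function(dir) {
  tsvs <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  tsvs <- tsvs[basename(tsvs) != "ground_truth.tsv"]
  if (length(tsvs) == 0) stop("no time-series TSV files in ", dir)
  timeseries <- list()
  for (f in tsvs) {
    ts <- read_timeseries(f)
    timeseries[[paste0(ts$subject_id, "_", ts$session_label)]] <- ts
  }
  truth_file <- file.path(dir, "ground_truth.tsv")
  truth <- if (file.exists(truth_file)) {
    utils::read.table(truth_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL
  list(timeseries = timeseries, truth = truth)
}

#' Write a state model (centroid matrix + JSON sidecar)
#'
#' @param model A [state_model()].
#' @param path_prefix Output path without extension.
#' @return Invisibly, the TSV path.
#' @export
write_state_model <- function(model, path_prefix) {
  stopifnot(inherits(model, "state_model"))
  tsv <- paste0(path_prefix, ".tsv")
  m <- model$centroids
  rownames(m) <- model$labels
  utils::write.table(m, tsv, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  jsonlite::write_json(
    list(k = model$k, centering_mode = model$centering_mode,
         labels = model$labels, provenance = model$provenance,
         session_mean_added_back = model$session_mean_added_back),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(tsv)
}

#' Write a state sequence as TSV
#'
#' @param seq A [state_sequence()].
#' @param path Output TSV path (columns window_index, label).
#' @return Invisibly, `path`.
#' @export
write_state_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "state_sequence"))
  utils::write.table(
    data.frame(window_index = seq_along(seq$labels), label = seq$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
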