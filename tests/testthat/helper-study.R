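# Shared end-to-end study computations for the heavier integration tests.
# Results are memoised so several test blocks can interrogate one run.

.study_cache <- new.env(parent = emptyenv())

# Full two-session analysis of one cohort at a given centering / scan
# length: session-A clustering, I/S labeling, session-B back-projection,
# per-subject prevalence and its between-session ICC.
prev_analysis <- function(coh, centering = "uncentered", scan = NULL,
                          seed = 1, window = 40) {
  ts <- coh$timeseries
  if (!is.null(scan)) ts <- lapply(ts, truncate_frames, n_keep = scan)
  dfc <- lapply(ts, sliding_window_fc, window_length_frames = window)
  keys_A <- grep("_A$", names(dfc), value = TRUE)
  keys_B <- sub("_A$", "_B", keys_A)
  session_mean <- NULL
  if (centering == "centered") {
    session_mean <- colMeans(
      do.call(rbind, lapply(dfc[keys_A], `[[`, "instances")))
    dfc <- lapply(lapply(dfc, center_within_subject), `[[`, "dfc")
  }
  inst_A <- do.call(rbind, lapply(dfc[keys_A], `[[`, "instances"))
  km <- kmeans_cosine(inst_A, 2, seed = seed, n_init = 20)
  model <- label_states(
    state_model(km$centroids, centering_mode = centering),
    session_mean = session_mean)
  counts <- vapply(dfc[keys_A], function(d) nrow(d$instances), integer(1))
  lab_A <- split(model$labels[km$labels],
                 rep(seq_along(keys_A), counts))
  names(lab_A) <- keys_A
  seq_B <- lapply(dfc[keys_B], back_project, model = model)
  prev_A <- vapply(lab_A, function(l) mean(l == "S"), numeric(1))
  prev_B <- vapply(seq_B, function(s) prevalence(s, "S"), numeric(1))
  list(icc_prev_S = icc(prev_A, prev_B),
       prev_A = prev_A, prev_B = prev_B,
       model = model, km = km, dfc = dfc,
       keys_A = keys_A, keys_B = keys_B,
       inst_A = inst_A, lab_A = lab_A, seq_B = seq_B)
}

# Reference low-noise study: the default cohort conditions with small
# observation noise, analyzed uncentered. Used for recovery, centering
# and silhouette checks.
low_noise_study <- function() {
  if (!is.null(.study_cache$low_noise)) return(.study_cache$low_noise)
  coh <- generate_cohort(cohort_config(noise_sd = 0.2, seed = 42))
  run <- prev_analysis(coh, "uncentered", seed = 7)
  run$cohort <- coh
  .study_cache$low_noise <- run
  run
}
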