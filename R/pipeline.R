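# Study orchestration: run the full two-state dFC analysis across a grid
# of processing-pipeline variants (scan length x atlas size x centering,
# optionally x GSR and x k) and emit report tables.

#' Configuration of a full study run
#'
#' Defines the processing-pipeline grid. The default grid mirrors a
#' 2 (scan length) x 2 (atlas size) x 2 (centering) design at desk scale.
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort, or a
#'   directory containing time series in the [write_cohort()] layout.
#' @param window_length_frames,step_frames Sliding-window geometry.
#' @param scan_lengths Frame counts to analyze; NULL means full length and
#'   its first half.
#' @param atlas_sizes ROI counts to emulate different atlas granularities
#'   (each generates its own cohort when `cohort` is a config); ignored
#'   for directory input.
#' @param centering Subset of `c("uncentered", "centered")`.
#' @param gsr Logical vector: apply global-signal regression or not.
#' @param k_values Cluster numbers (default 2).
#' @param clustering_scope `"all_subjects"` clusters every session-A
#'   instance; `"subset_fraction"` clusters only a fraction of subjects
#'   and back-projects the rest (emulating group splitting).
#' @param subset_fraction Fraction of subjects clustered under
#'   `"subset_fraction"`.
#' @param randomize_sessions Randomly relabel which acquired session of a
#'   subject counts as "A" (avoids temporal sequence effects).
#' @param n_boot Bootstrap resamples for parameter-reliability CIs.
#' @param n_boot_graph Bootstrap resamples for the (Q, E) clouds (0
#'   disables the clouds).
#' @param silhouette_k_max,silhouette_max_instances Silhouette-curve range
#'   and instance cap (0 for `silhouette_k_max` disables the curve).
#' @param kmeans_n_init Restarts for each clustering.
#' @param seed Master seed; every random decision in the study flows from
#'   it.
#' @return Object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         window_length_frames = 40L,
                         step_frames = 1L,
                         scan_lengths = NULL,
                         atlas_sizes = NULL,
                         centering = c("uncentered", "centered"),
                         gsr = FALSE,
                         k_values = 2L,
                         clustering_scope = c("all_subjects",
                                              "subset_fraction"),
                         subset_fraction = 1 / 3,
                         randomize_sessions = TRUE,
                         n_boot = 1000L,
                         n_boot_graph = 200L,
                         silhouette_k_max = 6L,
                         silhouette_max_instances = 600L,
                         kmeans_n_init = 20L,
                         seed = 1L) {
  clustering_scope <- match.arg(clustering_scope)
  centering <- match.arg(centering, c("uncentered", "centered"),
                         several.ok = TRUE)
  if (inherits(cohort, "cohort_config")) {
    scan_lengths <- scan_lengths %||%
      unique(c(cohort$n_frames, cohort$n_frames %/% 2L))
    atlas_sizes <- atlas_sizes %||% unique(c(cohort$n_rois, 2L * cohort$n_rois))
  } else {
    if (!dir.exists(cohort)) stop("cohort directory not found: ", cohort)
    atlas_sizes <- NA_integer_   # fixed by the data on disk
  }
  stopifnot(all(k_values >= 2), subset_fraction > 0, subset_fraction <= 1)
  structure(list(cohort = cohort,
                 window_length_frames = as.integer(window_length_frames),
                 step_frames = as.integer(step_frames),
                 scan_lengths = as.integer(scan_lengths),
                 atlas_sizes = as.integer(atlas_sizes),
                 centering = centering,
                 gsr = as.logical(gsr),
                 k_values = as.integer(k_values),
                 clustering_scope = clustering_scope,
                 subset_fraction = subset_fraction,
                 randomize_sessions = randomize_sessions,
                 n_boot = as.integer(n_boot),
                 n_boot_graph = as.integer(n_boot_graph),
                 silhouette_k_max = as.integer(silhouette_k_max),
                 silhouette_max_instances = as.integer(silhouette_max_instances),
                 kmeans_n_init = as.integer(kmeans_n_init),
                 seed = as.integer(seed)),
            class = "study_config")
}

# Assemble per-session pooled instance matrices for one grid cell.
pool_instances <- function(dfc_list, keys) {
  mats <- lapply(dfc_list[keys], `[[`, "instances")
  idx <- rep(keys, vapply(mats, nrow, integer(1)))
  list(instances = do.call(rbind, mats), key = idx)
}

# One grid cell: cluster session A, back-project, parameters, reliability,
# centroids, graph metrics, silhouette, cross-correlations.
run_cell <- function(dfc_raw, subjects, session_of, centering, k, cfg,
                     cell_seed, cell_id) {
  keys_A <- paste0(subjects, "_", session_of[subjects, "A"])
  keys_B <- paste0(subjects, "_", session_of[subjects, "B"])
  names(keys_A) <- names(keys_B) <- subjects
  centered_means <- NULL
  if (centering == "centered") {
    cent <- lapply(dfc_raw, center_within_subject)
    dfc_use <- lapply(cent, `[[`, "dfc")
    centered_means <- lapply(cent, `[[`, "mean")
  } else {
    dfc_use <- dfc_raw
  }
  pool_A_unc <- pool_instances(dfc_raw, keys_A)
  session_mean_A <- colMeans(pool_A_unc$instances)

  # clustering scope
  if (cfg$clustering_scope == "subset_fraction") {
    n_clustered <- max(2L, floor(cfg$subset_fraction * length(subjects)))
    clustered_subjects <- with_seed(derive_seed(cell_seed, 1),
                                    sample(subjects, n_clustered))
  } else {
    clustered_subjects <- subjects
  }
  pool_cl <- pool_instances(dfc_use, keys_A[clustered_subjects])
  km <- kmeans_cosine(pool_cl$instances, k,
                      seed = derive_seed(cell_seed, 2),
                      n_init = cfg$kmeans_n_init)
  model <- state_model(km$centroids, centering_mode = centering,
                       provenance = paste0(cell_id, ": session-A instances of ",
                                           length(clustered_subjects),
                                           " subjects"))
  if (k == 2) {
    model <- label_states(model, session_mean = if (centering == "centered")
      session_mean_A else NULL)
  }

  # session-A sequences: clustering partition where available, otherwise
  # back-projection onto the session-A centroids
  seqs_A <- list()
  offset <- 0L
  for (s in clustered_subjects) {
    n_i <- nrow(dfc_use[[keys_A[s]]]$instances)
    idx <- km$labels[(offset + 1L):(offset + n_i)]
    offset <- offset + n_i
    seqs_A[[s]] <- state_sequence(model$labels[idx],
                                  step_seconds = dfc_use[[keys_A[s]]]$step_seconds,
                                  subject_id = s, session_label = "A",
                                  state_index = idx)
  }
  for (s in setdiff(subjects, clustered_subjects)) {
    sq <- back_project(dfc_use[[keys_A[s]]], model)
    sq$subject_id <- s; sq$session_label <- "A"
    seqs_A[[s]] <- sq
  }
  seqs_B <- lapply(subjects, function(s) {
    sq <- back_project(dfc_use[[keys_B[s]]], model)
    sq$subject_id <- s; sq$session_label <- "B"
    sq
  })
  names(seqs_B) <- subjects

  states <- if (k == 2) c("I", "S") else model$labels
  params_A <- do.call(rbind, lapply(subjects, function(s) {
    dfc_parameters(dfc_use[[keys_A[s]]], seqs_A[[s]], states = states[1:2])
  }))
  params_B <- do.call(rbind, lapply(subjects, function(s) {
    dfc_parameters(dfc_use[[keys_B[s]]], seqs_B[[s]], states = states[1:2])
  }))
  reliability <- reliability_table(params_A, params_B,
                                   n_boot = cfg$n_boot,
                                   seed = derive_seed(cell_seed, 3))

  # session-B centroids from back-projected instances
  pool_B <- pool_instances(dfc_use, keys_B)
  labels_B <- unlist(lapply(subjects, function(s) seqs_B[[s]]$labels),
                     use.names = FALSE)
  cent_B <- lapply(states, function(st) {
    rowsel <- labels_B == st
    if (!any(rowsel)) return(NULL)
    compute_centroid(pool_B$instances[rowsel, , drop = FALSE])
  })
  names(cent_B) <- states

  state_rel <- list()
  for (a in seq_along(states)) {
    for (b in seq_along(states)) {
      if (is.null(cent_B[[states[b]]])) next
      ca <- model$centroids[match(states[a], model$labels), ]
      cb <- cent_B[[states[b]]]
      # session partner = the other state's centroid of the same session
      pa <- model$centroids[match(states[-a][1], model$labels), ]
      pb <- cent_B[[states[-b][1]]]
      for (rm_mean in if (centering == "uncentered" && k == 2 &&
                          !is.null(pb)) c(FALSE, TRUE) else FALSE) {
        cr <- centroid_reliability(ca, cb, remove_mean = rm_mean,
                                   partner_A = pa, partner_B = pb)
        state_rel[[length(state_rel) + 1L]] <- data.frame(
          state_A = states[a], state_B = states[b],
          remove_mean = rm_mean, icc = cr$icc, cd = cr$cd,
          stringsAsFactors = FALSE)
      }
    }
  }
  state_rel <- do.call(rbind, state_rel)

  # graph metrics of centroids (session mean added back when centered)
  add_back <- if (centering == "centered") session_mean_A else NULL
  graph_points <- do.call(rbind, lapply(states, function(st) {
    rows <- lapply(c("A", "B"), function(ses) {
      centroid <- if (ses == "A") {
        model$centroids[match(st, model$labels), ]
      } else cent_B[[st]]
      if (is.null(centroid)) return(NULL)
      if (!is.null(add_back)) centroid <- centroid + add_back
      g <- threshold_positive(centroid, dfc_raw[[1]]$n_rois)
      data.frame(state = st, session = ses,
                 Q = graph_modularity(g)$Q, E = global_efficiency(g),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  clouds <- NULL
  if (cfg$n_boot_graph > 0) {
    labels_cl <- unlist(lapply(clustered_subjects,
                               function(s) seqs_A[[s]]$labels),
                        use.names = FALSE)
    subj_cl <- rep(clustered_subjects,
                   vapply(clustered_subjects,
                          function(s) length(seqs_A[[s]]$labels), integer(1)))
    clouds <- bootstrap_state_graphs(pool_cl$instances, labels_cl, subj_cl,
                                     dfc_raw[[1]]$n_rois,
                                     n_boot = cfg$n_boot_graph,
                                     seed = derive_seed(cell_seed, 4),
                                     add_back = add_back)
  }

  silhouette <- NULL
  if (cfg$silhouette_k_max >= 2) {
    silhouette <- silhouette_curve(pool_cl$instances, k_min = 2L,
                                   k_max = cfg$silhouette_k_max,
                                   seed = derive_seed(cell_seed, 5),
                                   max_instances = cfg$silhouette_max_instances)
  }

  # cross-parameter correlations on session-averaged values
  param_cols <- c("mdt_I", "mdt_S", "prev_I", "prev_S", "iti",
                  "var_I", "var_S")
  avg <- params_A[, param_cols]
  for (p in param_cols) avg[[p]] <- (params_A[[p]] + params_B[[p]]) / 2
  crosscorr <- parameter_crosscorr(avg)

  n_tie_events <- sum(vapply(c(seqs_A, seqs_B),
                             function(s) s$n_ties %||% 0L, numeric(1)))
  list(cell_id = cell_id, model = model, km_objective = km$objective,
       params_A = params_A, params_B = params_B,
       reliability = reliability, state_reliability = state_rel,
       graph_points = graph_points, graph_clouds = clouds,
       silhouette = silhouette, crosscorr = crosscorr,
       centroids_B = cent_B, session_mean_A = session_mean_A,
       n_tie_events = n_tie_events,
       clustered_subjects = clustered_subjects)
}

#' Run the full study grid
#'
#' For every grid cell (atlas size x scan length x GSR x centering x k):
#' session-A clustering (or subset clustering plus within-A
#' back-projection), session-B back-projection, per-subject dFC
#' parameters, parameter- and centroid-reliability tables, graph-metric
#' points and bootstrap clouds, silhouette curve and cross-parameter
#' correlations. A manifest records every seed and decision flag. A
#' failing cell is logged and the remaining cells continue.
#'
#' @param config A [study_config()].
#' @return Object of class `dfc_study`: list with `cells` (per-cell result
#'   lists), `errors` (cell id -> condition message), `config` and
#'   `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  cells <- list()
  errors <- list()
  manifest <- list(seed = cfg$seed,
                   clustering_scope = cfg$clustering_scope,
                   randomize_sessions = cfg$randomize_sessions,
                   cells = list())
  from_dir <- !inherits(cfg$cohort, "cohort_config")
  for (ai in seq_along(cfg$atlas_sizes)) {
    if (from_dir) {
      loaded <- read_cohort(cfg$cohort)
      timeseries <- loaded$timeseries
      atlas_label <- ncol(timeseries[[1]]$values)
    } else {
      atlas_label <- cfg$atlas_sizes[ai]
      ccfg <- do.call(cohort_config,
                      utils::modifyList(unclass(cfg$cohort),
                                        list(n_rois = atlas_label,
                                             seed = derive_seed(cfg$seed,
                                                                100 + ai))))
      timeseries <- generate_cohort(ccfg)$timeseries
    }
    subjects <- sort(unique(vapply(timeseries, `[[`, "",  "subject_id")))
    # map analysis sessions A/B onto acquired sessions, optionally swapped
    session_of <- matrix("A", length(subjects), 2,
                         dimnames = list(subjects, c("A", "B")))
    session_of[, "B"] <- "B"
    if (cfg$randomize_sessions) {
      swap <- with_seed(derive_seed(cfg$seed, 200 + ai),
                        stats::runif(length(subjects)) < 0.5)
      session_of[swap, ] <- session_of[swap, c(2, 1)]
    }
    for (scan in cfg$scan_lengths) {
      for (use_gsr in cfg$gsr) {
        series <- lapply(timeseries, function(ts) {
          if (scan < nrow(ts$values)) ts <- truncate_frames(ts, scan)
          if (use_gsr) ts <- regress_global_signal(ts)
          ts
        })
        dfc_raw <- lapply(series, sliding_window_fc,
                          window_length_frames = cfg$window_length_frames,
                          step_frames = cfg$step_frames)
        for (centering in cfg$centering) {
          for (k in cfg$k_values) {
            cell_id <- paste0("atlas", atlas_label, "_scan", scan,
                              "_gsr", as.integer(use_gsr), "_",
                              centering, "_k", k)
            cell_seed <- derive_seed(cfg$seed,
                                     1000 * ai + 10 * scan +
                                       as.integer(use_gsr) * 5 +
                                       (centering == "centered") * 3 + k)
            res <- tryCatch(
              run_cell(dfc_raw, subjects, session_of, centering, k, cfg,
                       cell_seed, cell_id),
              error = function(e) e)
            if (inherits(res, "error")) {
              errors[[cell_id]] <- conditionMessage(res)
              warning("grid cell ", cell_id, " failed: ",
                      conditionMessage(res))
            } else {
              cells[[cell_id]] <- res
              manifest$cells[[cell_id]] <-
                list(seed = cell_seed, atlas = atlas_label, scan = scan,
                     gsr = use_gsr, centering = centering, k = k,
                     n_tie_events = res$n_tie_events,
                     clustered_subjects = res$clustered_subjects)
            }
          }
        }
      }
    }
  }
  structure(list(cells = cells, errors = errors, config = cfg,
                 manifest = manifest),
            class = "dfc_study")
}

#' @export
print.dfc_study <- function(x, ...) {
  cat("dFC study:", length(x$cells), "completed grid cells",
      if (length(x$errors)) paste0("(", length(x$errors), " failed)"), "\n")
  for (id in names(x$cells)) cat("  -", id, "\n")
  invisible(x)
}

#' Write the report bundle of a study
#'
#' Emits one state-reliability table (per-cell 2 x 2 ICC and CD blocks,
#' with and without centroid-mean removal for uncentered cells), one
#' parameter-reliability table with CIs, one cross-parameter correlation
#' table, one graph-cloud file, one silhouette file, and the manifest.
#'
#' @param study A [run_study()] result with at least one completed cell.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(study, dir) {
  stopifnot(inherits(study, "dfc_study"))
  if (length(study$cells) == 0) stop("study contains no completed cells")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bind_cells <- function(field) {
    parts <- lapply(names(study$cells), function(id) {
      df <- study$cells[[id]][[field]]
      if (is.null(df)) return(NULL)
      cbind(cell = id, df, stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  }
  utils::write.csv(bind_cells("state_reliability"),
                   file.path(dir, "state_reliability.csv"), row.names = FALSE)
  utils::write.csv(bind_cells("reliability"),
                   file.path(dir, "parameter_reliability.csv"),
                   row.names = FALSE)
  cc <- do.call(rbind, lapply(names(study$cells), function(id) {
    m <- study$cells[[id]]$crosscorr
    if (is.null(m)) return(NULL)
    pn <- rownames(m$rho)
    grid <- expand.grid(param_a = pn, param_b = pn,
                        stringsAsFactors = FALSE)
    data.frame(cell = id, grid,
               rho = as.vector(m$rho), p = as.vector(m$p),
               n = as.vector(m$n), stringsAsFactors = FALSE)
  }))
  utils::write.csv(cc, file.path(dir, "parameter_crosscorr.csv"),
                   row.names = FALSE)
  gp <- bind_cells("graph_points")
  gc <- bind_cells("graph_clouds")
  utils::write.csv(gp, file.path(dir, "graph_centroids.csv"),
                   row.names = FALSE)
  if (!is.null(gc)) {
    utils::write.csv(gc, file.path(dir, "graph_clouds.csv"),
                     row.names = FALSE)
  }
  sil <- bind_cells("silhouette")
  if (!is.null(sil)) {
    utils::write.csv(sil, file.path(dir, "silhouette.csv"),
                     row.names = FALSE)
  }
  manifest <- study$manifest
  manifest$errors <- study$errors
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
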