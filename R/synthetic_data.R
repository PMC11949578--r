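# Synthetic two-session resting-state cohorts with known two-regime
# switching structure. Each subject alternates, frame by frame, between an
# "integrated" covariance regime (uniformly high positive correlation) and a
# "segregated" regime (block-modular correlation) under a first-order Markov
# chain. A per-subject trait tilts the chain's occupancy, and a per-subject
# static-connectivity offset perturbs both regime correlation matrices, so
# that both the state dynamics and the static connectivity carry a
# subject-stable signal that test-retest reliability can recover.

#' Configuration of a synthetic two-session cohort
#'
#' Bundles and validates every knob of the generator. The defaults define
#' the package's reference study conditions: 40 subjects, 30 ROIs, 400
#' frames per session at TR = 1 s (window length 40 frames downstream),
#' slow two-state switching (mean dwell time about 200 frames, several
#' window lengths, so that window-level state labels are resolvable), a
#' logit-scale occupancy trait shared by both sessions of a subject, and
#' moderate observation noise.
#'
#' @param n_subjects Number of subjects; each gets two sessions ("A", "B").
#' @param n_rois Number of regions of interest.
#' @param n_frames Frames per session.
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @param p_stay_I,p_stay_S Per-frame Markov self-transition probabilities
#'   of the integrated / segregated regime, in (0, 1].
#' @param subject_trait_sd SD of the per-subject logit-scale occupancy
#'   trait t: the subject's stay probabilities become
#'   `plogis(qlogis(p_stay_S) + t)` and `plogis(qlogis(p_stay_I) - t)`, so
#'   positive t tilts occupancy towards the segregated regime. The trait is
#'   shared by both sessions and is the reliability signal.
#' @param n_modules Module count of the segregated correlation matrix.
#' @param r_integrated Uniform off-diagonal correlation of the integrated
#'   regime, in (0, 1).
#' @param r_within_module,r_between_module Within-/between-module
#'   correlation of the segregated regime.
#' @param static_offset_sd Scale of the per-subject symmetric rank-1
#'   perturbation of both regime correlation matrices (static-connectivity
#'   differences between subjects); shared by both sessions.
#' @param session_offset_sd Optional per-session rank-1 perturbation on top
#'   of the subject offset (0 by default: sessions differ only by RNG
#'   draws).
#' @param noise_sd SD of additive white observation noise.
#' @param seed Master RNG seed; every random draw flows from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 40L,
                          n_rois = 30L,
                          n_frames = 400L,
                          tr_seconds = 1,
                          p_stay_I = 0.995,
                          p_stay_S = 0.995,
                          subject_trait_sd = 0.5,
                          n_modules = 5L,
                          r_integrated = 0.55,
                          r_within_module = 0.55,
                          r_between_module = 0.05,
                          static_offset_sd = 0.1,
                          session_offset_sd = 0,
                          noise_sd = 0.5,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_rois = as.integer(n_rois),
              n_frames = as.integer(n_frames),
              tr_seconds = as.numeric(tr_seconds),
              p_stay_I = p_stay_I, p_stay_S = p_stay_S,
              subject_trait_sd = subject_trait_sd,
              n_modules = as.integer(n_modules),
              r_integrated = r_integrated,
              r_within_module = r_within_module,
              r_between_module = r_between_module,
              static_offset_sd = static_offset_sd,
              session_offset_sd = session_offset_sd,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_subjects >= 1, cfg$n_rois >= 2, cfg$n_frames >= 2,
            cfg$tr_seconds > 0,
            cfg$p_stay_I > 0, cfg$p_stay_I <= 1,
            cfg$p_stay_S > 0, cfg$p_stay_S <= 1,
            cfg$subject_trait_sd >= 0, cfg$static_offset_sd >= 0,
            cfg$session_offset_sd >= 0, cfg$noise_sd >= 0,
            cfg$r_integrated > 0, cfg$r_integrated < 1)
  # positive definiteness of both regimes is checked at build time
  build_state_covariances(cfg$n_rois, cfg$n_modules, cfg$r_integrated,
                          cfg$r_within_module, cfg$r_between_module)
  structure(cfg, class = "cohort_config")
}

#' Project a symmetric matrix back to a valid correlation matrix
#'
#' Symmetrizes, clips eigenvalues at a small floor, and rescales to unit
#' diagonal.
#' @keywords internal
#' @noRd
project_correlation <- function(m, eig_floor = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  m <- e$vectors %*% (vals * t(e$vectors))
  stats::cov2cor(m)
}

#' Build the integrated and segregated correlation matrices
#'
#' The integrated regime has a constant off-diagonal correlation
#' `r_integrated`; the segregated regime has `r_within_module` inside
#' near-equal contiguous modules and `r_between_module` outside. Both are
#' unit-diagonal, symmetric and positive definite; if a parameter choice is
#' not positive definite, the diagonal is jittered (and rescaled) up to a
#' maximal allowed amount before failing.
#'
#' @inheritParams cohort_config
#' @param max_jitter Maximal diagonal jitter attempted before giving up.
#' @return List with elements `integrated`, `segregated` (correlation
#'   matrices) and `modules` (integer module membership of each ROI).
#' @export
build_state_covariances <- function(n_rois, n_modules, r_integrated,
                                    r_within_module, r_between_module,
                                    max_jitter = 0.2) {
  n_rois <- as.integer(n_rois); n_modules <- as.integer(n_modules)
  stopifnot(n_rois >= 2, n_modules >= 1, n_modules <= n_rois)
  integrated <- matrix(r_integrated, n_rois, n_rois)
  diag(integrated) <- 1
  modules <- sort(rep_len(seq_len(n_modules), n_rois))
  segregated <- matrix(r_between_module, n_rois, n_rois)
  for (m in seq_len(n_modules)) {
    idx <- which(modules == m)
    segregated[idx, idx] <- r_within_module
  }
  diag(segregated) <- 1
  fix_pd <- function(mat, label) {
    jitter <- 0
    while (min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8) {
      jitter <- if (jitter == 0) 0.01 else jitter * 2
      if (jitter > max_jitter) {
        stop("state covariance '", label, "' is not positive definite for ",
             "r_integrated = ", r_integrated,
             ", r_within_module = ", r_within_module,
             ", r_between_module = ", r_between_module,
             " even after maximal diagonal jitter")
      }
      mat <- stats::cov2cor(mat + diag(jitter, nrow(mat)))
    }
    mat
  }
  list(integrated = fix_pd(integrated, "integrated"),
       segregated = fix_pd(segregated, "segregated"),
       modules = modules)
}

#' Sample a frame-level two-state Markov sequence
#'
#' First-order chain over labels I and S with the given self-transition
#' probabilities; the first frame is drawn from the chain's stationary
#' distribution (uniform when both states are absorbing).
#'
#' @param n_frames Sequence length.
#' @param p_stay_I,p_stay_S Self-transition probabilities in (0, 1].
#' @param seed Optional seed; NULL uses the current RNG stream.
#' @return Character vector of "I"/"S" labels.
#' @export
sample_state_sequence <- function(n_frames, p_stay_I, p_stay_S, seed = NULL) {
  stopifnot(n_frames >= 1,
            p_stay_I > 0, p_stay_I <= 1, p_stay_S > 0, p_stay_S <= 1)
  with_seed(seed, {
    leave_I <- 1 - p_stay_I
    leave_S <- 1 - p_stay_S
    pi_S <- if (leave_I + leave_S == 0) 0.5 else leave_I / (leave_I + leave_S)
    lab <- integer(n_frames)             # 0 = I, 1 = S
    lab[1] <- stats::rbinom(1, 1, pi_S)
    if (n_frames > 1) {
      u <- stats::runif(n_frames - 1)
      for (t in 2:n_frames) {
        stay <- if (lab[t - 1] == 1L) p_stay_S else p_stay_I
        lab[t] <- if (u[t - 1] < stay) lab[t - 1] else 1L - lab[t - 1]
      }
    }
    c("I", "S")[lab + 1L]
  })
}

#' Window-level ground-truth labels by majority vote
#'
#' The true label of a window is the majority of its frame labels; exact
#' ties go to the label of the window's center frame (offset
#' `floor(window/2)` from the window start).
#'
#' @param frame_labels Character vector of frame-level "I"/"S" labels.
#' @param window_length_frames,step_frames Window geometry (same convention
#'   as [sliding_window_fc()]).
#' @return Character vector with one label per window.
#' @export
window_truth_labels <- function(frame_labels, window_length_frames,
                                step_frames = 1L) {
  n <- length(frame_labels)
  w <- as.integer(window_length_frames)
  s <- as.integer(step_frames)
  stopifnot(w >= 1, w <= n, s >= 1)
  n_win <- (n - w) %/% s + 1L
  starts <- (seq_len(n_win) - 1L) * s + 1L
  is_S <- as.integer(frame_labels == "S")
  cs <- c(0L, cumsum(is_S))
  vapply(starts, function(t) {
    n_S <- cs[t + w] - cs[t]
    if (2L * n_S == w) frame_labels[t + w %/% 2L]
    else if (2L * n_S > w) "S" else "I"
  }, character(1))
}

#' Generate a synthetic two-session cohort
#'
#' Draws, for every subject, an occupancy trait and a static-connectivity
#' offset (both shared across the subject's two sessions), then simulates
#' each session by sampling a frame-level state sequence and drawing each
#' frame's ROI vector from the multivariate normal of its current regime
#' (after the subject/session offsets are folded into the correlation
#' matrices), plus white observation noise. Fully reproducible from the
#' config seed.
#'
#' @param config A [cohort_config()].
#' @return An object of class `dfc_cohort`: list with `timeseries` (named
#'   list of [roi_timeseries()] keyed `"<subject>_<session>"`),
#'   `frame_labels` (named list of frame-level truth labels), `truth`
#'   (data.frame with subject, session, trait, true stationary and realized
#'   prevalence of S, true transition count) and `covariances` (the two
#'   generating correlation matrices).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  covs <- build_state_covariances(cfg$n_rois, cfg$n_modules, cfg$r_integrated,
                                  cfg$r_within_module, cfg$r_between_module)
  roi_names <- sprintf("ROI%03d", seq_len(cfg$n_rois))
  with_seed(cfg$seed, {
    timeseries <- list()
    frame_labels <- list()
    truth <- vector("list", cfg$n_subjects * 2L)
    row <- 0L
    for (s in seq_len(cfg$n_subjects)) {
      subject_id <- sprintf("sub%03d", s)
      trait <- stats::rnorm(1, 0, cfg$subject_trait_sd)
      p_I <- stats::plogis(stats::qlogis(cfg$p_stay_I) - trait)
      p_S <- stats::plogis(stats::qlogis(cfg$p_stay_S) + trait)
      u <- stats::rnorm(cfg$n_rois); u <- u / sqrt(sum(u^2))
      perturb <- cfg$static_offset_sd * tcrossprod(u)
      base_I <- covs$integrated + perturb
      base_S <- covs$segregated + perturb
      leave_I <- 1 - p_I; leave_S <- 1 - p_S
      stat_prev_S <- if (leave_I + leave_S == 0) 0.5 else
        leave_I / (leave_I + leave_S)
      for (session in c("A", "B")) {
        corr_I <- base_I
        corr_S <- base_S
        if (cfg$session_offset_sd > 0) {
          v <- stats::rnorm(cfg$n_rois); v <- v / sqrt(sum(v^2))
          sess_perturb <- cfg$session_offset_sd * tcrossprod(v)
          corr_I <- corr_I + sess_perturb
          corr_S <- corr_S + sess_perturb
        }
        chol_I <- chol(project_correlation(corr_I))
        chol_S <- chol(project_correlation(corr_S))
        lab <- sample_state_sequence(cfg$n_frames, p_I, p_S, seed = NULL)
        X <- matrix(0, cfg$n_frames, cfg$n_rois)
        idx_I <- which(lab == "I"); idx_S <- which(lab == "S")
        if (length(idx_I)) {
          X[idx_I, ] <- matrix(stats::rnorm(length(idx_I) * cfg$n_rois),
                               ncol = cfg$n_rois) %*% chol_I
        }
        if (length(idx_S)) {
          X[idx_S, ] <- matrix(stats::rnorm(length(idx_S) * cfg$n_rois),
                               ncol = cfg$n_rois) %*% chol_S
        }
        if (cfg$noise_sd > 0) {
          X <- X + cfg$noise_sd *
            matrix(stats::rnorm(cfg$n_frames * cfg$n_rois), cfg$n_frames)
        }
        key <- paste0(subject_id, "_", session)
        timeseries[[key]] <- roi_timeseries(X, cfg$tr_seconds, subject_id,
                                            session, roi_names)
        frame_labels[[key]] <- lab
        row <- row + 1L
        truth[[row]] <- data.frame(
          subject = subject_id, session = session, trait = trait,
          stationary_prev_S = stat_prev_S,
          true_prev_S = mean(lab == "S"),
          true_transitions = sum(lab[-1] != lab[-length(lab)]),
          stringsAsFactors = FALSE)
      }
    }
    structure(list(timeseries = timeseries,
                   frame_labels = frame_labels,
                   truth = do.call(rbind, truth),
                   covariances = covs,
                   config = cfg),
              class = "dfc_cohort")
  })
}

#' @export
print.dfc_cohort <- function(x, ...) {
  cat("Synthetic dFC cohort:", x$config$n_subjects, "subjects x 2 sessions,",
      x$config$n_rois, "ROIs,", x$config$n_frames, "frames @ TR =",
      x$config$tr_seconds, "s\n")
  invisible(x)
}
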