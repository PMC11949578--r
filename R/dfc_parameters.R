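# State-dynamics parameters computed from a window-level state sequence:
# mean dwell time (MDT), prevalence (Prev), intertransition interval (ITI)
# and state variability (Var), per state where applicable. Undefined values
# are encoded as NA (never zero) and propagated as missing.

seq_labels <- function(seq) {
  if (inherits(seq, "state_sequence")) seq$labels else as.character(seq)
}

seq_step <- function(seq, step_seconds = NULL) {
  step_seconds %||%
    (if (inherits(seq, "state_sequence")) seq$step_seconds else 1)
}

#' Maximal runs of constant state
#'
#' Splits a state sequence into its dwell segments. Exactly one segment is
#' flagged `is_first` and one `is_last` (the same segment when there are no
#' transitions); these are excluded from dwell-time averaging because the
#' true beginning/end of the first/last dwell is unobserved.
#'
#' @param seq A [state_sequence()] or character label vector.
#' @return data.frame with columns `state`, `length` (in windows),
#'   `is_first`, `is_last`; attribute `n_transitions` = number of segments
#'   minus one.
#' @export
dwell_segments <- function(seq) {
  labels <- seq_labels(seq)
  stopifnot(length(labels) >= 1)
  r <- rle(labels)
  n_seg <- length(r$lengths)
  out <- data.frame(state = r$values,
                    length = r$lengths,
                    is_first = seq_len(n_seg) == 1L,
                    is_last = seq_len(n_seg) == n_seg,
                    stringsAsFactors = FALSE)
  attr(out, "n_transitions") <- n_seg - 1L
  out
}

#' Number of state transitions in a sequence
#'
#' @param seq A [state_sequence()] or character label vector.
#' @return Integer count.
#' @export
n_transitions <- function(seq) {
  attr(dwell_segments(seq), "n_transitions")
}

#' Mean dwell time of a state
#'
#' Mean length of the interior (neither first nor last) dwell segments of
#' the given state, in seconds. Undefined (NA) when the sequence has fewer
#' than two transitions or no interior segment of that state exists.
#'
#' @param seq A [state_sequence()] or character label vector.
#' @param state State label (e.g. `"I"` or `"S"`).
#' @param step_seconds Seconds per window step; taken from the sequence
#'   object when available, else 1.
#' @return Mean dwell time in seconds, or NA.
#' @export
mean_dwell_time <- function(seq, state, step_seconds = NULL) {
  step <- seq_step(seq, step_seconds)
  segs <- dwell_segments(seq)
  if (attr(segs, "n_transitions") < 2L) return(NA_real_)
  interior <- segs[!segs$is_first & !segs$is_last & segs$state == state, ]
  if (nrow(interior) == 0) return(NA_real_)
  mean(interior$length) * step
}

#' Prevalence of a state
#'
#' Fraction of windows assigned to the state; prevalences of the two states
#' of a two-state model sum to one exactly.
#'
#' @inheritParams mean_dwell_time
#' @return Fraction in \[0, 1\].
#' @export
prevalence <- function(seq, state) {
  labels <- seq_labels(seq)
  stopifnot(length(labels) >= 1)
  mean(labels == state)
}

#' Intertransition interval
#'
#' ITI = (MDT_I + MDT_S)/2 using the interior-segment mean dwell times.
#' Undefined (NA) when the sequence has fewer than three transitions or
#' either MDT is undefined. The same formula is applied regardless of
#' whether the number of dwell segments is even or odd; this choice is
#' recorded here.
#'
#' @inheritParams mean_dwell_time
#' @param states The two state labels.
#' @return ITI in seconds, or NA.
#' @export
intertransition_interval <- function(seq, states = c("I", "S"),
                                     step_seconds = NULL) {
  segs <- dwell_segments(seq)
  if (attr(segs, "n_transitions") < 3L) return(NA_real_)
  mdt1 <- mean_dwell_time(seq, states[1], step_seconds)
  mdt2 <- mean_dwell_time(seq, states[2], step_seconds)
  if (is.na(mdt1) || is.na(mdt2)) return(NA_real_)
  (mdt1 + mdt2) / 2
}

#' State variability
#'
#' Mean Euclidean distance of a subject's instances in the given state to
#' the plain (non-normalized) mean of those instances in the same run.
#' Euclidean distance - not cosine distance - is used deliberately, since
#' cosine distance is not invariant to translations of the clustering
#' space; Var is translation-invariant. NA when the run has no instance in
#' that state.
#'
#' @param dfc A [dfc_series()].
#' @param seq The aligned [state_sequence()] (same number of windows).
#' @param state State label.
#' @return Mean distance in Fisher-z units, or NA.
#' @export
state_variability <- function(dfc, seq, state) {
  stopifnot(inherits(dfc, "dfc_series"))
  labels <- seq_labels(seq)
  if (length(labels) != nrow(dfc$instances)) {
    stop("state sequence (", length(labels), ") and dFC series (",
         nrow(dfc$instances), ") are not aligned")
  }
  members <- dfc$instances[labels == state, , drop = FALSE]
  if (nrow(members) == 0) return(NA_real_)
  M <- colMeans(members)
  mean(sqrt(rowSums(sweep(members, 2, M)^2)))
}

#' All dFC parameters of one subject-session
#'
#' Computes the seven state-dynamics parameters (MDT, Prev and Var per
#' state, plus ITI) and the transition count from a dFC series and its
#' state sequence.
#'
#' @param dfc A [dfc_series()].
#' @param seq The aligned [state_sequence()].
#' @param states The two state labels (defaults to I/S).
#' @return One-row data.frame: subject, session, mdt_I, mdt_S, prev_I,
#'   prev_S, iti, var_I, var_S, n_transitions.
#' @export
dfc_parameters <- function(dfc, seq, states = c("I", "S")) {
  stopifnot(inherits(seq, "state_sequence"))
  data.frame(
    subject = seq$subject_id,
    session = seq$session_label,
    mdt_I = mean_dwell_time(seq, states[1]),
    mdt_S = mean_dwell_time(seq, states[2]),
    prev_I = prevalence(seq, states[1]),
    prev_S = prevalence(seq, states[2]),
    iti = intertransition_interval(seq, states),
    var_I = state_variability(dfc, seq, states[1]),
    var_S = state_variability(dfc, seq, states[2]),
    n_transitions = n_transitions(seq),
    stringsAsFactors = FALSE)
}
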