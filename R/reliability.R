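# Test-retest reliability: one-way random-effects intraclass correlation,
# Spearman rank correlation, percentile bootstrap confidence intervals over
# subjects, centroid reliability, and cross-parameter correlations.

#' Intraclass correlation coefficient (one-way random effects, k = 2)
#'
#' ICC = (MSbs - MSws) / (MSbs + (k - 1) * MSws), where MSbs is the mean
#' square between subjects and MSws the mean square within subjects from a
#' one-way random-effects ANOVA with k = 2 measurements per subject. This
#' estimates the between-subject share of total variance,
#' sigma_s^2 / (sigma_s^2 + sigma_e^2), and may be negative when
#' within-subject variability exceeds between-subject variability.
#'
#' Pairs with a missing value in either measurement are dropped.
#'
#' @param x,y Paired measurements (session A and B) of equal length; at
#'   least 3 complete pairs, not all values identical.
#' @return The ICC (numeric scalar, possibly negative).
#' @export
icc <- function(x, y) {
  icc_anova(x, y)$icc
}

#' One-way ANOVA decomposition behind the ICC
#'
#' Exposes the mean squares, the F statistic MSbs/MSws and its p-value
#' (df = n - 1 and n(k - 1)); the p-value convention is an F-test on the
#' between-/within-subject mean-square ratio.
#'
#' @inheritParams icc
#' @return List: `icc`, `ms_between`, `ms_within`, `f`, `df1`, `df2`, `p`,
#'   `n_used`.
#' @export
icc_anova <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) stop("ICC needs at least 2 complete paired units (got ", n, ")")
  vals <- cbind(x, y)
  if (max(vals) == min(vals)) {
    stop("all measurements are identical; ICC is undefined")
  }
  k <- 2
  m_i <- rowMeans(vals)
  g <- mean(vals)
  ms_between <- k * sum((m_i - g)^2) / (n - 1)
  ms_within <- sum((vals - m_i)^2) / (n * (k - 1))
  icc <- (ms_between - ms_within) / (ms_between + (k - 1) * ms_within)
  f <- if (ms_within > 0) ms_between / ms_within else Inf
  p <- stats::pf(f, n - 1, n * (k - 1), lower.tail = FALSE)
  list(icc = icc, ms_between = ms_between, ms_within = ms_within,
       f = f, df1 = n - 1, df2 = n * (k - 1), p = p, n_used = n)
}

#' Spearman rank correlation between two sessions
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (asymptotic when ties are present).
#'
#' @inheritParams icc
#' @return List with `rho`, `p` and `n_used`.
#' @export
spearman_reliability <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    stop("Spearman reliability needs at least 3 complete pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("a constant measurement vector has no defined rank correlation")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_used = length(x))
}

#' Percentile bootstrap confidence interval over subjects
#'
#' Resamples subjects (paired units) with replacement and takes percentile
#' bounds of the statistic's bootstrap distribution. Resamples on which the
#' statistic is undefined (error or NA) are redrawn up to a cap and
#' counted.
#'
#' @param statistic `function(x, y) -> numeric scalar` (e.g. [icc()]).
#' @param x,y Paired measurements.
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param conf Confidence level.
#' @return List with `lower`, `upper`, `n_degenerate` (redrawn resamples)
#'   and `replicates` (the bootstrap values).
#' @export
bootstrap_ci <- function(statistic, x, y, n_boot = 1000L, seed = 1L,
                         conf = 0.95) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("bootstrap needs at least 3 complete paired units")
  with_seed(seed, {
    vals <- numeric(n_boot)
    got <- 0L
    degenerate <- 0L
    max_draws <- 2L * n_boot
    draws <- 0L
    while (got < n_boot && draws < max_draws) {
      draws <- draws + 1L
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(statistic(x[idx], y[idx]), error = function(e) NA_real_)
      if (is.na(v)) {
        degenerate <- degenerate + 1L
      } else {
        got <- got + 1L
        vals[got] <- v
      }
    }
    if (got < n_boot) {
      stop("more than 50% of bootstrap resamples were degenerate (",
           degenerate, " of ", draws, " draws)")
    }
    q <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                         names = FALSE)
    list(lower = q[1], upper = q[2], n_degenerate = degenerate,
         replicates = vals)
  })
}

#' Reliability of a pair of state centroids
#'
#' Treats the edges as paired units: ICC between the entries of the two
#' centroid vectors, plus their cosine distance. With `remove_mean`, each
#' centroid first has the mean of its own session's compared centroid pair
#' subtracted (its session partner being the other state's centroid, via
#' [remove_centroid_mean()]), which suppresses the baseline similarity
#' that uncentered centroids share even across non-matching states.
#'
#' @param c_A,c_B Centroid edge vectors of equal length (session A and B).
#' @param remove_mean Subtract each session's centroid-pair mean first?
#' @param partner_A,partner_B The other state's centroid in the same
#'   session (required when `remove_mean`).
#' @return List with `icc` and `cd`.
#' @export
centroid_reliability <- function(c_A, c_B, remove_mean = FALSE,
                                 partner_A = NULL, partner_B = NULL) {
  stopifnot(length(c_A) == length(c_B))
  if (remove_mean) {
    if (is.null(partner_A) || is.null(partner_B)) {
      stop("remove_mean requires the session partner centroids")
    }
    c_A <- remove_centroid_mean(c_A, partner_A)$c1
    c_B <- remove_centroid_mean(c_B, partner_B)$c1
  }
  list(icc = icc(c_A, c_B), cd = cosine_distance(c_A, c_B))
}

#' Reliability table for dFC parameters between two sessions
#'
#' For each parameter column, matches subjects across sessions, drops
#' pairwise-missing values, and reports the ICC with percentile bootstrap
#' CI, the F-test p-value on the mean-square ratio, the Spearman rho with
#' its p-value, and the number of subjects used.
#'
#' @param params_A,params_B data.frames with a `subject` column and the
#'   parameter columns (one row per subject), e.g. rows of
#'   [dfc_parameters()] stacked per session.
#' @param param_cols Parameter columns to evaluate.
#' @param n_boot Bootstrap resamples for the ICC CI.
#' @param seed RNG seed.
#' @return data.frame: parameter, n_used, icc, icc_ci_low, icc_ci_high,
#'   icc_p, spearman_rho, spearman_p. Parameters with fewer than 3
#'   complete pairs yield an all-NA row (with n_used).
#' @export
reliability_table <- function(params_A, params_B,
                              param_cols = c("mdt_I", "mdt_S", "prev_I",
                                             "prev_S", "iti", "var_I",
                                             "var_S"),
                              n_boot = 1000L, seed = 1L) {
  merged <- merge(params_A[, c("subject", param_cols)],
                  params_B[, c("subject", param_cols)],
                  by = "subject", suffixes = c("_A", "_B"))
  rows <- lapply(seq_along(param_cols), function(pi) {
    p <- param_cols[pi]
    x <- merged[[paste0(p, "_A")]]
    y <- merged[[paste0(p, "_B")]]
    keep <- stats::complete.cases(x, y)
    n_used <- sum(keep)
    out <- data.frame(parameter = p, n_used = n_used, icc = NA_real_,
                      icc_ci_low = NA_real_, icc_ci_high = NA_real_,
                      icc_p = NA_real_, spearman_rho = NA_real_,
                      spearman_p = NA_real_, stringsAsFactors = FALSE)
    if (n_used < 3) return(out)
    an <- tryCatch(icc_anova(x[keep], y[keep]), error = function(e) NULL)
    if (!is.null(an)) {
      out$icc <- an$icc
      out$icc_p <- an$p
      ci <- tryCatch(
        bootstrap_ci(icc, x[keep], y[keep], n_boot = n_boot,
                     seed = derive_seed(seed, pi)),
        error = function(e) NULL)
      if (!is.null(ci)) {
        out$icc_ci_low <- ci$lower
        out$icc_ci_high <- ci$upper
      }
    }
    sp <- tryCatch(spearman_reliability(x[keep], y[keep]),
                   error = function(e) NULL)
    if (!is.null(sp)) {
      out$spearman_rho <- sp$rho
      out$spearman_p <- sp$p
    }
    out
  })
  do.call(rbind, rows)
}

#' Spearman correlations between dFC parameters
#'
#' Between-subject rank correlations of the parameters, computed on values
#' averaged across the two sessions, with pairwise-complete handling; each
#' cell reports the n it used. Cells with fewer than 3 complete pairs are
#' NA.
#'
#' @param params data.frame of per-subject session-averaged parameter
#'   values (numeric columns only are used).
#' @return List of symmetric matrices `rho`, `p`, `n`.
#' @export
parameter_crosscorr <- function(params) {
  num <- params[, vapply(params, is.numeric, logical(1)), drop = FALSE]
  if (nrow(num) < 3) stop("cross-correlations need at least 3 subjects")
  p_names <- colnames(num)
  np <- length(p_names)
  rho <- matrix(NA_real_, np, np, dimnames = list(p_names, p_names))
  pval <- rho
  nmat <- matrix(0L, np, np, dimnames = list(p_names, p_names))
  for (a in seq_len(np)) {
    for (b in a:np) {
      x <- num[[a]]; y <- num[[b]]
      keep <- stats::complete.cases(x, y)
      nmat[a, b] <- nmat[b, a] <- sum(keep)
      if (a == b) {
        rho[a, a] <- 1
        pval[a, a] <- 0
        next
      }
      if (sum(keep) < 3) next
      sp <- tryCatch(spearman_reliability(x[keep], y[keep]),
                     error = function(e) NULL)
      if (!is.null(sp)) {
        rho[a, b] <- rho[b, a] <- sp$rho
        pval[a, b] <- pval[b, a] <- sp$p
      }
    }
  }
  list(rho = rho, p = pval, n = nmat)
}
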