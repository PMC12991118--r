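#' Task-epoch window definitions
#'
#' Four epochs partition each trial: pretrial (2 to 1 s before trial start,
#' defined only after hit trials since trial initiation differs after misses),
#' early trial (trial start to 1 s before reward), late trial (the final 1 s
#' before reward) and reward (0 to 3 s after reward delivery). Late and reward
#' epochs exist only on hit trials; the early epoch is likewise restricted to
#' hit trials (of duration > 1 s) so that the epochs stay mutually consistent.
#'
#' @param pretrial,early_end_offset,late_duration,reward_duration Window
#'   parameters in seconds: pretrial is `(start - pretrial[1],
#'   start - pretrial[2])`, the early epoch ends `early_end_offset` s before
#'   reward, the late epoch spans the final `late_duration` s before reward,
#'   and the reward epoch the first `reward_duration` s after it.
#' @return An object of class `epoch_windows`.
#' @export
epoch_windows <- function(pretrial = c(2, 1), early_end_offset = 1,
                          late_duration = 1, reward_duration = 3) {
  if (pretrial[1] <= pretrial[2]) stop("pretrial window reversed")
  structure(list(pretrial = pretrial, early_end_offset = early_end_offset,
                 late_duration = late_duration,
                 reward_duration = reward_duration),
            class = "epoch_windows")
}

## mean of trace columns with timestamps in the half-open window (a, b];
## returns NA if the window catches no frame
window_mean <- function(mat, times, a, b) {
  sel <- times > a & times <= b
  if (!any(sel)) return(rep(NA_real_, nrow(mat)))
  rowMeans(mat[, sel, drop = FALSE])
}

#' Per-trial epoch activity table
#'
#' Computes the mean ΔF/F of every neuron in each task epoch of each trial,
#' restricted to the first `max_trials` trials of the session. Entries that
#' are unavailable under the epoch rules (pretrial only following a hit;
#' early only on hit trials longer than 1 s; late/reward only on hit trials)
#' are `NA`, not zero.
#'
#' @param session A [session_record()].
#' @param windows An [epoch_windows()].
#' @param max_trials Trial cutoff (default 40).
#' @return An object of class `epoch_activity`: a list of four neurons x
#'   trials matrices (`pre`, `early`, `late`, `rew`) plus the trial table.
#' @export
epoch_activity <- function(session, windows = epoch_windows(),
                           max_trials = 40) {
  ev <- session$events
  n_tr <- min(nrow(ev), max_trials)
  ev <- ev[seq_len(n_tr), , drop = FALSE]
  times <- session_times(session)
  n <- nrow(session$dff)
  blank <- matrix(NA_real_, n, n_tr)
  out <- list(pre = blank, early = blank, late = blank, rew = blank)
  for (I in seq_len(n_tr)) {
    s <- ev$start_s[I]; r <- ev$reward_s[I]; hit <- ev$outcome[I] == "hit"
    prev_hit <- I > 1L && ev$outcome[I - 1L] == "hit"
    if (prev_hit)
      out$pre[, I] <- window_mean(session$dff, times,
                                  s - windows$pretrial[1], s - windows$pretrial[2])
    if (hit) {
      if (ev$duration_s[I] > windows$early_end_offset)
        out$early[, I] <- window_mean(session$dff, times, s,
                                      r - windows$early_end_offset)
      out$late[, I] <- window_mean(session$dff, times,
                                   r - windows$late_duration, r)
      out$rew[, I] <- window_mean(session$dff, times, r,
                                  r + windows$reward_duration)
    }
  }
  if (!any(ev$outcome == "hit"))
    warning("session has no hit trials; late/reward epochs are empty")
  structure(c(out, list(events = ev)), class = "epoch_activity")
}

## OLS slope of y on x over non-NA pairs; NA with fewer than 2 points
ols_slope <- function(x, y) {
  ok <- is.finite(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0) return(NA_real_)
  stats::cov(x, y) / stats::var(x)
}

#' Task-tuning vectors and learning slopes
#'
#' Summarizes each neuron by its mean epoch activity across trials (the
#' four-dimensional task-tuning vector Pre/Early/Late/Rew) and by the
#' ordinary-least-squares slope of each epoch activity against trial index
#' (the per-epoch learning slopes ΔPre/ΔEarly/ΔLate/ΔRew). Means and slopes
#' use the available (non-NA) trials only; a slope needs at least two.
#'
#' @param table An [epoch_activity()] table.
#' @return A data.frame of class `task_tuning` with columns `neuron_id`,
#'   `pre`, `early`, `late`, `rew`, `d_pre`, `d_early`, `d_late`, `d_rew`.
#' @export
tuning_and_delta <- function(table) {
  stopifnot(inherits(table, "epoch_activity"))
  n <- nrow(table$pre)
  idx <- seq_len(ncol(table$pre))
  res <- data.frame(neuron_id = seq_len(n))
  for (ep in c("pre", "early", "late", "rew")) {
    m <- table[[ep]]
    res[[ep]] <- rowMeans(m, na.rm = TRUE)
    res[[ep]][!rowSums(is.finite(m))] <- NA_real_
    res[[paste0("d_", ep)]] <- apply(m, 1L, function(y) ols_slope(idx, y))
  }
  class(res) <- c("task_tuning", "data.frame")
  res
}

#' Write a task-tuning table to CSV
#'
#' @param tuning A `task_tuning` data.frame.
#' @param path Output file path.
#' @export
write_tuning <- function(tuning, path) {
  utils::write.csv(as.data.frame(tuning), path, row.names = FALSE)
  invisible(path)
}

#' Bootstrap test for sparse, CN-specific learning
#'
#' Builds a null distribution for the across-session median learning slope by
#' repeatedly drawing one neuron per session and taking the median of their
#' slopes, then compares the conditioned neurons' median against it. The draw
#' can optionally be restricted per session to candidate-CN neurons (the
#' neurons most similar in activity and trial-start tuning to the CN, see
#' [candidate_cn_mask()]).
#'
#' @param deltas_by_session List of per-session numeric vectors of learning
#'   slopes (one entry per neuron).
#' @param cn_ids Integer vector: the CN index in each session.
#' @param n_draws Number of bootstrap draws (>= 100).
#' @param seed Integer seed (required; no default).
#' @param candidate_masks Optional list of per-session logical masks
#'   restricting which neurons may be drawn.
#' @return A list with `cn_median`, `cn_median_percentile` (fraction of null
#'   draws strictly below the CN median plus half the ties), the one-sided
#'   `p_value` (fraction of null draws >= the CN median), and the
#'   `null_distribution`.
#' @export
cn_sparsity_bootstrap <- function(deltas_by_session, cn_ids, n_draws = 1e4,
                                  seed, candidate_masks = NULL) {
  if (missing(seed)) stop("seed is required")
  if (length(deltas_by_session) < 2L) stop("need at least 2 sessions")
  if (n_draws < 100L) stop("n_draws must be >= 100")
  n_ses <- length(deltas_by_session)
  pools <- lapply(seq_len(n_ses), function(s) {
    d <- deltas_by_session[[s]]
    keep <- is.finite(d)
    if (!is.null(candidate_masks)) {
      keep <- keep & candidate_masks[[s]]
      if (!any(keep)) stop("candidate mask empty in session ", s)
    }
    d[keep]
  })
  set.seed(seed)
  draws <- vapply(pools, function(p) p[sample.int(length(p), n_draws,
                                                  replace = TRUE)],
                  numeric(n_draws))
  null <- apply(draws, 1L, stats::median)
  cn_med <- stats::median(vapply(seq_len(n_ses), function(s)
    deltas_by_session[[s]][cn_ids[s]], numeric(1)))
  pct <- mean(null < cn_med) + 0.5 * mean(null == cn_med)
  list(cn_median = cn_med, cn_median_percentile = pct,
       p_value = mean(null >= cn_med), null_distribution = null)
}

## per-neuron screening statistics used for CN candidacy
cn_screen_stats <- function(session) {
  h <- session$dff
  sds <- apply(h, 1L, stats::sd)
  modulation <- rowMeans(h > sds)
  times <- session_times(session)
  ev <- session$events
  in_trial <- pre <- matrix(NA_real_, nrow(h), nrow(ev))
  for (I in seq_len(nrow(ev))) {
    s <- ev$start_s[I]
    in_trial[, I] <- window_mean(h, times, s, s + ev$duration_s[I])
    pre[, I] <- window_mean(h, times, s - 2, s - 1)
  }
  tuning <- rowMeans(in_trial, na.rm = TRUE) - rowMeans(pre, na.rm = TRUE)
  list(modulation = modulation, start_tuning = tuning)
}

#' Candidate conditioned-neuron mask
#'
#' Flags the neurons of a screening session whose activity-modulation
#' fraction (fraction of time spent above one standard deviation of activity)
#' and trial-start tuning (mean activity from trial start to trial end minus
#' the mean in the 2-1 s pre-start window) are most similar to those of a
#' reference neuron. Similarity is Euclidean distance in rank space over the
#' two statistics; the closest `top_frac` of neurons are flagged.
#'
#' @param session A [session_record()] from the session preceding CN choice.
#' @param reference Index of the reference neuron (defaults to the session's
#'   CN).
#' @param top_frac Fraction of neurons to flag (default 0.05).
#' @return Logical mask over neurons.
#' @export
candidate_cn_mask <- function(session, reference = session$cn,
                              top_frac = 0.05) {
  st <- cn_screen_stats(session)
  r1 <- rank(st$modulation); r2 <- rank(st$start_tuning)
  d <- sqrt((r1 - r1[reference])^2 + (r2 - r2[reference])^2)
  k <- max(1L, ceiling(top_frac * length(d)))
  d <= sort(d)[k]
}

#' Epoch-weighted population average trace
#'
#' Time series obtained by weighting each neuron's ΔF/F trace by its tuning
#' component for the requested epoch and normalizing by the summed absolute
#' weights, so the output keeps trace units.
#'
#' @param session A [session_record()].
#' @param tuning A `task_tuning` table for the session's neurons.
#' @param epoch One of `"pre"`, `"early"`, `"late"`, `"rew"`.
#' @return Numeric vector, one value per frame.
#' @export
epoch_weighted_average <- function(session, tuning, epoch = "pre") {
  epoch <- match.arg(epoch, c("pre", "early", "late", "rew"))
  w <- tuning[[epoch]]
  w[!is.finite(w)] <- 0
  if (all(w == 0)) stop("all epoch weights are zero")
  as.numeric(crossprod(w, session$dff)) / sum(abs(w))
}

#' Pretrial activity predicts trial performance
#'
#' Regresses trial duration on the population-mean pretrial activity of the
#' same trial and reports the one-sided Wald p-value for a negative slope
#' (higher preparatory activity, shorter trials).
#'
#' @param session A [session_record()].
#' @param windows An [epoch_windows()].
#' @param max_trials Trial cutoff (default 40).
#' @return A list with `slope`, `wald_p` (one-sided, negative alternative)
#'   and `n_trials`.
#' @export
pretrial_performance_regression <- function(session,
                                            windows = epoch_windows(),
                                            max_trials = 40) {
  ea <- epoch_activity(session, windows, max_trials)
  pop_pre <- colMeans(ea$pre, na.rm = TRUE)
  dur <- ea$events$duration_s
  ok <- is.finite(pop_pre) & is.finite(dur)
  if (sum(ok) < 10L) stop("need >= 10 trials with defined pretrial activity")
  if (stats::var(pop_pre[ok]) == 0)
    stop("degenerate variance in pretrial activity")
  fit <- stats::lm(dur[ok] ~ pop_pre[ok])
  co <- summary(fit)$coefficients
  list(slope = co[2, 1],
       wald_p = stats::pt(co[2, 3], df = fit$df.residual),
       n_trials = sum(ok))
}
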