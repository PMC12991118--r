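#' Photostimulation group set
#'
#' Holds the stimulation-site coordinates and repeat onset times of each
#' holographic photostimulation group. Sites within a group must lie within
#' `max_sep` micrometers of each other (a hardware constraint of the light
#' path).
#'
#' @param sites List with one numeric sites x 2 matrix of coordinates (μm)
#'   per group.
#' @param onsets List with one numeric vector of repeat onset times (s) per
#'   group.
#' @param max_sep Maximum allowed pairwise site separation in μm (default
#'   400).
#' @param stim_duration Stimulus duration in seconds (default 0.1).
#' @param isi Inter-stimulus interval in seconds (default 0.6).
#' @return An object of class `photostim_groups`.
#' @export
photostim_groups <- function(sites, onsets, max_sep = 400,
                             stim_duration = 0.1, isi = 0.6) {
  if (length(sites) != length(onsets))
    stop("sites and onsets must have one entry per group")
  for (g in seq_along(sites)) {
    s <- as.matrix(sites[[g]])
    if (ncol(s) != 2L || any(!is.finite(s)))
      stop("group ", g, ": sites must be a finite n x 2 matrix")
    if (nrow(s) > 1L && max(stats::dist(s)) >= max_sep)
      stop("group ", g, ": max pairwise site separation exceeds ", max_sep,
           " um")
    sites[[g]] <- s
  }
  structure(list(sites = sites, onsets = onsets, n_groups = length(sites),
                 max_sep = max_sep, stim_duration = stim_duration, isi = isi),
            class = "photostim_groups")
}

#' @export
print.photostim_groups <- function(x, ...) {
  cat(sprintf("%d photostimulation groups, %s sites/group, %s repeats/group\n",
              x$n_groups,
              paste(range(vapply(x$sites, nrow, 1L)), collapse = "-"),
              paste(range(vapply(x$onsets, length, 1L)), collapse = "-")))
  invisible(x)
}

#' Read/write photostimulation group definitions as CSV
#'
#' `write_groups_csv` emits two files: `<stem>_sites.csv` with columns
#' `group_id, site_x_um, site_y_um` and `<stem>_onsets.csv` with columns
#' `group_id, onset_s`. `read_groups_csv` reassembles a
#' [photostim_groups()] from them.
#'
#' @param groups A `photostim_groups` object.
#' @param stem File-path stem.
#' @rdname groups_csv
#' @export
write_groups_csv <- function(groups, stem) {
  sites <- do.call(rbind, lapply(seq_along(groups$sites), function(g)
    data.frame(group_id = g, site_x_um = groups$sites[[g]][, 1],
               site_y_um = groups$sites[[g]][, 2])))
  ons <- do.call(rbind, lapply(seq_along(groups$onsets), function(g)
    data.frame(group_id = g, onset_s = groups$onsets[[g]])))
  utils::write.csv(sites, paste0(stem, "_sites.csv"), row.names = FALSE)
  utils::write.csv(ons, paste0(stem, "_onsets.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname groups_csv
#' @export
read_groups_csv <- function(stem) {
  sites <- utils::read.csv(paste0(stem, "_sites.csv"))
  ons <- utils::read.csv(paste0(stem, "_onsets.csv"))
  ids <- sort(unique(sites$group_id))
  photostim_groups(
    sites = lapply(ids, function(g)
      as.matrix(sites[sites$group_id == g, c("site_x_um", "site_y_um")])),
    onsets = lapply(ids, function(g) ons$onset_s[ons$group_id == g]))
}

#' Classify neurons as photostimulation targets and non-targets
#'
#' For each neuron and group, the minimum 2-D Euclidean distance to a
#' stimulation site decides the class: targets lie within 20 μm of a site
#' (potentially directly photostimulated), non-targets 30-100 μm away
#' (indirectly driven); the 20-30 μm annulus and neurons beyond 100 μm are
#' excluded. For paired-day analyses, pass the second day's positions: a
#' neuron keeps a class only if it satisfies the criterion on both days.
#'
#' @param positions Neurons x 2 coordinate matrix (μm).
#' @param groups A [photostim_groups()].
#' @param positions_b Optional second-day coordinates for cross-day masks.
#' @param target_radius,nontarget_range Class boundaries in μm.
#' @return An object of class `neuron_masks` with the distance matrix `d`
#'   (neurons x groups), logical matrices `target` and `nontarget`, and the
#'   radii used.
#' @export
classify_neurons <- function(positions, groups, positions_b = NULL,
                             target_radius = 20,
                             nontarget_range = c(30, 100)) {
  positions <- as.matrix(positions)
  if (any(!is.finite(positions))) stop("missing neuron positions")
  dmat <- function(pos) {
    vapply(groups$sites, function(s) {
      dx <- outer(pos[, 1], s[, 1], "-")
      dy <- outer(pos[, 2], s[, 2], "-")
      sqrt(apply(dx^2 + dy^2, 1L, min))
    }, numeric(nrow(pos)))
  }
  d <- dmat(positions)
  target <- d < target_radius
  nontarget <- d > nontarget_range[1] & d < nontarget_range[2]
  if (!is.null(positions_b)) {
    db <- dmat(as.matrix(positions_b))
    target <- target & (db < target_radius)
    nontarget <- nontarget & (db > nontarget_range[1] & db < nontarget_range[2])
  }
  structure(list(d = d, target = target, nontarget = nontarget,
                 target_radius = target_radius,
                 nontarget_range = nontarget_range),
            class = "neuron_masks")
}

#' Repeat responses to photostimulation
#'
#' For every neuron, group and repeat, the repeat response is the mean raw
#' fluorescence in the 300 ms window after stimulus offset minus the mean in
#' the 200 ms window before stimulus onset, normalized by the neuron's
#' repeat-averaged pre-stimulus baseline for that group (the 100 ms
#' stimulation period itself is excluded as laser-contaminated). Responses
#' are not computed for neurons that were targets of the immediately
#' preceding stimulation, whose activity is often still elevated; repeats
#' whose windows extend past the trace are dropped.
#'
#' @param traces Raw fluorescence matrix, neurons x frames.
#' @param groups A [photostim_groups()].
#' @param masks A [classify_neurons()] result (used for the
#'   preceding-target suppression rule).
#' @param frame_rate Frame rate in Hz (default 20).
#' @param before,after Window lengths in seconds (defaults 0.2 and 0.3).
#' @return An object of class `repeat_tensor`: `w_rep` is a list of
#'   neurons x repeats matrices (one per group, NA where suppressed or
#'   dropped), `b` the neurons x groups baseline matrix.
#' @export
repeat_response <- function(traces, groups, masks, frame_rate = 20,
                            before = 0.2, after = 0.3) {
  traces <- as.matrix(traces)
  n <- nrow(traces)
  times <- (seq_len(ncol(traces)) - 1L) / frame_rate
  sched <- do.call(rbind, lapply(seq_len(groups$n_groups), function(g)
    data.frame(g = g, a = seq_along(groups$onsets[[g]]),
               onset = groups$onsets[[g]])))
  sched <- sched[order(sched$onset), , drop = FALSE]
  prev_targets <- rep(FALSE, n)
  bef_mean <- aft_mean <- lapply(seq_len(groups$n_groups), function(g)
    matrix(NA_real_, n, length(groups$onsets[[g]])))
  n_dropped <- 0L
  for (k in seq_len(nrow(sched))) {
    g <- sched$g[k]; a <- sched$a[k]; on <- sched$onset[k]
    off <- on + groups$stim_duration
    sel_b <- times >= on - before & times < on
    sel_a <- times > off & times <= off + after
    if (on - before < 0 || off + after > times[length(times)] ||
        !any(sel_b) || !any(sel_a)) {
      n_dropped <- n_dropped + 1L
    } else {
      bm <- rowMeans(traces[, sel_b, drop = FALSE])
      am <- rowMeans(traces[, sel_a, drop = FALSE])
      bm[prev_targets] <- NA_real_
      am[prev_targets] <- NA_real_
      bef_mean[[g]][, a] <- bm
      aft_mean[[g]][, a] <- am
    }
    prev_targets <- masks$target[, g]
  }
  if (n_dropped > 0L)
    message(n_dropped, " repeat(s) dropped: window outside trace")
  b <- matrix(vapply(bef_mean, function(m) rowMeans(m, na.rm = TRUE),
                     numeric(n)), nrow = n)
  w_rep <- lapply(seq_len(groups$n_groups), function(g) {
    out <- (aft_mean[[g]] - bef_mean[[g]]) / b[, g]
    out[!is.finite(b[, g]) | b[, g] <= 0, ] <- NA_real_   # invalid baseline
    out
  })
  structure(list(w_rep = w_rep, b = b, n_dropped = n_dropped),
            class = "repeat_tensor")
}

#' Photostimulation response statistics
#'
#' The PS response of a neuron to a group is the mean of its repeat
#' responses divided by their standard deviation across repeats (sample,
#' n-1), so highly variable responses are down-weighted. Responses are
#' defined only where at least `min_repeats` repeats are available and the
#' repeat standard deviation is positive.
#'
#' @param tensor A [repeat_response()] tensor.
#' @param min_repeats Minimum repeat count (default 10).
#' @return An object of class `ps_response` with neurons x groups matrices
#'   `mu`, `sigma`, `w_ps` (= mu/sigma) and `n_rep`.
#' @export
ps_response <- function(tensor, min_repeats = 10) {
  mats <- tensor$w_rep
  n <- nrow(mats[[1]])
  g_mat <- function(f) matrix(vapply(mats, f, numeric(n)), nrow = n)
  mu <- g_mat(function(m) rowMeans(m, na.rm = TRUE))
  sigma <- g_mat(function(m) apply(m, 1L, stats::sd, na.rm = TRUE))
  n_rep <- g_mat(function(m) rowSums(is.finite(m)))
  w_ps <- mu / sigma
  bad <- n_rep < min_repeats | !is.finite(sigma) | sigma == 0
  degen <- n_rep >= min_repeats & is.finite(mu) & mu != 0 &
    is.finite(sigma) & sigma == 0
  if (any(degen))
    warning("zero repeat variability with nonzero mean; entries dropped")
  w_ps[bad] <- NA_real_
  mu[n_rep == 0] <- NA_real_
  structure(list(mu = mu, sigma = sigma, w_ps = w_ps, n_rep = n_rep,
                 min_repeats = min_repeats),
            class = "ps_response")
}

#' Across-day change in photostimulation response
#'
#' The ΔPS response is the difference of the two days' mean repeat responses
#' normalized by the square root of the summed repeat variances (standard
#' error propagation across a difference). Entries are defined only where
#' both days pass the minimum-repeat threshold.
#'
#' @param day_a,day_b [ps_response()] objects for the earlier and later day,
#'   stimulating the same groups.
#' @return Neurons x groups matrix of ΔPS responses (NA where undefined).
#' @export
delta_ps_response <- function(day_a, day_b) {
  if (!all(dim(day_a$mu) == dim(day_b$mu)))
    stop("sessions must stimulate the same neurons and groups")
  ok <- day_a$n_rep >= day_a$min_repeats & day_b$n_rep >= day_b$min_repeats &
    is.finite(day_a$sigma) & is.finite(day_b$sigma) &
    (day_a$sigma + day_b$sigma) > 0
  d <- (day_b$mu - day_a$mu) / sqrt(day_a$sigma^2 + day_b$sigma^2)
  d[!ok] <- NA_real_
  d
}

#' Masked causal-connectivity matrices and group totals
#'
#' Restricts PS responses to non-target neurons (the causal connectivity W;
#' with a second day, the Δcausal connectivity ΔW), and sums target-neuron
#' responses per group into the group totals used as control regressors.
#'
#' @param ps_a A [ps_response()] for the (first) session.
#' @param masks A [classify_neurons()] result.
#' @param ps_b Optional second-day [ps_response()]; adds `dW`, `dps_all` and
#'   `dw_g`.
#' @return An object of class `connectivity` with `W` (neurons x groups,
#'   non-targets only), `w_g` (per-group summed target response), and when
#'   `ps_b` is given `dW`, `dps_all` (ΔPS for all neurons) and `dw_g`.
#' @export
connectivity_matrices <- function(ps_a, masks, ps_b = NULL) {
  if (!all(dim(ps_a$w_ps) == dim(masks$target)))
    stop("masks inconsistent with PS response dimensions")
  W <- ps_a$w_ps
  W[!masks$nontarget] <- NA_real_
  sum_targets <- function(m) {
    out <- vapply(seq_len(ncol(m)), function(g) {
      v <- m[masks$target[, g], g]
      sum(v[is.finite(v)])
    }, numeric(1))
    empty <- colSums(masks$target) == 0
    if (any(empty)) {
      warning("group(s) with empty target set: totals set to 0")
      out[empty] <- 0
    }
    out
  }
  w_g <- sum_targets(ps_a$w_ps)
  res <- list(W = W, w_g = w_g)
  if (!is.null(ps_b)) {
    dps <- delta_ps_response(ps_a, ps_b)
    dW <- dps
    dW[!masks$nontarget] <- NA_real_
    res$dps_all <- dps
    res$dW <- dW
    res$dw_g <- sum_targets(dps)
    res$w_g_b <- sum_targets(ps_b$w_ps)
  }
  structure(res, class = "connectivity")
}

#' Write a neurons x groups matrix in long form
#'
#' Emits columns `neuron_id, group_id, value`, omitting undefined entries.
#'
#' @param mat Neurons x groups matrix (e.g. `W` or `dW`).
#' @param path Output CSV path.
#' @export
write_connectivity_csv <- function(mat, path) {
  idx <- which(is.finite(mat), arr.ind = TRUE)
  utils::write.csv(data.frame(neuron_id = idx[, 1], group_id = idx[, 2],
                              value = mat[idx]),
                   path, row.names = FALSE)
  invisible(path)
}
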