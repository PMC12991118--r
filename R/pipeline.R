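## Deterministic derivation of per-stage seeds from one experiment seed.
stage_seed <- function(seed, stage) {
  (seed * 97L + stage * 1009L) %% .Machine$integer.max
}

#' Run the full synthetic pipeline end to end
#'
#' Samples a ground-truth circuit, simulates BCI sessions with a rising CN
#' gain schedule, maps causal connectivity with a simulated photostimulation
#' block on each of two days (the second day carrying a planted
#' learning-related weight change that strengthens the output of
#' pretrial-tuned neurons), and fits the regression stage: the causal
#' connectivity lasso MLR on task tuning (base4), the Δcausal-connectivity
#' MLR (full8), and the correlation-regressor Wald tests with the summed
#' target-response control. A CN-specificity bootstrap across the simulated
#' sessions completes the summary.
#'
#' @param seed Global experiment seed; every stage derives its own seed from
#'   it deterministically.
#' @param n_neurons,n_groups,group_size,repeats Simulation sizes.
#' @param n_sessions Sessions for the CN bootstrap.
#' @param n_boot Bootstrap draws.
#' @param delta_coupling Planted across-day output strengthening per unit of
#'   (centered) pretrial tuning.
#' @param out_json Optional path: write the summary as JSON.
#' @return A list of class `photoplast_report`: the summary (JSON-ready) plus
#'   the fitted objects.
#' @export
run_full_synthetic <- function(seed = 1, n_neurons = 150, n_groups = 60,
                               group_size = 10, repeats = 12,
                               n_sessions = 3, n_boot = 2000,
                               delta_coupling = 0.03, out_json = NULL) {
  cfg <- circuit_config(n_neurons = n_neurons)
  circuit <- sample_circuit(cfg, seed = stage_seed(seed, 1))

  # sessions (one per "day"; the last is the learning day used for tuning)
  sessions <- lapply(seq_len(n_sessions), function(s) {
    circ_s <- circuit
    circ_s$cn <- which(circuit$epoch == "late")[s]
    if (is.na(circ_s$cn)) stop("not enough late-tuned CN candidates")
    simulate_session(circ_s, schedule = seq(0.3, 2.2, length.out = 40),
                     seed = stage_seed(seed, 10 + s))
  })
  session <- sessions[[n_sessions]]

  tuning <- tuning_and_delta(epoch_activity(session))
  if (!nrow(session$events)) stop("tuning stage: session has no trials")

  # photostimulation days: baseline weights, then weights plus a planted
  # pretrial-output strengthening
  groups <- sample_groups(circuit$positions, n_groups = n_groups,
                          group_size = group_size, repeats = repeats,
                          seed = stage_seed(seed, 2))
  pre_c <- circuit$tuning[, "pretrial"] - mean(circuit$tuning[, "pretrial"])
  dw_true <- matrix(pre_c, n_neurons, n_neurons, byrow = TRUE) * delta_coupling
  blk_a <- simulate_photostim_block(circuit, groups,
                                    seed = stage_seed(seed, 3))
  blk_b <- simulate_photostim_block(circuit, groups, delta_w = dw_true,
                                    seed = stage_seed(seed, 4))
  masks <- blk_a$masks
  ps_a <- ps_response(repeat_response(blk_a$traces, groups, masks), 10)
  ps_b <- ps_response(repeat_response(blk_b$traces, groups, masks), 10)
  con <- connectivity_matrices(ps_a, masks, ps_b)

  # causal connectivity fit (base4) with control
  tab_w <- build_tuning_regressors(tuning, ps_a, masks, "base4")
  y_w <- con$W[cbind(tab_w$i, tab_w$g)]
  keep <- is.finite(y_w)
  fit_w <- fit_lasso_cv(y_w[keep], tab_w[keep, , drop = FALSE],
                        seed = stage_seed(seed, 5))

  # correlation regressor Wald test (control = summed target response)
  C <- pairwise_correlations(session)
  a_rho <- correlation_regressor(C, ps_a, masks)
  rows_w <- cbind(tab_w$i, tab_w$g)[keep, , drop = FALSE]
  wald_rho <- wald_positive_test(con$W[rows_w], a_rho[rows_w],
                                 con$w_g[rows_w[, 2]])

  # delta fit (full8) with the change-in-target-response control
  tab_d <- build_tuning_regressors(tuning, ps_b, masks, "full8",
                                   control = con$dw_g)
  y_d <- con$dW[cbind(tab_d$i, tab_d$g)]
  keep_d <- is.finite(y_d)
  fit_d <- fit_lasso_cv(y_d[keep_d], tab_d[keep_d, , drop = FALSE],
                        seed = stage_seed(seed, 6))

  # CN-specificity bootstrap across sessions
  deltas <- lapply(sessions, function(s)
    tuning_and_delta(epoch_activity(s))$d_late)
  boot <- cn_sparsity_bootstrap(deltas,
                                vapply(sessions, function(s) s$cn, 1L),
                                n_draws = n_boot,
                                seed = stage_seed(seed, 7))

  bw <- coef(fit_w)
  summary <- list(
    seed = seed,
    n_neurons = n_neurons, n_groups = n_groups, repeats = repeats,
    n_w_pairs = sum(keep), n_dw_pairs = sum(keep_d),
    w_holdout_cor = fit_w$holdout_cor,
    dw_holdout_cor = fit_d$holdout_cor,
    coef_pretrial_target = unname(bw["nt_1.tg_pre"]),
    coef_like_to_like_reward = unname(bw["nt_rew.tg_rew"]),
    corr_regressor_slope = wald_rho$slope,
    corr_regressor_p = wald_rho$p_value,
    cn_bootstrap_percentile = boot$cn_median_percentile,
    cn_bootstrap_p = boot$p_value)
  if (!is.null(out_json))
    jsonlite::write_json(summary, out_json, auto_unbox = TRUE, digits = NA)
  structure(list(summary = summary, fit_w = fit_w, fit_d = fit_d,
                 wald_rho = wald_rho, bootstrap = boot, tuning = tuning,
                 connectivity = con),
            class = "photoplast_report")
}

#' @export
print.photoplast_report <- function(x, ...) {
  s <- x$summary
  cat("Synthetic end-to-end report\n")
  cat(sprintf("  W fit: %d pairs, held-out r = %.3f\n", s$n_w_pairs,
              s$w_holdout_cor))
  cat(sprintf("  pretrial-target coefficient: %.4f; like-to-like reward: %.4f\n",
              s$coef_pretrial_target, s$coef_like_to_like_reward))
  cat(sprintf("  correlation regressor: slope %.4f (one-sided p %.2g)\n",
              s$corr_regressor_slope, s$corr_regressor_p))
  cat(sprintf("  CN bootstrap percentile: %.3f (p %.3g)\n",
              s$cn_bootstrap_percentile, s$cn_bootstrap_p))
  invisible(x)
}

#' Compare plasticity loci in the RNN model
#'
#' For each requested plasticity locus, scans the learning rate on
#' calibration seeds, trains `n_seeds` networks at the selected rate,
#' measures in-silico photostimulation maps before and after training, and
#' pools correlation-versus-connectivity Wald tests across seeds. Reports
#' per-locus learning speed (median trials to 90% of target), the pooled
#' test statistics, and the rejected-run fraction.
#'
#' @param loci Character vector of plasticity loci.
#' @param n_seeds Networks per locus.
#' @param seed Base seed.
#' @param trials Training trials per network.
#' @param cfg_fun Function locus -> [rnn_config()] (default: standard
#'   configuration with that locus).
#' @param lr Optional named vector of fixed learning rates (skips the scan).
#' @return A list of class `locus_comparison`: per-locus results and a
#'   summary data.frame.
#' @export
run_model_comparison <- function(loci = c("recurrent", "input"),
                                 n_seeds = 10, seed = 1, trials = 40,
                                 cfg_fun = NULL, lr = NULL) {
  if (is.null(cfg_fun))
    cfg_fun <- function(locus) rnn_config(plasticity_locus = locus)
  per_locus <- lapply(loci, function(locus) {
    cfg <- cfg_fun(locus)
    lr_sel <- if (!is.null(lr) && locus %in% names(lr)) lr[[locus]] else
      scan_learning_rate(cfg, trials = trials,
                         base_seed = stage_seed(seed, 20))$lr
    trainings <- lapply(seq_len(n_seeds), function(s)
      train_bptt(rnn_model(cfg, seed = stage_seed(seed, 100 + s)),
                 trials = trials, lr = lr_sel,
                 seed = stage_seed(seed, 200 + s)))
    kept <- Filter(function(tr) !tr$rejected, trainings)
    ana <- model_connectivity_analysis(kept, seed = stage_seed(seed, 300))
    ttt <- vapply(trainings, function(tr)
      if (is.na(tr$trials_to_target)) Inf else tr$trials_to_target,
      numeric(1))
    list(locus = locus, lr = lr_sel, trainings = trainings,
         median_trials_to_target = stats::median(ttt),
         rejected_fraction = mean(vapply(trainings, function(tr)
           tr$rejected, logical(1))),
         analysis = ana)
  })
  names(per_locus) <- loci
  summary <- do.call(rbind, lapply(per_locus, function(r)
    data.frame(locus = r$locus, lr = r$lr,
               median_trials_to_target = r$median_trials_to_target,
               rejected_fraction = r$rejected_fraction,
               corr_W_p = r$analysis$corr_W$p_value,
               dcorr_dW_p = r$analysis$dcorr_dW$p_value,
               n_pairs = r$analysis$n_pairs)))
  structure(list(per_locus = per_locus, summary = summary, seed = seed),
            class = "locus_comparison")
}

#' @export
print.locus_comparison <- function(x, ...) {
  cat("RNN plasticity-locus comparison\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Reconstruction fidelity versus photostimulation group size
#'
#' Holds the total number of stimulation events fixed and varies how many
#' neurons are stimulated per event. Pairwise weights are reconstructed by
#' ridge-regressing each neuron's mean per-group responses on the group
#' membership matrix, and fidelity is the correlation between reconstructed
#' and true weights over well-separated pairs. More neurons per group cover
#' more weights per event, so fidelity rises with group size and saturates.
#'
#' @param sizes Group sizes to test.
#' @param n_neurons Circuit size.
#' @param n_groups,repeats Stimulation events per size (`n_groups * repeats`
#'   is the fixed event budget).
#' @param ridge Ridge penalty of the reconstruction.
#' @param seed Base seed.
#' @return Data.frame with columns `size` and `fidelity`.
#' @export
run_group_size_experiment <- function(sizes = c(1, 2, 5, 10, 15),
                                      n_neurons = 150, n_groups = 60,
                                      repeats = 12, ridge = 1, seed = 1) {
  circuit <- sample_circuit(circuit_config(n_neurons = n_neurons),
                            seed = stage_seed(seed, 1))
  d_pair <- as.matrix(stats::dist(circuit$positions))
  out <- lapply(sizes, function(k) {
    if (k >= n_neurons)
      stop("group size leaves no non-target neurons")
    grp <- sample_groups(circuit$positions, n_groups = n_groups,
                         group_size = k, repeats = repeats,
                         seed = stage_seed(seed, 30 + k))
    blk <- simulate_photostim_block(circuit, grp,
                                    seed = stage_seed(seed, 60 + k))
    tens <- repeat_response(blk$traces, grp, blk$masks)
    mu <- ps_response(tens, min_repeats = max(3, repeats %/% 2))$mu
    # membership matrix: groups x neurons (targets of each group)
    M <- t(blk$masks$target) * 1
    # reconstruct each neuron's incoming weights from the groups in which it
    # was not itself (nearly) directly driven
    w_hat <- matrix(NA_real_, n_neurons, n_neurons)
    for (i in seq_len(n_neurons)) {
      use <- blk$masks$d[i, ] > 30 & is.finite(mu[i, ])
      if (sum(use) < 3) next
      Mi <- M[use, , drop = FALSE]
      w_hat[i, ] <- solve(crossprod(Mi) + ridge * diag(n_neurons),
                          crossprod(Mi, mu[i, use]))
    }
    # fidelity over all well-separated pairs: columns never probed at this
    # budget stay at the ridge prior (0), so sparse coverage is penalized
    valid <- d_pair > 30 & row(d_pair) != col(d_pair) & is.finite(w_hat)
    data.frame(size = k,
               fidelity = stats::cor(w_hat[valid], circuit$w_true[valid]))
  })
  do.call(rbind, out)
}
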