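#' Preparatory-circuit model configuration
#'
#' Configuration of the hand-wired firing-rate circuit that captures the
#' transition from preparatory (pretrial) to late-trial dynamics: a pretrial
#' population generating low-dimensional preparatory activity, a downstream
#' trial population, several identical initially-untuned modules (one of
#' whose neurons is the conditioned neuron), and a reward neuron. Dynamics
#' follow `h <- h + (dt/tau) * (-h + W phi(h) + U x)` with a rectifier
#' nonlinearity and no noise. Learning is applied by hand as discrete weight
#' increments (no online plasticity): strengthened pretrial input onto one
#' neuron per module (creating the Δpretrial population), plus either a
#' broadcast increase from Δpretrial neurons onto all downstream populations
#' or, alternatively, feedback from Δpretrial neurons onto the pretrial
#' population.
#'
#' Baseline weights and increments are calibrated so that the CN's
#' late-period activity sits just below the movement threshold before
#' learning and above it afterwards in both variants (see
#' `inst/scripts/calibrate-prep-model.R`).
#'
#' @param n_pretrial,n_trial,n_modules,module_size,n_reward Population sizes.
#' @param dt,tau Integration step and time constant (s).
#' @param t_pre,t_late Pretrial and late-period durations (s).
#' @param movement_threshold CN late-period activity required to move the
#'   reward port.
#' @param w_pp,w_tp,w_tt,w_mod,w_tm,w_rt Baseline weights: within-pretrial,
#'   pretrial->trial, within-trial, within-module, trial->module,
#'   trial->reward (per connection).
#' @param w_pm,w_pr Weak baseline pretrial->module and pretrial->reward
#'   weights (the widespread pretrial excitation motif; small enough that
#'   modules stay essentially untuned before learning).
#' @param dw_pre,dw_broadcast,dw_feedback Learning increments: pretrial onto
#'   each Δpretrial neuron; Δpretrial broadcast onto downstream populations;
#'   Δpretrial feedback onto the pretrial population.
#' @param input_amp Amplitude of the constant per-period drives.
#' @return An object of class `prep_config`.
#' @export
prep_config <- function(n_pretrial = 10, n_trial = 10, n_modules = 5,
                        module_size = 4, n_reward = 1, dt = 0.01, tau = 0.1,
                        t_pre = 1, t_late = 1, movement_threshold = 0.15,
                        w_pp = 0.05, w_tp = 0.03, w_tt = 0.03, w_mod = 0.1,
                        w_tm = 0.005, w_rt = 0.03, w_pm = 0.003, w_pr = 0.003,
                        dw_pre = 0.05,
                        dw_broadcast = 0.04, dw_feedback = 0.04,
                        input_amp = 1) {
  if (module_size < 2) stop("module_size must be >= 2 (CN is a module neuron)")
  structure(as.list(environment()), class = "prep_config")
}

#' Build the hand-wired preparatory network
#'
#' Wires the baseline circuit: recurrent excitation within the pretrial
#' population, widespread pretrial-to-trial excitation, weak recurrence in
#' the trial population, internal excitation within each module, weak
#' trial-to-module drive (so the CN has weak trial responses before
#' learning), and trial-to-reward drive. Modules receive no pretrial input
#' (initially untuned). The CN is the second neuron of the first module;
#' the Δpretrial candidates are the first neuron of each module.
#'
#' @param cfg A [prep_config()].
#' @return An object of class `prep_network` with weight matrix `W`, input
#'   matrix `U` (two drive channels: pretrial, trial), population `labels`,
#'   `cn` index, `dpre` indices, and `cfg`.
#' @export
build_network <- function(cfg = prep_config()) {
  n <- cfg$n_pretrial + cfg$n_trial + cfg$n_modules * cfg$module_size +
    cfg$n_reward
  P <- seq_len(cfg$n_pretrial)
  Tr <- cfg$n_pretrial + seq_len(cfg$n_trial)
  mod_start <- cfg$n_pretrial + cfg$n_trial
  modules <- lapply(seq_len(cfg$n_modules) - 1L, function(m)
    mod_start + m * cfg$module_size + seq_len(cfg$module_size))
  M <- unlist(modules)
  R <- mod_start + cfg$n_modules * cfg$module_size + seq_len(cfg$n_reward)
  W <- matrix(0, n, n)
  W[P, P] <- cfg$w_pp
  W[Tr, P] <- cfg$w_tp
  W[Tr, Tr] <- cfg$w_tt
  for (idx in modules) { W[idx, idx] <- cfg$w_mod; diag(W[idx, idx]) <- 0 }
  W[M, Tr] <- cfg$w_tm
  W[R, Tr] <- cfg$w_rt
  W[M, P] <- cfg$w_pm
  W[R, P] <- cfg$w_pr
  U <- matrix(0, n, 2)
  U[P, 1] <- cfg$input_amp
  U[Tr, 2] <- cfg$input_amp
  labels <- rep("module", n)
  labels[P] <- "pretrial"; labels[Tr] <- "trial"; labels[R] <- "reward"
  dpre <- vapply(modules, `[`, numeric(1), 1L)
  structure(list(W = W, U = U, labels = labels,
                 cn = modules[[1]][2], dpre = dpre,
                 populations = list(pretrial = P, trial = Tr,
                                    modules = modules, reward = R),
                 manipulation = "none", cfg = cfg),
            class = "prep_network")
}

#' @export
print.prep_network <- function(x, ...) {
  cat(sprintf(
    "Preparatory circuit: %d neurons (%d pretrial, %d trial, %d x %d modules, %d reward), learning: %s\n",
    nrow(x$W), x$cfg$n_pretrial, x$cfg$n_trial, x$cfg$n_modules,
    x$cfg$module_size, x$cfg$n_reward, x$manipulation))
  invisible(x)
}

#' Apply the learning manipulation to the preparatory network
#'
#' `"broadcast"` applies both experimental motifs: strengthened pretrial
#' input onto one neuron per module (these become the Δpretrial population)
#' and a broadcast increase from Δpretrial neurons onto all downstream
#' populations (trial, modules, reward; no self-connections). `"feedback"`
#' applies the pretrial-onto-Δpretrial increase plus the alternative motif:
#' strengthened connections from Δpretrial neurons back onto the pretrial
#' population. `"none"` returns the network unchanged. No other weights are
#' touched.
#'
#' @param network A [build_network()] result.
#' @param manipulation `"none"`, `"broadcast"` or `"feedback"`.
#' @return The modified network.
#' @export
apply_learning <- function(network,
                           manipulation = c("none", "broadcast", "feedback")) {
  manipulation <- match.arg(manipulation)
  if (manipulation == "none") return(network)
  cfg <- network$cfg
  P <- network$populations$pretrial
  down <- c(network$populations$trial,
            unlist(network$populations$modules),
            network$populations$reward)
  W <- network$W
  W[network$dpre, P] <- W[network$dpre, P] + cfg$dw_pre
  if (manipulation == "broadcast") {
    W[down, network$dpre] <- W[down, network$dpre] + cfg$dw_broadcast
    for (dp in network$dpre) W[dp, dp] <- network$W[dp, dp]
  } else {
    W[P, network$dpre] <- W[P, network$dpre] + cfg$dw_feedback
  }
  network$W <- W
  network$manipulation <- manipulation
  network
}

#' Simulate one trial of the preparatory circuit
#'
#' Deterministic simulation from rest: the pretrial drive is on for `t_pre`
#' seconds, then the circuit transitions directly to the late period with
#' the trial drive on for `t_late` seconds (early and late trial collapsed,
#' as in short BCI trials).
#'
#' @param network A [build_network()] result (possibly after
#'   [apply_learning()]).
#' @return An object of class `prep_trace`: hidden trajectory `H` (neurons x
#'   steps), per-neuron `pre_mean` and `late_mean`, per-population mean
#'   traces, the CN late-period mean `cn_late` and whether it crosses the
#'   movement threshold.
#' @export
simulate_trial <- function(network) {
  cfg <- network$cfg
  n <- nrow(network$W)
  a <- cfg$dt / cfg$tau
  Tp <- round(cfg$t_pre / cfg$dt); Tl <- round(cfg$t_late / cfg$dt)
  H <- matrix(0, n, Tp + Tl)
  h <- rep(0, n)
  for (t in seq_len(Tp + Tl)) {
    x <- if (t <= Tp) c(1, 0) else c(0, 1)
    h <- h + a * (-h + network$W %*% pmax(h, 0) + network$U %*% x)
    if (!all(is.finite(h))) stop("non-finite state at step ", t)
    H[, t] <- h
  }
  pre_mean <- rowMeans(H[, seq_len(Tp), drop = FALSE])
  late_mean <- rowMeans(H[, Tp + seq_len(Tl), drop = FALSE])
  pops <- list(pretrial = network$populations$pretrial,
               dpretrial = network$dpre,
               trial = network$populations$trial,
               cn = network$cn,
               reward = network$populations$reward)
  pop_traces <- lapply(pops, function(idx)
    colMeans(H[idx, , drop = FALSE]))
  structure(list(H = H, pre_mean = pre_mean, late_mean = late_mean,
                 pop_traces = pop_traces, cn_late = late_mean[network$cn],
                 crosses_threshold =
                   late_mean[network$cn] > cfg$movement_threshold,
                 Tp = Tp, Tl = Tl),
            class = "prep_trace")
}

#' @export
print.prep_trace <- function(x, ...) {
  cat(sprintf("Preparatory-model trial: CN late activity %.4f (%s threshold)\n",
              x$cn_late,
              if (x$crosses_threshold) "crosses" else "below"))
  invisible(x)
}

## Deterministic in-silico photostimulation of the rectified circuit:
## clamp each neuron to h_pert in turn and measure everyone else's change
## in activity (during-clamp mean minus resting baseline).
prep_photostim <- function(network, h_pert = 1, during_s = 1) {
  cfg <- network$cfg
  n <- nrow(network$W)
  a <- cfg$dt / cfg$tau
  Td <- round(during_s / cfg$dt)
  out <- matrix(0, n, n)
  for (g in seq_len(n)) {
    h <- rep(0, n); h[g] <- h_pert
    acc <- rep(0, n)
    for (t in seq_len(Td)) {
      h <- h + a * (-h + network$W %*% pmax(h, 0))
      h[g] <- h_pert
      acc <- acc + h
    }
    out[, g] <- acc / Td   # baseline is the resting state (0)
  }
  out
}

#' Regression of model Δcausal connectivity on model tuning
#'
#' The in-model analog of the Δcausal-connectivity fit: in-silico
#' photostimulation maps are measured before and after the learning
#' manipulation, each neuron is given a tuning vector from the simulated
#' trial (pretrial mean, late mean, and their learning-related changes), and
#' a cross-validated lasso MLR predicts the per-pair change in
#' photostimulation response from the tuning products `Y_i * X_g`. Since
#' every stimulated neuron receives the same direct drive, no control
#' regressor is used. The key motifs appear as positive coefficients on the
#' pretrial(target) x Δpretrial(non-target) interaction and on the
#' Δpretrial(target) main effect.
#'
#' @param network_pre Baseline network ([build_network()]).
#' @param network_post Network after [apply_learning()].
#' @param h_pert Photostimulation clamp value.
#' @param folds,seed Cross-validation settings for [fit_lasso_cv()].
#' @return List with the `mlr_fit`, the regressor `table`, the response
#'   `dW`, and the named `key_coefficients`.
#' @export
model_delta_connectivity_fit <- function(network_pre, network_post,
                                         h_pert = 1, folds = 10, seed = 1) {
  W0 <- prep_photostim(network_pre, h_pert)
  W1 <- prep_photostim(network_post, h_pert)
  tr0 <- simulate_trial(network_pre)
  tr1 <- simulate_trial(network_post)
  tun <- data.frame(pre = tr0$pre_mean, late = tr0$late_mean,
                    d_pre = tr1$pre_mean - tr0$pre_mean,
                    d_late = tr1$late_mean - tr0$late_mean)
  if (all(abs(tun$d_pre) < 1e-12) && all(abs(tun$d_late) < 1e-12) &&
      stats::var(tun$pre) == 0)
    stop("degenerate tuning variance")
  n <- nrow(W0)
  masks <- structure(list(target = diag(n) > 0, nontarget = diag(n) == 0),
                     class = "neuron_masks")
  w_unit <- diag(n)   # single-neuron groups, uniform direct drive
  tab <- build_regressors_generic(tun, c("pre", "late", "d_pre", "d_late"),
                                  w_unit, masks, include_control = FALSE)
  dW <- (W1 - W0)[cbind(tab$i, tab$g)]
  keep_cols <- attr(tab, "tuning_cols")
  X <- as.matrix(as.data.frame(tab)[keep_cols])
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 1e-12, drop = FALSE]
  fit <- fit_lasso_cv(dW, X, folds = folds, seed = seed)
  b <- coef(fit)
  keys <- c(pre_to_dpre = unname(b["nt_d_pre.tg_pre"]),
            dpre_to_all = unname(b["nt_1.tg_d_pre"]))
  # marginal (single-regressor) association for the same motifs; an
  # effective pattern routed through the preparatory population shows up
  # here even when the sparse multivariate fit attributes it to collinear
  # interaction terms
  marg <- sapply(c(pre_to_dpre = "nt_d_pre.tg_pre",
                   dpre_to_all = "nt_1.tg_d_pre"),
                 function(cl) {
                   if (stats::sd(tab[[cl]]) < 1e-12) return(NA_real_)
                   wald_positive_test(dW, tab[[cl]])$statistic
                 })
  list(fit = fit, table = tab, dW = dW, key_coefficients = keys,
       key_marginal_t = marg)
}
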