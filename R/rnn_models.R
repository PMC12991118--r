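#' Rate-RNN configuration
#'
#' Configuration of the vanilla rate recurrent network used to model the
#' motor-cortex (MC) circuit during BCI learning: `n` hidden neurons
#' represent MC, `d` input neurons represent upstream drive. Hidden dynamics
#' follow `h <- h + (dt/tau) * (-h + phi(a_exc * (W_rec h + W_inp x)) + noise)`
#' with `phi = tanh` by default. The plasticity locus selects which weights
#' receive gradients during training: upstream (`input`), local recurrent
#' (`recurrent`), `both` (with matched update magnitudes), per-neuron
#' `excitability`, or the recurrent weights of a separate upstream RNN
#' (`upstream_recurrent`).
#'
#' @param n,d Hidden and input layer sizes.
#' @param dt,tau Integration time step and network time constant (s);
#'   requires `dt < tau`.
#' @param noise_scale SD of the per-step hidden noise.
#' @param w_rec_scale,w_inp_scale Initialization scales; entries are drawn as
#'   `scale/sqrt(fan_in) * N(0,1)` so the recurrent spectral radius is about
#'   `w_rec_scale`.
#' @param nonlinearity `"tanh"`, `"relu"` or `"linear"`.
#' @param h_pert Clamp value used for in-silico photostimulation.
#' @param ps_repeats Photostimulation repeats per stimulated neuron.
#' @param ps_input_noise SD of the input-layer noise injected during
#'   photostimulation.
#' @param stabilization_trials Trials with frozen weights before and after
#'   training, used for CN selection, the activity target and correlations.
#' @param plasticity_locus Which weights are plastic (see Description).
#' @param feedback_noise_scale SD of the feedback-misalignment perturbation
#'   added to the readout to form the credit-routing vector.
#' @param t_pre,t_late Pretrial and late-period durations per trial (s).
#' @param upstream_n Hidden size of the upstream RNN (upstream_recurrent
#'   locus).
#' @param w_csc_scale Scale of optional hidden-to-input loop connections
#'   (0 disables the loop).
#' @return An object of class `rnn_config`.
#' @export
rnn_config <- function(n = 100, d = 10, dt = 0.01, tau = 0.1,
                       noise_scale = 0.01, w_rec_scale = 0.5,
                       w_inp_scale = 0.1,
                       nonlinearity = c("tanh", "relu", "linear"),
                       h_pert = 1, ps_repeats = 5, ps_input_noise = 0.02,
                       stabilization_trials = 10,
                       plasticity_locus = c("recurrent", "input", "both",
                                            "excitability",
                                            "upstream_recurrent"),
                       feedback_noise_scale = 0.25,
                       t_pre = 1, t_late = 1, upstream_n = 20,
                       w_csc_scale = 0) {
  nonlinearity <- match.arg(nonlinearity)
  plasticity_locus <- match.arg(plasticity_locus)
  if (dt >= tau) stop("dt must be smaller than tau")
  if (n < 2 || d < 1) stop("n and d must be positive (n >= 2)")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  structure(list(n = as.integer(n), d = as.integer(d), dt = dt, tau = tau,
                 noise_scale = noise_scale, w_rec_scale = w_rec_scale,
                 w_inp_scale = w_inp_scale, nonlinearity = nonlinearity,
                 h_pert = h_pert, ps_repeats = as.integer(ps_repeats),
                 ps_input_noise = ps_input_noise,
                 stabilization_trials = as.integer(stabilization_trials),
                 plasticity_locus = plasticity_locus,
                 feedback_noise_scale = feedback_noise_scale,
                 t_pre = t_pre, t_late = t_late,
                 upstream_n = as.integer(upstream_n),
                 w_csc_scale = w_csc_scale),
            class = "rnn_config")
}

phi_fun <- function(kind) switch(kind,
  tanh = list(f = tanh, df_from_u = function(u, p) 1 - p^2),
  relu = list(f = function(x) pmax(x, 0),
              df_from_u = function(u, p) (u > 0) * 1),
  linear = list(f = identity, df_from_u = function(u, p) u * 0 + 1))

#' Initialize a rate RNN model
#'
#' Draws recurrent and input weights (`scale/sqrt(fan_in) * N(0,1)`), the two
#' constant task input vectors (standard normal, one for the pretrial and one
#' for the late period), and variant-specific weights (upstream RNN,
#' hidden-to-input loop). The conditioned neuron, activity target and
#' readout/feedback vectors are set later by [select_model_cn()].
#'
#' @param cfg An [rnn_config()].
#' @param seed Integer seed.
#' @return An object of class `rnn_model`.
#' @export
rnn_model <- function(cfg = rnn_config(), seed = 1) {
  set.seed(seed)
  n <- cfg$n; d <- cfg$d
  m <- list(cfg = cfg, seed = seed,
            W_rec = matrix(stats::rnorm(n * n, 0, cfg$w_rec_scale / sqrt(n)), n),
            W_inp = matrix(stats::rnorm(n * d, 0, cfg$w_inp_scale / sqrt(d)), n),
            x_pre = stats::rnorm(d), x_late = stats::rnorm(d),
            a_exc = rep(1, n), cn = NA_integer_, gamma_hat = NA_real_,
            w_bci = NULL, w_back = NULL)
  if (cfg$plasticity_locus == "upstream_recurrent") {
    nu <- cfg$upstream_n
    m$W_rec_up <- matrix(stats::rnorm(nu * nu, 0, cfg$w_rec_scale / sqrt(nu)), nu)
    m$W_inp_g <- matrix(stats::rnorm(nu * d, 0, cfg$w_inp_scale / sqrt(d)), nu)
    m$W_inp_up <- matrix(stats::rnorm(n * nu, 0, cfg$w_inp_scale / sqrt(nu)), n)
  }
  if (cfg$w_csc_scale > 0)
    m$W_csc <- matrix(stats::rnorm(d * n, 0, cfg$w_csc_scale / sqrt(n)), d)
  structure(m, class = "rnn_model")
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf("Rate RNN: n = %d, d = %d, locus = %s, nonlinearity = %s\n",
              x$cfg$n, x$cfg$d, x$cfg$plasticity_locus, x$cfg$nonlinearity))
  if (!is.na(x$cn))
    cat(sprintf("CN = %d, target activity = %.4f\n", x$cn, x$gamma_hat))
  invisible(x)
}

#' One step of the hidden dynamics
#'
#' Advances the hidden state by a single Euler step of the rate equation,
#' optionally with an externally supplied noise vector (zero noise when
#' `NULL` and `deterministic = TRUE`, freshly drawn otherwise).
#'
#' @param model An [rnn_model()].
#' @param state Hidden state vector (length n).
#' @param input Input vector (length d).
#' @param noise Optional length-n noise vector; if `NULL` and
#'   `deterministic = FALSE`, drawn as `noise_scale * N(0,1)`.
#' @param deterministic Suppress noise when `noise` is NULL.
#' @return The next hidden state.
#' @export
step_dynamics <- function(model, state, input, noise = NULL,
                          deterministic = FALSE) {
  cfg <- model$cfg
  if (!all(is.finite(state))) stop("non-finite hidden state")
  if (is.null(noise))
    noise <- if (deterministic) rep(0, cfg$n) else
      stats::rnorm(cfg$n, 0, cfg$noise_scale)
  ph <- phi_fun(cfg$nonlinearity)
  u <- model$a_exc * (model$W_rec %*% state + model$W_inp %*% input)
  out <- state + cfg$dt / cfg$tau * (-state + ph$f(u) + noise)
  if (!all(is.finite(out))) stop("non-finite state after step")
  as.numeric(out)
}

## Full forward pass of one trial (pretrial then late period), storing the
## trajectory and preactivations needed by BPTT. Returns n x T matrices.
rnn_trial_forward <- function(model) {
  cfg <- model$cfg
  n <- cfg$n
  Tp <- round(cfg$t_pre / cfg$dt); Tl <- round(cfg$t_late / cfg$dt)
  Tt <- Tp + Tl
  a <- cfg$dt / cfg$tau
  ph <- phi_fun(cfg$nonlinearity)
  up <- cfg$plasticity_locus == "upstream_recurrent" &&
    !is.null(model$W_rec_up)
  X <- cbind(matrix(model$x_pre, cfg$d, Tp), matrix(model$x_late, cfg$d, Tl))
  H <- matrix(0, n, Tt); Uact <- matrix(0, n, Tt); P <- matrix(0, n, Tt)
  Xeff <- matrix(0, cfg$d, Tt)
  if (up) {
    nu <- cfg$upstream_n
    G <- matrix(0, nu, Tt); UG <- matrix(0, nu, Tt); PG <- matrix(0, nu, Tt)
    g <- rep(0, nu)
  }
  h <- rep(0, n)
  noise <- matrix(stats::rnorm(n * Tt, 0, cfg$noise_scale), n)
  for (t in seq_len(Tt)) {
    xt <- X[, t]
    if (!is.null(model$W_csc)) xt <- ph$f(model$W_csc %*% h + xt)
    Xeff[, t] <- xt
    if (up) {
      ug <- model$W_rec_up %*% g + model$W_inp_g %*% xt
      pg <- ph$f(ug)
      g <- g + a * (-g + pg)
      G[, t] <- g; UG[, t] <- ug; PG[, t] <- pg
      u <- model$a_exc * (model$W_rec %*% h + model$W_inp_up %*% g)
    } else {
      u <- model$a_exc * (model$W_rec %*% h + model$W_inp %*% xt)
    }
    p <- ph$f(u)
    h <- h + a * (-h + p + noise[, t])
    H[, t] <- h; Uact[, t] <- u; P[, t] <- p
  }
  out <- list(H = H, U = Uact, P = P, X = Xeff, Tp = Tp, Tl = Tl)
  if (up) { out$G <- G; out$UG <- UG; out$PG <- PG }
  out
}

#' Select the model conditioned neuron and activity target
#'
#' From the stabilization trials (frozen weights), the CN is chosen among
#' neurons whose mean pretrial and late-period activity both exceed the
#' population medians, as the eligible neuron with the smallest
#' pretrial/late difference (ties broken toward the lowest index), mirroring
#' the experimental requirement of an active neuron with weak trial-start
#' tuning. The activity target is the 95th percentile of the CN's activity
#' over the stabilization period. The readout `w_bci` is one-hot at the CN
#' and the credit-routing vector `w_back = w_bci + w_tilde` with
#' `w_tilde ~ feedback_noise_scale * N(0,1)` zeroed at the CN, so
#' `w_back . w_bci = 1` exactly.
#'
#' @param model An [rnn_model()].
#' @param stab_trials List of trial forward passes (internal format) from the
#'   stabilization period; run automatically by [train_bptt()].
#' @return The model with `cn`, `gamma_hat`, `w_bci`, `w_back` set.
#' @export
select_model_cn <- function(model, stab_trials) {
  Tp <- stab_trials[[1]]$Tp
  pre <- rowMeans(sapply(stab_trials, function(s)
    rowMeans(s$H[, seq_len(Tp), drop = FALSE])))
  late <- rowMeans(sapply(stab_trials, function(s)
    rowMeans(s$H[, -seq_len(Tp), drop = FALSE])))
  elig <- which(pre > stats::median(pre) & late > stats::median(late))
  if (length(elig) == 0L) stop("no eligible CN candidates")
  cn <- elig[which.min(abs(pre - late)[elig])]
  gamma_hat <- stats::quantile(
    unlist(lapply(stab_trials, function(s) s$H[cn, ])), 0.95, names = FALSE)
  w_bci <- rep(0, model$cfg$n); w_bci[cn] <- 1
  w_tilde <- stats::rnorm(model$cfg$n, 0, model$cfg$feedback_noise_scale)
  w_tilde[cn] <- 0
  model$cn <- cn
  model$gamma_hat <- gamma_hat
  model$w_bci <- w_bci
  model$w_back <- w_bci + w_tilde
  model
}

## BPTT gradients of the late-period MSE loss for one trial, with the error
## routed through w_back instead of the true readout. Returns the gradients
## for the active plasticity locus.
rnn_trial_backward <- function(model, fw) {
  cfg <- model$cfg
  a <- cfg$dt / cfg$tau
  n <- cfg$n; Tt <- fw$Tp + fw$Tl
  ph <- phi_fun(cfg$nonlinearity)
  locus <- cfg$plasticity_locus
  up <- locus == "upstream_recurrent"
  Hprev <- cbind(rep(0, n), fw$H[, -Tt, drop = FALSE])
  gamma <- fw$H[model$cn, ]
  dW <- if (locus %in% c("recurrent", "both")) matrix(0, n, n)
  dU <- if (locus %in% c("input", "both")) matrix(0, n, cfg$d)
  da <- if (locus == "excitability") rep(0, n)
  dWup <- if (up) matrix(0, cfg$upstream_n, cfg$upstream_n)
  if (up) {
    Gprev <- cbind(rep(0, cfg$upstream_n), fw$G[, -Tt, drop = FALSE])
    delta_g <- rep(0, cfg$upstream_n)
  }
  delta <- rep(0, n)
  for (t in Tt:1) {
    if (t > fw$Tp)
      delta <- delta + (2 * (gamma[t] - model$gamma_hat) / fw$Tl) * model$w_back
    dphi <- ph$df_from_u(fw$U[, t], fw$P[, t])
    z <- a * model$a_exc * dphi * delta
    if (!is.null(dW)) dW <- dW + tcrossprod(z, Hprev[, t])
    if (!is.null(dU)) dU <- dU + tcrossprod(z, fw$X[, t])
    if (!is.null(da)) {
      v <- fw$U[, t] / model$a_exc     # pre-gain activation
      da <- da + a * dphi * delta * v
    }
    if (up) {
      # credit reaches g_t from h_t (same step, via W_inp_up) and from g_{t+1}
      delta_g <- delta_g + as.numeric(crossprod(model$W_inp_up, z))
      dphig <- ph$df_from_u(fw$UG[, t], fw$PG[, t])
      zg <- a * dphig * delta_g
      dWup <- dWup + tcrossprod(zg, Gprev[, t])
      delta_g <- as.numeric((1 - a) * delta_g + crossprod(model$W_rec_up, zg))
    }
    delta <- as.numeric((1 - a) * delta + crossprod(model$W_rec, z))
  }
  list(dW = dW, dU = dU, da = da, dWup = dWup)
}

#' Train an RNN on the BCI task by backpropagation through time
#'
#' Runs the stabilization period (no weight updates), selects the CN and
#' activity target, then trains one trial at a time: each trial resets the
#' hidden state to zero, presents the constant pretrial then late-period
#' inputs, and minimizes the MSE between the CN readout and the target over
#' the late period only, with credit routed through the misaligned feedback
#' vector. Gradients are applied only to the weights of the configured
#' plasticity locus (in `both` mode the input-layer rate is rescaled once so
#' the two loci produce comparable update magnitudes). A final stabilization
#' period is recorded for correlation analyses. Runs whose loss never drops
#' below its initial value are flagged as rejected.
#'
#' @param model An [rnn_model()] (CN selected automatically if unset).
#' @param trials Number of training trials.
#' @param lr Learning rate.
#' @param seed Integer seed for trial noise and feedback draw.
#' @param target_frac Fraction of the activity target counting as learned
#'   (default 0.9).
#' @return An object of class `rnn_training`: the initial and trained models,
#'   per-trial `loss` and `cn_late` activity, `trials_to_target`, per-neuron
#'   incoming weight-change magnitudes, stabilization trial logs before and
#'   after training, and the `rejected` flag.
#' @export
train_bptt <- function(model, trials = 40, lr = 0.1, seed = 1,
                       target_frac = 0.9) {
  set.seed(seed)
  cfg <- model$cfg
  stab_before <- replicate(cfg$stabilization_trials, rnn_trial_forward(model),
                           simplify = FALSE)
  if (is.na(model$cn)) model <- select_model_cn(model, stab_before)
  model_init <- model
  locus <- cfg$plasticity_locus
  loss <- cn_late <- numeric(trials)
  lr_inp <- lr
  both_scaled <- locus != "both"
  for (k in seq_len(trials)) {
    fw <- rnn_trial_forward(model)
    gamma_late <- fw$H[model$cn, -seq_len(fw$Tp)]
    loss[k] <- mean((gamma_late - model$gamma_hat)^2)
    cn_late[k] <- mean(gamma_late)
    if (!is.finite(loss[k])) stop("non-finite loss at trial ", k)
    gr <- rnn_trial_backward(model, fw)
    if (!both_scaled) {
      # match update magnitudes across the two loci
      ninp <- sqrt(sum(gr$dU^2)); nrec <- sqrt(sum(gr$dW^2))
      if (ninp > 0 && nrec > 0) lr_inp <- lr * nrec / ninp
      both_scaled <- TRUE
    }
    if (!is.null(gr$dW)) model$W_rec <- model$W_rec - lr * gr$dW
    if (!is.null(gr$dU)) model$W_inp <- model$W_inp - lr_inp * gr$dU
    if (!is.null(gr$da)) model$a_exc <- model$a_exc - lr * gr$da
    if (!is.null(gr$dWup)) model$W_rec_up <- model$W_rec_up - lr * gr$dWup
  }
  stab_after <- replicate(cfg$stabilization_trials, rnn_trial_forward(model),
                          simplify = FALSE)
  dw_in <- rowSums(abs(model$W_rec - model_init$W_rec)) +
    rowSums(abs(model$W_inp - model_init$W_inp))
  structure(list(model_init = model_init, model = model, loss = loss,
                 cn_late = cn_late,
                 trials_to_target =
                   which(cn_late >= target_frac * model$gamma_hat)[1],
                 weight_change_in = dw_in,
                 stab_before = stab_before, stab_after = stab_after,
                 rejected = !any(loss < loss[1]), seed = seed, lr = lr),
            class = "rnn_training")
}

#' @export
print.rnn_training <- function(x, ...) {
  cat(sprintf(
    "RNN training (%s locus): %d trials, loss %.4g -> %.4g%s\n",
    x$model$cfg$plasticity_locus, length(x$loss), x$loss[1],
    x$loss[length(x$loss)], if (x$rejected) " [REJECTED: no loss decrease]" else ""))
  cat(sprintf("CN late activity reached 90%% of target at trial %s\n",
              x$trials_to_target))
  invisible(x)
}

#' Scan learning rates for experiment-like training speed
#'
#' Trains a few calibration seeds at each rate of a log-spaced grid and
#' keeps the rates that are usable: stable (finite, decreasing loss) and
#' reliably learning (every calibration run reaches the target within the
#' trial budget). Among usable rates whose median trials-to-target stays
#' within `max_ttt`, the selected rate is the slowest-completing one — the
#' training speed closest to the tens-of-trials timescale of the animals
#' while still learning within the bound.
#'
#' @param cfg An [rnn_config()].
#' @param lr_grid Learning-rate grid (default 9 values over 4 decades).
#' @param n_seeds Calibration seeds per rate.
#' @param trials Training trials per run.
#' @param max_ttt Upper bound on the acceptable median trials-to-target.
#' @param base_seed Seed offset for the calibration runs.
#' @return List with the selected `lr` and the scan `table`.
#' @export
scan_learning_rate <- function(cfg, lr_grid = 10^seq(-3, 1, length.out = 9),
                               n_seeds = 3, trials = 40, max_ttt = 30,
                               base_seed = 1000) {
  rows <- lapply(lr_grid, function(lr) {
    res <- lapply(seq_len(n_seeds), function(s) {
      tr <- try(train_bptt(rnn_model(cfg, seed = base_seed + s),
                           trials = trials, lr = lr, seed = base_seed + s),
                silent = TRUE)
      if (inherits(tr, "try-error")) return(NULL)
      tr
    })
    res <- Filter(Negate(is.null), res)
    if (length(res) < n_seeds)
      return(data.frame(lr = lr, median_ttt = NA, stable = FALSE))
    ttt <- vapply(res, function(r)
      if (is.na(r$trials_to_target)) Inf else r$trials_to_target, numeric(1))
    stable <- !any(vapply(res, function(r) r$rejected, logical(1)))
    data.frame(lr = lr, median_ttt = stats::median(ttt), stable = stable,
               all_complete = all(is.finite(ttt)))
  })
  tab <- do.call(rbind, rows)
  # a usable rate must be stable and learn reliably on every calibration run
  ok <- tab$stable & tab$all_complete & is.finite(tab$median_ttt) &
    tab$median_ttt <= max_ttt
  if (!any(ok))
    stop("no stable learning rate completed within ", max_ttt, " trials")
  sel <- tab$lr[ok][which.max(tab$median_ttt[ok])]
  list(lr = sel, table = tab)
}

#' In-silico photostimulation of a model network
#'
#' Clamps each stimulated neuron in turn to `h_pert` for the stimulation
#' duration and measures every other neuron's activity change (mean during
#' the clamp minus mean over the preceding window), averaged across repeats.
#' The network is first allowed to settle; noise enters through the input
#' layer during stimulation (plus the usual hidden noise). Repeats of all
#' stimulated neurons are batched as independent trajectory columns. With a
#' single stimulated neuron per group, every other neuron is a non-target.
#'
#' @param model An [rnn_model()].
#' @param neurons Neurons to stimulate (default: all).
#' @param h_pert Clamp value (default from config).
#' @param repeats Repeats per neuron (default from config).
#' @param settle_s,before_s,during_s Settle, baseline and clamp durations (s).
#' @param during_skip_s Initial portion of the clamp excluded from the
#'   during-average (default 0: the whole clamp counts, as in the
#'   before-versus-during definition; set > 0 to measure the settled
#'   response only).
#' @param seed Integer seed.
#' @return An n x length(neurons) matrix of PS responses; entry [i, g] is
#'   neuron i's response to stimulating neuron `neurons[g]` (the clamped
#'   neuron's own row entry is its direct response).
#' @export
insilico_photostim <- function(model, neurons = seq_len(model$cfg$n),
                               h_pert = model$cfg$h_pert,
                               repeats = model$cfg$ps_repeats,
                               settle_s = 1, before_s = 1, during_s = 1,
                               during_skip_s = 0, seed = 1) {
  cfg <- model$cfg
  if (any(neurons < 1 | neurons > cfg$n)) stop("stimulated neuron out of range")
  set.seed(seed)
  n <- cfg$n; a <- cfg$dt / cfg$tau
  ph <- phi_fun(cfg$nonlinearity)
  B <- length(neurons) * repeats
  col_g <- rep(seq_along(neurons), each = repeats)
  clamp_idx <- cbind(neurons[col_g], seq_len(B))
  Ts <- round(settle_s / cfg$dt); Tb <- round(before_s / cfg$dt)
  Td <- round(during_s / cfg$dt); Tskip <- round(during_skip_s / cfg$dt)
  if (Tskip >= Td) stop("during_skip_s must be smaller than during_s")
  H <- matrix(0, n, B)
  up <- !is.null(model$W_rec_up)
  if (up) G <- matrix(0, cfg$upstream_n, B)
  acc_before <- acc_during <- matrix(0, n, B)
  step_batch <- function(clamped) {
    X <- matrix(stats::rnorm(cfg$d * B, 0, cfg$ps_input_noise), cfg$d, B)
    if (!is.null(model$W_csc)) X <- ph$f(model$W_csc %*% H + X)
    if (up) {
      G <<- G + a * (-G + ph$f(model$W_rec_up %*% G + model$W_inp_g %*% X))
      drive <- model$W_inp_up %*% G
    } else {
      drive <- model$W_inp %*% X
    }
    U <- model$a_exc * (model$W_rec %*% H + drive)
    H <- H + a * (-H + ph$f(U) +
                    matrix(stats::rnorm(n * B, 0, cfg$noise_scale), n, B))
    if (clamped) H[clamp_idx] <- h_pert
    H <<- H
  }
  for (t in seq_len(Ts)) step_batch(FALSE)
  for (t in seq_len(Tb)) { step_batch(FALSE); acc_before <- acc_before + H }
  for (t in seq_len(Td)) {
    step_batch(TRUE)
    if (t > Tskip) acc_during <- acc_during + H
  }
  resp <- acc_during / (Td - Tskip) - acc_before / Tb
  # average repeats per stimulated neuron
  out <- matrix(0, n, length(neurons))
  for (g in seq_along(neurons))
    out[, g] <- rowMeans(resp[, col_g == g, drop = FALSE])
  out
}

## correlation matrix of hidden activity pooled over stabilization trials
stab_correlations <- function(stab_trials) {
  H <- do.call(cbind, lapply(stab_trials, function(s) s$H))
  suppressWarnings(stats::cor(t(H)))
}

#' Correlation-versus-connectivity analysis of trained model networks
#'
#' For one or several trained networks (e.g. seeds of the same plasticity
#' locus), measures in-silico photostimulation maps before and after
#' training, computes pairwise activity correlations from the stabilization
#' periods, and pools all ordered (non-target, stimulated) pairs into
#' one-sided positive Wald tests of (i) correlation predicting causal
#' connectivity before learning and (ii) correlation change predicting
#' connectivity change. No control regressor is needed: every stimulated
#' neuron receives the same direct drive.
#'
#' @param trainings A single `rnn_training` or a list of them.
#' @param seed Base seed for the photostimulation noise.
#' @param ... Passed to [insilico_photostim()].
#' @return List with Wald results `corr_W` and `dcorr_dW`, the number of
#'   pooled pairs, and the per-network data frame `pairs`.
#' @export
model_connectivity_analysis <- function(trainings, seed = 1, ...) {
  if (inherits(trainings, "rnn_training")) trainings <- list(trainings)
  pairs <- lapply(seq_along(trainings), function(k) {
    tr <- trainings[[k]]
    W0 <- insilico_photostim(tr$model_init, seed = seed + 2L * k, ...)
    W1 <- insilico_photostim(tr$model, seed = seed + 2L * k + 1L, ...)
    C0 <- stab_correlations(tr$stab_before)
    C1 <- stab_correlations(tr$stab_after)
    off <- which(row(W0) != col(W0))
    data.frame(net = k, W = W0[off], dW = (W1 - W0)[off],
               C = C0[off], dC = (C1 - C0)[off])
  })
  pairs <- do.call(rbind, pairs)
  list(corr_W = wald_positive_test(pairs$W, pairs$C),
       dcorr_dW = wald_positive_test(pairs$dW, pairs$dC),
       n_pairs = nrow(pairs), pairs = pairs)
}

#' Relative size of loop feedback versus task input
#'
#' For networks with hidden-to-input loop connections, the ratio of the
#' summed norms of the loop contribution `W_csc h_t` to the summed norms of
#' the unmodified task inputs over a trajectory. Zero when the loop is
#' absent.
#'
#' @param model An [rnn_model()] with `W_csc` (or without, giving 0).
#' @param H Hidden trajectory, n x T.
#' @param X_task Task-input trajectory, d x T.
#' @return The scalar ratio.
#' @export
loop_input_ratio <- function(model, H, X_task) {
  denom <- sum(sqrt(colSums(X_task^2)))
  if (denom == 0) stop("task input has zero norm")
  if (is.null(model$W_csc)) return(0)
  sum(sqrt(colSums((model$W_csc %*% H)^2))) / denom
}
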