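#' Synthetic circuit configuration
#'
#' Ground-truth parameters of the simulated motor-cortex field of view:
#' neuron count and positions in a square FoV, a distance-dependent
#' connectivity kernel (excitatory within the excitation radius, weakly
#' inhibitory beyond, mirroring measured photostimulation response profiles),
#' task-epoch drive assignments that tile the trial, and tuning-coupled
#' weight structure (stronger output from pretrial-tuned neurons;
#' like-to-like coupling among reward-tuned neurons) that the regression
#' stage should recover.
#'
#' @param n_neurons Number of neurons (a typical FoV holds ~480).
#' @param fov_um Side of the square field of view (μm).
#' @param excitation_radius Distance (μm) at which the mean connection
#'   weight changes sign (default 60).
#' @param sigma_e,sigma_i Gaussian length scales (μm) of the excitatory and
#'   inhibitory kernel components.
#' @param pos_amp Peak amplitude of the excitatory kernel component.
#' @param weight_jitter SD of multiplicative weight variability.
#' @param coupling_pre Added output weight per unit of (centered) pretrial
#'   tuning of the presynaptic neuron.
#' @param coupling_rew Like-to-like weight coupling per unit product of
#'   (centered) reward tunings.
#' @param epoch_probs Probabilities of the five drive assignments
#'   (pretrial, early, late, reward, untuned).
#' @param amp_mean,amp_sd Lognormal parameters of per-neuron drive
#'   amplitudes (ΔF/F units).
#' @return An object of class `circuit_config`.
#' @export
circuit_config <- function(n_neurons = 480, fov_um = 1000,
                           excitation_radius = 60, sigma_e = 30,
                           sigma_i = 55, pos_amp = 0.15,
                           weight_jitter = 0.5, coupling_pre = 0.04,
                           coupling_rew = 0.04,
                           epoch_probs = c(pretrial = 0.2, early = 0.2,
                                           late = 0.2, reward = 0.2,
                                           untuned = 0.2),
                           amp_mean = 0.3, amp_sd = 0.4) {
  stopifnot(n_neurons >= 10, fov_um > 0, sigma_e > 0, sigma_i > sigma_e,
            abs(sum(epoch_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "circuit_config")
}

#' Sample a ground-truth synthetic circuit
#'
#' Draws neuron positions uniformly in the FoV, assigns each neuron a task
#' epoch drive (or none) with a drive amplitude, chooses a late-tuned
#' conditioned neuron, and builds the true weight matrix
#' `W[i, j]` (influence of j on i) as a difference-of-Gaussians distance
#' kernel whose mean crosses zero at `excitation_radius`, multiplied by
#' positive jitter, plus centered tuning-coupled terms.
#'
#' @param cfg A [circuit_config()].
#' @param seed Integer seed; the circuit is reproducible from it.
#' @return An object of class `synthetic_circuit` with `positions`,
#'   `w_true`, `epoch` (factor), `amp`, `tuning` (per-neuron drive amplitude
#'   by epoch), `cn`, `cfg`, `seed`.
#' @export
sample_circuit <- function(cfg = circuit_config(), seed = 1) {
  set.seed(seed)
  n <- cfg$n_neurons
  pos <- cbind(stats::runif(n, 0, cfg$fov_um), stats::runif(n, 0, cfg$fov_um))
  epoch <- factor(sample(names(cfg$epoch_probs), n, replace = TRUE,
                         prob = cfg$epoch_probs),
                  levels = names(cfg$epoch_probs))
  amp <- stats::rlnorm(n, log(cfg$amp_mean), cfg$amp_sd)
  tuning <- sapply(c("pretrial", "early", "late", "reward"), function(e)
    ifelse(epoch == e, amp, 0))
  d <- as.matrix(stats::dist(pos))
  r <- cfg$excitation_radius
  # inhibitory amplitude chosen so the kernel changes sign at r
  neg_amp <- cfg$pos_amp * exp(-r^2 / (2 * cfg$sigma_e^2) +
                                 r^2 / (2 * cfg$sigma_i^2))
  kern <- cfg$pos_amp * exp(-d^2 / (2 * cfg$sigma_e^2)) -
    neg_amp * exp(-d^2 / (2 * cfg$sigma_i^2))
  jitter <- matrix(stats::rlnorm(n * n, 0, cfg$weight_jitter), n)
  pre_c <- tuning[, "pretrial"] - mean(tuning[, "pretrial"])
  rew_c <- tuning[, "reward"] - mean(tuning[, "reward"])
  w <- kern * jitter +
    cfg$coupling_pre * matrix(pre_c, n, n, byrow = TRUE) +
    cfg$coupling_rew * outer(rew_c, rew_c)
  diag(w) <- 0
  cn <- which(epoch == "late")[1]
  if (is.na(cn)) cn <- 1L
  structure(list(positions = pos, w_true = w, epoch = epoch, amp = amp,
                 tuning = tuning, cn = cn, cfg = cfg, seed = seed),
            class = "synthetic_circuit")
}

#' @export
print.synthetic_circuit <- function(x, ...) {
  cat(sprintf(
    "Synthetic circuit: %d neurons in %g x %g um, CN = %d (%s-tuned)\n",
    nrow(x$positions), x$cfg$fov_um, x$cfg$fov_um, x$cn,
    as.character(x$epoch[x$cn])))
  invisible(x)
}

#' Sample photostimulation groups over a circuit
#'
#' Draws `n_groups` groups of `group_size` stimulation sites centered on
#' randomly chosen neurons, under the hardware constraint that the maximum
#' pairwise separation within a group stays below `max_sep` (sites are drawn
#' within a disc of radius `max_sep / 2` around a seed neuron). Repeat onset
#' times interleave all groups cyclically with one stimulus every `isi`
#' seconds.
#'
#' @param positions Neurons x 2 coordinate matrix (μm).
#' @param n_groups,group_size Group count and sites per group.
#' @param max_sep Maximum pairwise site separation (μm).
#' @param repeats Repeats per group.
#' @param isi Inter-stimulus interval (s).
#' @param t0 Time of the first stimulus (s).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per group.
#' @return A [photostim_groups()] object; each group's sites are neuron
#'   positions, with the chosen neuron indices in `$site_neurons`.
#' @export
sample_groups <- function(positions, n_groups = 100, group_size = 10,
                          max_sep = 400, repeats = 20, isi = 0.6, t0 = 2,
                          seed = 1, max_tries = 200) {
  set.seed(seed)
  n <- nrow(positions)
  sites <- vector("list", n_groups)
  site_neurons <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      center <- sample.int(n, 1)
      dd <- sqrt((positions[, 1] - positions[center, 1])^2 +
                   (positions[, 2] - positions[center, 2])^2)
      pool <- which(dd < max_sep / 2)
      if (length(pool) < group_size) next
      idx <- sample(pool, group_size)
      if (max(stats::dist(positions[idx, , drop = FALSE])) < max_sep) {
        sites[[g]] <- positions[idx, , drop = FALSE]
        site_neurons[[g]] <- idx
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not sample group ", g, " under the separation ",
                  "constraint after ", max_tries, " tries")
  }
  # interleaved schedule: one full cycle of groups per repeat
  onsets <- lapply(seq_len(n_groups), function(g)
    t0 + isi * (g - 1 + n_groups * (seq_len(repeats) - 1)))
  out <- photostim_groups(sites, onsets, max_sep = max_sep, isi = isi)
  out$site_neurons <- site_neurons
  out
}

#' Simulate a photostimulation block from the ground-truth circuit
#'
#' Generates raw fluorescence traces at 20 Hz in which every stimulus
#' application adds a response over the 400 ms following onset: target
#' neurons (within 20 μm of a site) receive a fixed direct drive, and every
#' other neuron receives the one-step propagated drive `sum_j w_true[i, j]`
#' over the group's targets, with additive Gaussian repeat-to-repeat noise.
#' With `delta_w`, a second-day block is generated from `w_true + delta_w`
#' (paired-days mode is obtained by calling once with and once without).
#'
#' @param circuit A [sample_circuit()] result.
#' @param groups A [sample_groups()] result.
#' @param frame_rate Hz (default 20).
#' @param amp_direct Direct target response (ΔF/F units, default 0.5).
#' @param noise_rep SD of the per-repeat response noise (default 0.1).
#' @param noise_base SD of the baseline fluorescence fluctuations relative
#'   to baseline (default 0.02).
#' @param delta_w Optional true across-day weight change matrix.
#' @param seed Integer seed.
#' @return List with `traces` (raw fluorescence, neurons x frames), the
#'   `masks` from [classify_neurons()], and `expected` (neurons x groups
#'   matrix of noise-free non-target response sizes).
#' @export
simulate_photostim_block <- function(circuit, groups, frame_rate = 20,
                                     amp_direct = 0.5, noise_rep = 0.1,
                                     noise_base = 0.02, delta_w = NULL,
                                     seed = 1) {
  set.seed(seed)
  w <- circuit$w_true
  if (!is.null(delta_w)) w <- w + delta_w
  n <- nrow(w)
  masks <- classify_neurons(circuit$positions, groups)
  t_end <- max(unlist(groups$onsets)) + 1
  n_frames <- ceiling(t_end * frame_rate)
  times <- (seq_len(n_frames) - 1) / frame_rate
  f0 <- stats::runif(n, 80, 120)
  rel <- matrix(stats::rnorm(n * n_frames, 0, noise_base), n)
  expected <- matrix(0, n, groups$n_groups)
  for (g in seq_len(groups$n_groups)) {
    tg <- masks$target[, g]
    propagated <- as.numeric(w[, tg, drop = FALSE] %*% rep(1, sum(tg)))
    resp0 <- ifelse(tg, amp_direct, propagated)
    expected[, g] <- resp0
    for (on in groups$onsets[[g]]) {
      sel <- times > on & times <= on + 0.5
      if (!any(sel)) next
      resp <- resp0 + stats::rnorm(n, 0, noise_rep)
      rel[, sel] <- rel[, sel] + resp
    }
  }
  traces <- f0 * (1 + rel)
  list(traces = traces, masks = masks, expected = expected, f0 = f0)
}

#' Session-generator configuration
#'
#' @param spont_s Spontaneous period before the task (s), used for the BCI
#'   thresholds.
#' @param noise SD of the per-frame drive noise (ΔF/F units).
#' @param amp_cn Peak CN drive amplitude at gain 1 (ΔF/F units).
#' @param tau_cal Calcium decay time constant (s).
#' @param f0_range Range of baseline fluorescence values.
#' @param max_s Hard cap on session duration (s).
#' @param early_s Duration of the early-epoch drive after trial start (s).
#' @param reward_s Duration of the reward-epoch drive (s).
#' @return An object of class `session_config`.
#' @export
session_config <- function(spont_s = 60, noise = 0.05, amp_cn = 0.5,
                           tau_cal = 1, f0_range = c(80, 120), max_s = 900,
                           early_s = 1, reward_s = 3) {
  structure(as.list(environment()), class = "session_config")
}

#' Simulate a closed-loop BCI session from the ground-truth circuit
#'
#' Runs the trial state machine online: epoch-tuned drives are generated
#' frame by frame according to the current trial phase (pretrial-tuned
#' neurons fire during the pre-start delay, early-tuned after the trial
#' start, late-tuned in proportion to port progress, reward-tuned after
#' reward delivery), the CN's late-type drive is scaled by the per-trial
#' learning gain schedule, and its resulting raw fluorescence drives the
#' reward port through the BCI transform. Drives are propagated one step
#' through the true weights, convolved with an exponential calcium kernel,
#' and scaled onto per-neuron baselines. The session ends when the schedule
#' is exhausted.
#'
#' @param circuit A [sample_circuit()] result.
#' @param schedule Per-trial CN gain multipliers (length = trial count); a
#'   rising schedule produces within-session learning.
#' @param cfg A [session_config()].
#' @param bci A [bci_config()].
#' @param seed Integer seed.
#' @return A [session_record()] with the circuit's positions and CN.
#' @export
simulate_session <- function(circuit, schedule = seq(1, 2.2, length.out = 40),
                             cfg = session_config(), bci = bci_config(),
                             seed = 1) {
  set.seed(seed)
  n <- nrow(circuit$positions)
  fr <- bci$frame_rate
  dt <- 1 / fr
  n_trials <- length(schedule)
  lam <- exp(-dt / cfg$tau_cal)
  gain_cal <- 1 - lam     # unit-gain calcium filter
  tun <- circuit$tuning
  is_cn <- seq_len(n) == circuit$cn

  # spontaneous period: baseline noise plus modest CN drive at gain 1
  n_spont <- round(cfg$spont_s * fr)
  max_frames <- n_spont + round(cfg$max_s * fr)
  drive <- matrix(0, n, max_frames)
  cn_cal <- 0
  cn_raw <- numeric(max_frames)
  f0 <- stats::runif(n, cfg$f0_range[1], cfg$f0_range[2])
  w_cn <- circuit$w_true[circuit$cn, ]

  thr <- NULL
  state <- bci_state_init(bci)
  trial_no <- 0L
  last_reward <- -Inf
  trial_starts <- numeric(0); rewards <- numeric(0)
  outcomes <- character(0); durations <- numeric(0)
  port <- numeric(max_frames)
  k_end <- max_frames
  progress <- 0

  for (k in seq_len(max_frames)) {
    t <- (k - 1) * dt
    in_spont <- k <= n_spont
    ph_pre <- ph_early <- ph_rew <- FALSE
    if (!in_spont) {
      ph_pre <- state$mode %in% c("delay", "return")
      ph_early <- state$mode == "trial" &&
        t - state$trial_start <= cfg$early_s
      ph_rew <- t - last_reward <= cfg$reward_s
      progress <- if (state$mode == "trial")
        min(state$disp / bci$reward_distance, 1) else 0
    }
    d_k <- stats::rnorm(n, 0, cfg$noise)
    if (!in_spont) {
      if (ph_pre) d_k <- d_k + tun[, "pretrial"]
      if (ph_early) d_k <- d_k + tun[, "early"]
      if (progress > 0) d_k <- d_k + tun[, "late"] * progress
      if (ph_rew) d_k <- d_k + tun[, "reward"]
    }
    # CN drive: deterministic bursts scaled by the learning gain. The
    # spontaneous period includes one large calibration event that sets the
    # upper threshold well above typical trial bursts, so port speed grows
    # smoothly with the gain schedule.
    g_cn <- if (in_spont || trial_no < 1L) 1 else schedule[trial_no]
    cn_drive <- if (in_spont) {
      cfg$amp_cn * as.numeric(t %% 10 < 0.5) +
        8 * cfg$amp_cn * as.numeric(t >= cfg$spont_s / 2 &
                                      t < cfg$spont_s / 2 + 0.5)
    } else if (state$mode == "trial") {
      # ramps with port progress, so activity peaks just before reward and
      # its amplitude tracks the learning gain
      cfg$amp_cn * g_cn * (0.2 + 0.8 * progress)
    } else 0
    d_k[circuit$cn] <- d_k[circuit$cn] + cn_drive
    drive[, k] <- d_k

    # CN pathway computed online (propagation + calcium + baseline)
    r_cn <- d_k[circuit$cn] + sum(w_cn * d_k) - w_cn[circuit$cn] * d_k[circuit$cn]
    cn_cal <- lam * cn_cal + gain_cal * r_cn
    cn_raw[k] <- f0[circuit$cn] * (1 + cn_cal)

    if (in_spont) {
      if (k == n_spont) {
        thr <- compute_thresholds(cn_raw[seq_len(n_spont)])
        state$mode <- "return"; state$timer <- bci$port_return_time
      }
      next
    }
    st <- bci_state_step(state, cn_raw[k], t, thr, bci)
    state <- st$state
    port[k] <- if (state$mode == "trial") state$disp else 0
    if (identical(st$event, "trial_start_pending")) {
      if (trial_no >= n_trials) { k_end <- k; break }
      trial_no <- trial_no + 1L
      trial_starts <- c(trial_starts, t + dt)
    } else if (identical(st$event, "reward")) {
      rewards <- c(rewards, t); outcomes <- c(outcomes, "hit")
      durations <- c(durations, t - trial_starts[length(trial_starts)])
      last_reward <- t
    } else if (identical(st$event, "miss")) {
      rewards <- c(rewards, NA_real_); outcomes <- c(outcomes, "miss")
      durations <- c(durations, bci$timeout)
    }
  }
  n_done <- length(outcomes)
  if (n_done == 0L) warning("session produced no completed trials")
  drive <- drive[, seq_len(k_end), drop = FALSE]
  rates <- drive + circuit$w_true %*% drive
  cal <- t(apply(rates, 1L, function(x)
    stats::filter(gain_cal * x, lam, method = "recursive")))
  raw <- f0 * (1 + cal)
  raw[circuit$cn, ] <- cn_raw[seq_len(k_end)]
  events <- data.frame(start_s = trial_starts[seq_len(n_done)],
                       reward_s = if (n_done) rewards else numeric(0),
                       outcome = if (n_done) outcomes else character(0),
                       duration_s = if (n_done) durations else numeric(0))
  if (any(outcomes == "miss") && all(outcomes == "miss"))
    warning("all trials missed (silent or untrained CN)")
  session_record(raw = raw, events = events, cn = circuit$cn,
                 positions = circuit$positions, frame_rate = fr,
                 id = sprintf("synthetic-seed%d", seed))
}
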