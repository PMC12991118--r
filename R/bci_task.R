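#' BCI configuration
#'
#' Parameters of the closed-loop optical brain-computer interface: a single
#' conditioned neuron's (CN) raw fluorescence is mapped to an analog voltage,
#' the voltage to a stepping frequency of the motorized reward port, and the
#' port's travel to trial outcomes.
#'
#' @param gain Stepping-frequency gain in steps/s per volt.
#' @param v_max Maximum control voltage in volts.
#' @param step_size Size of one port step in micrometers.
#' @param start_distance Port start position in mm from the mouth.
#' @param reward_distance Travel in mm (from the start position) at which the
#'   reward position is reached.
#' @param timeout Maximum trial duration in seconds.
#' @param fl_dwell Time in seconds the CN must stay below the lower threshold
#'   after a rewarded trial before the intertrial delay starts.
#' @param intertrial_delay Delay in seconds between threshold crossing and the
#'   next trial start.
#' @param port_return_time Dead time in seconds while the port returns to the
#'   start position.
#' @param frame_rate Imaging frame rate in Hz.
#' @param feedback_lag Optional fixed feedback delay in seconds between CN
#'   activity and port movement (default 0).
#'
#' @return An object of class `bci_config`.
#' @export
bci_config <- function(gain = 7.9, v_max = 3.3, step_size = 685,
                       start_distance = 7, reward_distance = 6,
                       timeout = 10, fl_dwell = 0.2, intertrial_delay = 2,
                       port_return_time = 0.3, frame_rate = 20,
                       feedback_lag = 0) {
  cfg <- list(gain = gain, v_max = v_max, step_size = step_size,
              start_distance = start_distance,
              reward_distance = reward_distance, timeout = timeout,
              fl_dwell = fl_dwell, intertrial_delay = intertrial_delay,
              port_return_time = port_return_time, frame_rate = frame_rate,
              feedback_lag = feedback_lag)
  pos <- vapply(cfg[setdiff(names(cfg), "feedback_lag")], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))
  if (!all(pos))
    stop("all bci_config fields must be single positive finite numbers: ",
         paste(names(pos)[!pos], collapse = ", "))
  if (feedback_lag < 0) stop("feedback_lag must be >= 0")
  if (reward_distance > start_distance)
    stop("reward_distance must not exceed start_distance")
  if (fl_dwell >= timeout) stop("fl_dwell must be smaller than timeout")
  structure(cfg, class = "bci_config")
}

#' Compute voltage-map thresholds from a spontaneous period
#'
#' The lower threshold FL is the median and the upper threshold FU the maximum
#' of the CN's raw fluorescence during the spontaneous period immediately
#' preceding the behavioral session. The median of an even-length trace is the
#' mean of the central pair.
#'
#' @param spontaneous_trace Numeric vector of raw fluorescence values.
#' @return An object of class `bci_thresholds` with fields `FL`, `FU` and a
#'   logical `degenerate` flag (`TRUE` when FU == FL, in which case the linear
#'   segment of the voltage map is undefined).
#' @export
compute_thresholds <- function(spontaneous_trace) {
  if (length(spontaneous_trace) == 0L)
    stop("spontaneous trace is empty")
  if (!all(is.finite(spontaneous_trace)))
    stop("spontaneous trace contains non-finite values")
  fl <- stats::median(spontaneous_trace)
  fu <- max(spontaneous_trace)
  structure(list(FL = fl, FU = fu, degenerate = isTRUE(fu == fl)),
            class = "bci_thresholds")
}

#' @export
print.bci_thresholds <- function(x, ...) {
  cat(sprintf("BCI thresholds: FL = %g, FU = %g%s\n", x$FL, x$FU,
              if (x$degenerate) " (degenerate: FU == FL)" else ""))
  invisible(x)
}

#' Control voltage from CN fluorescence
#'
#' Piecewise-linear map from raw CN fluorescence to the analog control
#' voltage: 0 at or below FL, linear between FL and FU, clamped at `v_max`
#' above FU.
#'
#' @param h_cn Raw fluorescence value(s) of the conditioned neuron.
#' @param thr A `bci_thresholds` object (non-degenerate).
#' @param cfg A [bci_config()].
#' @return Voltage(s) in `[0, v_max]`.
#' @export
control_voltage <- function(h_cn, thr, cfg = bci_config()) {
  if (thr$degenerate)
    stop("thresholds are degenerate (FU == FL); voltage map undefined")
  if (!all(is.finite(h_cn))) stop("non-finite CN fluorescence")
  v <- cfg$v_max * (h_cn - thr$FL) / (thr$FU - thr$FL)
  pmin(pmax(v, 0), cfg$v_max)
}

#' Port stepping frequency from control voltage
#'
#' @param v Control voltage(s) in `[0, v_max]`.
#' @param cfg A [bci_config()].
#' @return Stepping frequency in steps/s (`gain * v`).
#' @export
step_frequency <- function(v, cfg = bci_config()) {
  if (any(!is.finite(v)) || any(v < 0) || any(v > cfg$v_max))
    stop("voltage outside [0, v_max]")
  cfg$gain * v
}

## --- trial state machine -------------------------------------------------
##
## Modes: "trial"    port moving, timeout clock running
##        "wait_low" after a hit, CN must sit below FL for fl_dwell
##        "delay"    intertrial delay
##        "return"   port travelling back to the start position
## The same stepper drives run_closed_loop() and the session generator.

bci_state_init <- function(cfg) {
  list(mode = "return", timer = 0, disp = 0, low_run = 0,
       trial_start = NA_real_, stoch = FALSE)
}

## One frame of the state machine. h is the CN raw fluorescence on this
## frame, t its time in seconds. Returns list(state, event, speed_mm_s).
bci_state_step <- function(state, h, t, thr, cfg, stochastic = FALSE) {
  dt <- 1 / cfg$frame_rate
  event <- NA_character_
  speed <- 0
  if (state$mode == "trial") {
    v <- control_voltage(h, thr, cfg)
    f <- step_frequency(v, cfg)
    step_mm <- cfg$step_size / 1000
    d <- if (stochastic) step_mm * stats::rpois(1L, f * dt) else
      step_mm * f * dt
    state$disp <- state$disp + d
    speed <- d / dt
    if (state$disp >= cfg$reward_distance) {
      event <- "reward"
      state$mode <- "wait_low"
      state$low_run <- 0
    } else if (t - state$trial_start + dt / 2 >= cfg$timeout) {
      event <- "miss"
      state$mode <- "return"
      state$timer <- cfg$port_return_time
    }
  } else if (state$mode == "wait_low") {
    state$low_run <- if (h < thr$FL) state$low_run + dt else 0
    if (state$low_run >= cfg$fl_dwell) {
      state$mode <- "delay"
      state$timer <- cfg$intertrial_delay
    }
  } else if (state$mode == "delay") {
    state$timer <- state$timer - dt
    if (state$timer <= 0) {
      state$mode <- "return"
      state$timer <- cfg$port_return_time
    }
  } else if (state$mode == "return") {
    state$timer <- state$timer - dt
    if (state$timer <= 0) {
      state$mode <- "trial"
      state$disp <- 0
      state$trial_start <- t + dt
      event <- "trial_start_pending"
    }
  }
  list(state = state, event = event, speed = speed)
}

#' Run the closed-loop BCI trial state machine over a recorded CN trace
#'
#' Replays a CN raw fluorescence trace through the BCI: the voltage map and
#' stepping-frequency relation convert fluorescence to port speed, trials end
#' in a hit when cumulative port travel reaches `reward_distance` within
#' `timeout` seconds, otherwise in a miss. After a hit the CN must fall below
#' FL for `fl_dwell` s, followed by the intertrial delay and the port-return
#' dead time, before the next trial starts. Port motion integrates the
#' expected displacement `step_size * f_step * dt` per frame; set
#' `stochastic = TRUE` to sample discrete Poisson step events instead.
#'
#' @param cn_trace Raw fluorescence trace of the CN, sampled at
#'   `cfg$frame_rate`.
#' @param thr A `bci_thresholds` object.
#' @param cfg A [bci_config()].
#' @param stochastic Sample discrete step events instead of integrating the
#'   expected displacement.
#' @return A list of class `bci_run` with `events` (data.frame with columns
#'   `start_s`, `reward_s` (NA on miss), `outcome`, `duration_s`) and `port`
#'   (per-frame cumulative port displacement in mm within the current trial).
#' @export
run_closed_loop <- function(cn_trace, thr, cfg = bci_config(),
                            stochastic = FALSE) {
  dt <- 1 / cfg$frame_rate
  n <- length(cn_trace)
  lag_frames <- round(cfg$feedback_lag * cfg$frame_rate)
  if (n < 2L) {
    warning("trace shorter than one trial-start preamble; no trials run")
    return(structure(list(
      events = data.frame(start_s = numeric(0), reward_s = numeric(0),
                          outcome = character(0), duration_s = numeric(0)),
      port = numeric(0)), class = "bci_run"))
  }
  state <- bci_state_init(cfg)
  state$mode <- "trial"; state$trial_start <- 0
  starts <- 0; rewards <- numeric(0); outcomes <- character(0)
  durations <- numeric(0); port <- numeric(n)
  for (k in seq_len(n)) {
    t <- (k - 1L) * dt
    h <- cn_trace[max(1L, k - lag_frames)]
    st <- bci_state_step(state, h, t, thr, cfg, stochastic)
    state <- st$state
    port[k] <- if (state$mode == "trial") state$disp else 0
    if (identical(st$event, "reward")) {
      rewards <- c(rewards, t)
      outcomes <- c(outcomes, "hit")
      durations <- c(durations, t - starts[length(starts)])
    } else if (identical(st$event, "miss")) {
      rewards <- c(rewards, NA_real_)
      outcomes <- c(outcomes, "miss")
      durations <- c(durations, cfg$timeout)
    } else if (identical(st$event, "trial_start_pending")) {
      starts <- c(starts, t + dt)
    }
  }
  n_done <- length(outcomes)
  events <- data.frame(start_s = starts[seq_len(n_done)],
                       reward_s = if (n_done) rewards else numeric(0),
                       outcome = if (n_done) outcomes else character(0),
                       duration_s = if (n_done) durations else numeric(0))
  structure(list(events = events, port = port), class = "bci_run")
}

#' @export
print.bci_run <- function(x, ...) {
  ev <- x$events
  cat(sprintf("BCI run: %d trials (%d hits, %d misses)\n", nrow(ev),
              sum(ev$outcome == "hit"), sum(ev$outcome == "miss")))
  invisible(x)
}

#' Write trial events to CSV
#'
#' One row per trial with columns `start_s`, `reward_s` (NA for misses),
#' `outcome` and `duration_s`.
#'
#' @param run A `bci_run` object (or its `events` data.frame).
#' @param path Output file path.
#' @export
write_trial_events <- function(run, path) {
  ev <- if (inherits(run, "bci_run")) run$events else run
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}
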