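#' Assemble a BCI session record
#'
#' The common currency of the analysis stages: per-neuron fluorescence traces
#' at the imaging frame rate, the trial-event table, the conditioned-neuron
#' index, and neuron coordinates. ΔF/F is derived from the raw traces as
#' `(F - F0) / F0` with F0 the per-neuron median fluorescence across the
#' session.
#'
#' @param raw Numeric matrix of raw fluorescence, neurons x frames.
#' @param events Trial-event data.frame with columns `start_s`, `reward_s`,
#'   `outcome`, `duration_s` (as produced by [run_closed_loop()]).
#' @param cn Index of the conditioned neuron.
#' @param positions Optional neurons x 2 matrix of coordinates in micrometers.
#' @param frame_rate Imaging frame rate in Hz (default 20).
#' @param id Optional session identifier.
#' @param dff Optional pre-computed ΔF/F matrix; derived from `raw` if absent.
#' @return An object of class `session_record` with elements `raw`, `dff`,
#'   `events`, `cn`, `positions`, `frame_rate`, `id`.
#' @export
session_record <- function(raw, events, cn, positions = NULL,
                           frame_rate = 20, id = "session", dff = NULL) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop("raw traces must be a finite numeric matrix (neurons x frames)")
  req <- c("start_s", "reward_s", "outcome", "duration_s")
  if (!all(req %in% names(events)))
    stop("events must have columns ", paste(req, collapse = ", "))
  if (cn < 1 || cn > nrow(raw)) stop("cn index out of range")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(raw) || ncol(positions) != 2L)
      stop("positions must be a neurons x 2 matrix")
  }
  if (is.null(dff)) {
    f0 <- apply(raw, 1L, stats::median)
    if (any(f0 <= 0)) stop("non-positive median fluorescence; cannot form dF/F")
    dff <- sweep(sweep(raw, 1L, f0, "-"), 1L, f0, "/")
  }
  structure(list(raw = raw, dff = dff, events = as.data.frame(events),
                 cn = as.integer(cn), positions = positions,
                 frame_rate = frame_rate, id = id),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "Session '%s': %d neurons x %d frames @ %g Hz, %d trials (%d hits), CN = %d\n",
    x$id, nrow(x$raw), ncol(x$raw), x$frame_rate, nrow(x$events),
    sum(x$events$outcome == "hit"), x$cn))
  invisible(x)
}

## frame timestamps (s); frame k is acquired at (k-1)/frame_rate
session_times <- function(session) {
  (seq_len(ncol(session$raw)) - 1L) / session$frame_rate
}
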