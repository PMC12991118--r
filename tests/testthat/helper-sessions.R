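## Test helpers: small hand-built session records.

## Build a session from an explicit dF/F matrix and event table. Raw traces
## are a positive affine image of dff so that dF/F-based code paths work.
toy_session <- function(dff, events, cn = 1L, frame_rate = 20,
                        positions = NULL, id = "toy") {
  dff <- as.matrix(dff)
  session_record(raw = 100 * (1 + dff), events = events, cn = cn,
                 positions = positions, frame_rate = frame_rate, id = id,
                 dff = dff)
}

## Event table helper
trial_events <- function(start_s, reward_s, timeout = 10) {
  outcome <- ifelse(is.na(reward_s), "miss", "hit")
  data.frame(start_s = start_s, reward_s = reward_s, outcome = outcome,
             duration_s = ifelse(is.na(reward_s), timeout,
                                 reward_s - start_s))
}
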