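# Independent oracles used by the tests; these re-derive expected values
# from first principles and must stay independent of the package internals.

# Closed-form current response of the lumped R-C electrode model to the
# square-wave stimulus: resistive plateau V(t)/R plus, after every edge of
# size dV, a transient (dV/R) exp(-(t - t_edge)/(R C)).
oracle_rc_trace <- function(stim, r_mohm, c_pf) {
  n <- round(stim$duration_s * stim$sample_rate_hz)
  t <- (seq_len(n) - 1) / stim$sample_rate_hz
  phase <- (t * stim$frequency_hz) %% 1
  v <- stim$dc_offset_mv +
    (stim$peak_to_peak_mv / 2) * ifelse(phase < 0.5, 1, -1)
  i <- v / r_mohm * 1000
  if (c_pf > 0) {
    tau <- r_mohm * c_pf * 1e-6
    half <- 1 / (2 * stim$frequency_hz)
    k <- 0
    while (k * half < stim$duration_s) {
      dv <- stim$peak_to_peak_mv * (-1)^k
      sel <- t >= k * half
      i[sel] <- i[sel] + dv / r_mohm * 1000 * exp(-(t[sel] - k * half) / tau)
      k <- k + 1
    }
  }
  i
}

# Brute-force evaluation of the contact-detection rule, written as a literal
# walk over the last three step changes.
oracle_detect <- function(history, threshold = 0.25, tol = 0.01) {
  if (length(history) < 4) return(FALSE)
  h <- history[(length(history) - 3):length(history)]
  rise <- 0
  for (k in 2:4) {
    d <- h[k] - h[k - 1]
    if (d <= -tol) return(FALSE)
    rise <- rise + d
  }
  rise > threshold
}

# Pool per-pipette rows over a list of trial records.
pipette_rows <- function(records) {
  do.call(rbind, lapply(records, function(r) r$pipettes))
}

# Gigasealing intervals per pipette from a trial's event log.
seal_intervals <- function(events) {
  starts <- events[events$event == "SEAL_START", ]
  ends <- events[events$event %in% c("SEAL_OK", "SEAL_FAIL", "SEAL_ABORTED"), ]
  if (!nrow(starts)) {
    return(data.frame(pipette = integer(0), from = numeric(0),
                      to = numeric(0)))
  }
  do.call(rbind, lapply(seq_len(nrow(starts)), function(k) {
    p <- starts$pipette[k]
    e <- ends[ends$pipette == p & ends$t >= starts$t[k], ]
    data.frame(pipette = p, from = starts$t[k], to = min(e$t))
  }))
}
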