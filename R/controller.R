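#' Pneumatic set points
#'
#' The discrete pressure states applied to the pipette interior, in mBar:
#' high positive +800 (descent), low positive +25 (localization and
#' hunting), atmospheric 0, low suction -15 (gigasealing), high suction
#' -300 (break-in pulses).
#'
#' @return Named numeric vector of set points in mBar.
#' @export
pressure_set_points <- function() {
  c(HIGH_POSITIVE = 800, LOW_POSITIVE = 25, ATMOSPHERIC = 0,
    LOW_SUCTION = -15, HIGH_SUCTION = -300)
}

#' Pipette phases and the legal transition graph
#'
#' @return Named list mapping each phase to the phases it may legally
#'   transition to. Phases absent from the list are terminal.
#' @export
phase_transitions <- function() {
  list(
    INSTALLED = c("QC_FAILED", "LOCALIZING"),
    LOCALIZING = c("DEACTIVATED_CLOGGED", "HUNTING"),
    HUNTING = c("HALTED", "GIGASEALING", "LOST"),
    HALTED = c("HUNTING", "GIGASEALING", "LOST"),
    GIGASEALING = c("GIGASEALED_HELD", "SEAL_FAILED"),
    GIGASEALED_HELD = c("BREAKING_IN", "LOST"),
    BREAKING_IN = c("WHOLE_CELL", "GIGASEALED_HELD")
  )
}

#' The timed gigasealing pressure/voltage program
#'
#' Six ordered steps totalling 60 s: (1) hold low positive pressure for 10 s
#' to confirm contact; (2) atmospheric for 5 s; (3) low suction for 10 s to
#' form the seal; (4) return to atmospheric and switch the holding potential
#' to -35 mV (instantaneous); (5) ramp the holding potential linearly from
#' -35 to -70 mV over 30 s; (6) hold 5 s.
#'
#' @return A data frame of class `gigaseal_schedule` with columns `step`,
#'   `pressure`, `duration_s`, `voltage_start_mv`, `voltage_end_mv`.
#' @export
#' @examples
#' sum(gigaseal_schedule()$duration_s)  # 60
gigaseal_schedule <- function() {
  sched <- data.frame(
    step = 1:6,
    pressure = c("LOW_POSITIVE", "ATMOSPHERIC", "LOW_SUCTION",
                 "ATMOSPHERIC", "ATMOSPHERIC", "ATMOSPHERIC"),
    duration_s = c(10, 5, 10, 0, 30, 5),
    voltage_start_mv = c(0, 0, 0, -35, -35, -70),
    voltage_end_mv = c(0, 0, 0, -35, -70, -70),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("gigaseal_schedule", "data.frame")
  sched
}

#' Total duration of a gigasealing schedule, seconds
#'
#' @param schedule A [gigaseal_schedule()].
#' @return Total duration in seconds (60 for the default program).
#' @export
schedule_duration <- function(schedule = gigaseal_schedule()) {
  sum(schedule$duration_s)
}

#' Holding voltage at a given schedule time
#'
#' @param schedule A [gigaseal_schedule()].
#' @param t Time since schedule start, seconds (vectorized).
#' @return Holding voltage in mV (piecewise linear; non-increasing after the
#'   switch to -35 mV).
#' @export
schedule_voltage_at <- function(schedule = gigaseal_schedule(), t) {
  ends <- cumsum(schedule$duration_s)
  starts <- ends - schedule$duration_s
  vapply(t, function(tt) {
    tt <- min(max(tt, 0), ends[length(ends)])
    seg <- which(tt <= ends & schedule$duration_s > 0)[1]
    if (is.na(seg)) seg <- nrow(schedule)
    d <- schedule$duration_s[seg]
    frac <- if (d > 0) (tt - starts[seg]) / d else 1
    schedule$voltage_start_mv[seg] +
      frac * (schedule$voltage_end_mv[seg] - schedule$voltage_start_mv[seg])
  }, numeric(1))
}

#' Pneumatic state at a given schedule time
#'
#' @param schedule A [gigaseal_schedule()].
#' @param t Time since schedule start, seconds (vectorized).
#' @return Pressure state labels.
#' @export
schedule_pressure_at <- function(schedule = gigaseal_schedule(), t) {
  ends <- cumsum(schedule$duration_s)
  vapply(t, function(tt) {
    tt <- min(max(tt, 0), ends[length(ends)])
    seg <- which(tt <= ends & schedule$duration_s > 0)[1]
    if (is.na(seg)) seg <- nrow(schedule)
    schedule$pressure[seg]
  }, character(1))
}

#' Pipette quality-control check
#'
#' A pipette is acceptable iff its bath resistance lies in the inclusive
#' 3-9 MOhm range; failing pipettes take no further part in the trial.
#'
#' @param measured_r_mohm Measured bath resistance, MOhm (vectorized).
#' @param range_mohm Acceptance range, inclusive.
#' @return Logical: pass?
#' @export
qc_check <- function(measured_r_mohm, range_mohm = c(3, 9)) {
  measured_r_mohm >= range_mohm[1] & measured_r_mohm <= range_mohm[2]
}

#' Regional localization clog check
#'
#' After descent to depth (under low positive pressure), a pipette whose
#' resistance has risen by strictly more than 0.35 MOhm relative to its
#' surface reading is deemed blocked or fouled: it is depressurized to
#' atmospheric and its actuator deactivated.
#'
#' @param surface_r_mohm Resistance measured outside the brain, MOhm.
#' @param depth_r_mohm Resistance measured at target depth, MOhm.
#' @param threshold_mohm Clog-detection threshold, MOhm (strict).
#' @return Logical: keep the pipette? (`FALSE` means deactivate.)
#' @export
regional_localization <- function(surface_r_mohm, depth_r_mohm,
                                  threshold_mohm = 0.35) {
  (depth_r_mohm - surface_r_mohm) <= threshold_mohm
}

#' Neuron contact detector
#'
#' Fires iff the last three step-to-step changes of the averaged resistance
#' are all non-decreasing (each change must exceed `-monotone_tol_mohm`, a
#' small tolerance absorbing measurement noise) and their cumulative rise
#' strictly exceeds `threshold_mohm` (0.25 MOhm over three actuation steps).
#'
#' @param history Numeric vector of averaged resistance readings, MOhm; the
#'   last four are used. Fewer than four readings simply yields `FALSE`.
#' @param threshold_mohm Cumulative rise threshold over three steps (strict).
#' @param monotone_tol_mohm Noise tolerance on per-step monotonicity.
#' @return Logical: contact detected?
#' @export
#' @examples
#' detect_neuron(c(5.00, 5.10, 5.20, 5.30))  # TRUE
#' detect_neuron(c(5.00, 5.30, 5.20, 5.60))  # FALSE (non-monotone)
detect_neuron <- function(history, threshold_mohm = 0.25,
                          monotone_tol_mohm = 0.01) {
  if (length(history) < 4L) return(FALSE)
  h <- utils::tail(history, 4L)
  d <- diff(h)
  all(d > -monotone_tol_mohm) && sum(d) > threshold_mohm
}

#' Execute the gigasealing schedule on one pipette
#'
#' Runs the timed pressure/voltage program against the rig. The outcome is
#' `"SEAL_OK"` iff the final seal resistance is >= 1000 MOhm. With
#' `abort_policy = TRUE` the attempt is terminated early (`"SEAL_ABORTED"`)
#' when the resistance rise at the `abort_at_s` checkpoint (35 s) is below
#' `abort_min_delta_mohm` (100 MOhm), mirroring the manual override. On
#' completion the pipette's motor is deactivated for the rest of the trial.
#'
#' @param rig A [new_rig()] environment.
#' @param i Pipette index; must be in contact and stationary.
#' @param schedule A [gigaseal_schedule()].
#' @param waiting_min Minutes the contact was held before this attempt.
#' @param abort_policy Auto-abort failing attempts at the checkpoint?
#' @param abort_at_s Abort checkpoint, seconds into the schedule.
#' @param abort_min_delta_mohm Minimum resistance rise at the checkpoint.
#' @return List with `outcome` (`"SEAL_OK"`, `"SEAL_FAIL"` or
#'   `"SEAL_ABORTED"`), `elapsed_s`, `final_r_mohm` and
#'   `delta_at_check_mohm`.
#' @export
run_gigaseal_schedule <- function(rig, i, schedule = gigaseal_schedule(),
                                  waiting_min = 0, abort_policy = FALSE,
                                  abort_at_s = 35,
                                  abort_min_delta_mohm = 100) {
  i <- check_pipette_index(rig, i)
  start_gigaseal_attempt(rig, i, waiting_min = waiting_min)
  r0 <- rig$seal_r0[i]
  ends <- cumsum(schedule$duration_s)
  starts <- ends - schedule$duration_s
  elapsed <- 0
  delta_at_check <- NA_real_
  for (seg in seq_len(nrow(schedule))) {
    d <- schedule$duration_s[seg]
    if (d <= 0) next
    # the growth boost is decided by the most hyperpolarized holding level
    # reached in the segment (the ramp spends the segment at <= -35 mV)
    holding <- min(schedule$voltage_start_mv[seg], schedule$voltage_end_mv[seg])
    pres <- schedule$pressure[seg]
    seg_start <- starts[seg]
    if (abort_policy && is.na(delta_at_check) &&
        seg_start < abort_at_s && abort_at_s <= seg_start + d) {
      d1 <- abort_at_s - seg_start
      r_now <- gigaseal_step(rig, i, d1, pressure = pres, holding_mv = holding)
      elapsed <- elapsed + d1
      delta_at_check <- r_now - r0
      if (delta_at_check < abort_min_delta_mohm) {
        set_pressure(rig, i, "ATMOSPHERIC")
        return(list(outcome = "SEAL_ABORTED", elapsed_s = elapsed,
                    final_r_mohm = r_now,
                    delta_at_check_mohm = delta_at_check))
      }
      d <- d - d1
      if (d <= 0) next
    }
    r_now <- gigaseal_step(rig, i, d, pressure = pres, holding_mv = holding)
    elapsed <- elapsed + d
  }
  final_r <- rig$seal_r[i]
  list(
    outcome = if (final_r >= 1000) "SEAL_OK" else "SEAL_FAIL",
    elapsed_s = elapsed,
    final_r_mohm = final_r,
    delta_at_check_mohm = delta_at_check
  )
}

# --- trial machinery -------------------------------------------------------

new_event_log <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- numeric(0); e$pipette <- integer(0)
  e$event <- character(0); e$detail <- character(0)
  e
}

log_event <- function(log, t, pipette, event, detail = "") {
  k <- length(log$t) + 1L
  log$t[k] <- t; log$pipette[k] <- as.integer(pipette)
  log$event[k] <- event; log$detail[k] <- detail
  invisible(log)
}

events_df <- function(log) {
  data.frame(t = log$t, pipette = log$pipette, event = log$event,
             detail = log$detail, stringsAsFactors = FALSE)
}

make_transitioner <- function(n) {
  env <- new.env(parent = emptyenv())
  env$phase <- rep("INSTALLED", n)
  env$log <- character(0)
  graph <- phase_transitions()
  env$to <- function(i, new_phase) {
    from <- env$phase[i]
    allowed <- graph[[from]]
    if (is.null(allowed) || !(new_phase %in% allowed)) {
      abort_protocol(sprintf("illegal phase transition %s -> %s (pipette %d)",
                             from, new_phase, i))
    }
    env$log <- c(env$log, paste0(from, "->", new_phase))
    env$phase[i] <- new_phase
  }
  env
}

averaged_measure <- function(rig, i) {
  averaged_resistance(vapply(1:5, function(k) rig_measure(rig, i), numeric(1)))
}

# Draw the own-step index at which each hunter's detector fires: the neuron
# encounter is geometric on steps (or prescribed), detection fires three
# ramp steps later.
draw_detection_steps <- function(rig, hunters, budget_steps) {
  ts <- rig$tissue
  det <- rep(Inf, rig$n)
  for (i in hunters) {
    enc <- if (!is.null(ts$deterministic_encounter_steps)) {
      ts$deterministic_encounter_steps[i]
    } else {
      stats::rgeom(1, ts$encounter_hazard_per_step) + 1L
    }
    d <- enc + 3L
    det[i] <- if (d <= budget_steps) d else Inf
  }
  det
}

mark_contact <- function(rig, i) {
  rig$contact[i] <- "contacting"
  rig$ramp_steps_done[i] <- rig$tissue$contact_ramp_steps
}

#' Run one multipatching trial
#'
#' Executes the full control algorithm for one trial against a virtual rig:
#' quality control, descent under high positive pressure, regional
#' localization with clog deactivation, then the variant-specific
#' coordination of neuron hunting, gigasealing and break-in.
#'
#' Variants:
#' \describe{
#'   \item{`sync_all`}{Pipettes hunt independently; each detection
#'     deactivates that motor while the rest continue. When every pipette
#'     has stopped, gigasealing runs simultaneously in all of them, then
#'     break-in synchronously. Held contacts are exposed to dislodgement by
#'     the other pipettes' movement, and their seal success decays with
#'     waiting time.}
#'   \item{`retract_replay`}{As `sync_all`, but each detection retracts the
#'     pipette 30 um and holds. When all are done, every pipette advances
#'     30 um simultaneously (contact is re-established with probability
#'     `replay_recontact_prob`), then synchronous gigasealing and break-in.}
#'   \item{`interleaved`}{All pipettes step together; on any detection all
#'     are halted, the detecting pipette alone runs the gigasealing
#'     schedule, then the rest resume. Repeats until every pipette has
#'     attempted; break-in is simultaneous on all held gigaseals.
#'     Gigasealed pipettes are immune to motion artifacts.}
#' }
#'
#' @param variant One of `"sync_all"`, `"retract_replay"`, `"interleaved"`.
#' @param n_pipettes Number of installed pipettes.
#' @param depths_um Target depths in um (recycled to `n_pipettes`).
#' @param tissue A [tissue_model()].
#' @param pipettes A [pipette_spec()] or list of one per pipette.
#' @param seed Optional seed; `NULL` consumes the ambient RNG stream (as
#'   [run_campaign()] does).
#' @param step_measure_s Wall time of one advance-and-measure hunting step.
#' @param max_hunt_travel_um Hunting travel budget past the start depth; a
#'   pipette that exhausts it without contact is deactivated.
#' @param retract_um Retraction distance for `retract_replay`, um.
#' @param abort_policy Auto-abort failing interleaved gigaseal attempts at
#'   35 s (< 100 MOhm rise)?
#' @param breakin_delay_s Delay between the last gigaseal attempt and the
#'   operator-commanded break-in.
#' @return An object of class `trial_record`: per-pipette outcomes,
#'   timings, the controller event log and the phase-transition trace.
#' @export
#' @examples
#' rec <- run_trial("interleaved", seed = 1)
#' rec$pipettes[, c("detected", "sealed", "whole_cell")]
run_trial <- function(variant = c("interleaved", "sync_all", "retract_replay"),
                      n_pipettes = 4,
                      depths_um = 400,
                      tissue = tissue_model(),
                      pipettes = pipette_spec(),
                      seed = NULL,
                      step_measure_s = 0.5,
                      max_hunt_travel_um = 3000,
                      retract_um = 30,
                      abort_policy = FALSE,
                      breakin_delay_s = 0) {
  variant <- match.arg(variant)
  with_seed(seed, {
    depths_um <- rep_len(depths_um, n_pipettes)
    rig <- new_rig(n_pipettes, tissue, pipettes)
    log <- new_event_log()
    tr <- make_transitioner(n_pipettes)
    n <- n_pipettes
    t <- 0

    qc <- logical(n); surface_r <- rep(NA_real_, n)
    detected <- logical(n); sealed <- logical(n); whole_cell <- logical(n)
    dislodged <- logical(n); exhausted <- logical(n)
    lost_waiting <- logical(n); seal_wait_min <- rep(NA_real_, n)
    seal_s_total <- 0

    # --- QC in the bath ----------------------------------------------------
    for (i in seq_len(n)) {
      surface_r[i] <- averaged_measure(rig, i)
      qc[i] <- qc_check(surface_r[i])
      if (qc[i]) {
        tr$to(i, "LOCALIZING")
        log_event(log, t, i, "QC_PASS",
                  sprintf("R=%.2f MOhm", surface_r[i]))
      } else {
        tr$to(i, "QC_FAILED")
      }
    }
    installed <- which(qc)

    # --- descent (simultaneous) and regional localization ------------------
    descent_s <- 0
    if (length(installed)) {
      for (i in installed) set_pressure(rig, i, "HIGH_POSITIVE")
      for (i in installed) descend_to_depth(rig, i, depths_um[i])
      descent_s <- max(depths_um[installed]) / 200
      t <- t + descent_s
      for (i in installed) set_pressure(rig, i, "LOW_POSITIVE")
      t <- t + step_measure_s  # one synchronized depth measurement
      for (i in installed) {
        depth_r <- averaged_measure(rig, i)
        if (regional_localization(surface_r[i], depth_r)) {
          tr$to(i, "HUNTING")
        } else {
          tr$to(i, "DEACTIVATED_CLOGGED")
          set_pressure(rig, i, "ATMOSPHERIC")
          log_event(log, t, i, "CLOG_DEACTIVATED",
                    sprintf("dR=%.2f MOhm", depth_r - surface_r[i]))
        }
      }
    }
    rig$clock_s <- t
    hunters <- which(tr$phase == "HUNTING")
    budget_steps <- floor(max_hunt_travel_um / 2)
    detect_at <- draw_detection_steps(rig, hunters, budget_steps)
    hunt_s <- 0
    seal_done_order <- integer(0)

    finish_seal <- function(i, res, wait_min) {
      # shared bookkeeping after a gigaseal attempt completes
      seal_wait_min[i] <<- wait_min
      seal_s_total <<- seal_s_total + res$elapsed_s
      if (res$outcome == "SEAL_OK") {
        sealed[i] <<- TRUE
        tr$to(i, "GIGASEALED_HELD")
      } else {
        tr$to(i, "SEAL_FAILED")
      }
      log_event(log, t, i, res$outcome,
                sprintf("R=%.0f MOhm", res$final_r_mohm))
      seal_done_order <<- c(seal_done_order, i)
    }

    if (variant == "interleaved") {
      own_steps <- integer(n)
      while (length(hunters)) {
        ev_steps <- pmin(detect_at[hunters], budget_steps) - own_steps[hunters]
        bout <- min(ev_steps)
        if (bout > 0) {
          t <- t + bout * step_measure_s
          hunt_s <- hunt_s + bout * step_measure_s
          own_steps[hunters] <- own_steps[hunters] + bout
          for (i in hunters) {
            log_event(log, t, i, "STEP", sprintf("steps=%d", bout))
          }
        }
        at_event <- hunters[own_steps[hunters] >=
                              pmin(detect_at[hunters], budget_steps)]
        det_now <- at_event[is.finite(detect_at[at_event])]
        exh_now <- at_event[!is.finite(detect_at[at_event])]
        for (i in exh_now) {
          exhausted[i] <- TRUE
          tr$to(i, "LOST")
          hunters <- setdiff(hunters, i)
        }
        if (length(det_now)) {
          c_i <- min(det_now)  # simultaneous detections: lowest index first
          detected[c_i] <- TRUE
          mark_contact(rig, c_i)
          log_event(log, t, c_i, "DETECT", "monotone rise > 0.25 MOhm")
          log_event(log, t, c_i, "HALT_ALL", "all motors halted")
          for (h in setdiff(hunters, c_i)) tr$to(h, "HALTED")
          tr$to(c_i, "GIGASEALING")
          log_event(log, t, c_i, "SEAL_START", "waiting_min=0")
          res <- run_gigaseal_schedule(rig, c_i, waiting_min = 0,
                                       abort_policy = abort_policy)
          t <- t + res$elapsed_s
          rig$clock_s <- t
          if (res$outcome == "SEAL_ABORTED") {
            tr$to(c_i, "SEAL_FAILED")
            seal_wait_min[c_i] <- 0
            seal_s_total <- seal_s_total + res$elapsed_s
            log_event(log, t, c_i, "SEAL_ABORTED",
                      sprintf("dR=%.0f MOhm at 35 s", res$delta_at_check_mohm))
            seal_done_order <- c(seal_done_order, c_i)
          } else {
            finish_seal(c_i, res, 0)
          }
          hunters <- setdiff(hunters, c_i)
          for (h in hunters) tr$to(h, "HUNTING")
          if (length(hunters)) {
            log_event(log, t, min(hunters), "RESUME", "neuron hunting resumed")
          }
        }
      }
      # held gigaseals can be lost while waiting for the operator's break-in
      for (i in which(sealed)) {
        if (stats::runif(1) < tissue$seal_loss_while_held_prob) {
          lost_waiting[i] <- TRUE
          tr$to(i, "LOST")
        }
      }
    } else {
      # both synchronized variants: independent concurrent hunting
      stop_step <- pmin(detect_at, budget_steps)
      stop_step[setdiff(seq_len(n), hunters)] <- NA
      hunt_start <- t
      all_stop_steps <- stop_step[hunters]
      last_stop <- if (length(hunters)) max(all_stop_steps) else 0
      for (i in hunters) {
        t_i <- hunt_start + stop_step[i] * step_measure_s
        log_event(log, t_i, i, "STEP", sprintf("steps=%d", stop_step[i]))
        if (is.finite(detect_at[i])) {
          detected[i] <- TRUE
          mark_contact(rig, i)
          log_event(log, t_i, i, "DETECT", "monotone rise > 0.25 MOhm")
          tr$to(i, "HALTED")
          if (variant == "retract_replay") {
            log_event(log, t_i, i, "STEP",
                      sprintf("retract %g um", retract_um))
          }
        } else {
          exhausted[i] <- TRUE
          tr$to(i, "LOST")
        }
      }
      t <- t + last_stop * step_measure_s
      hunt_s <- hunt_s + last_stop * step_measure_s
      contacts <- which(detected)
      wait_min <- (t - (hunt_start + stop_step * step_measure_s)) / 60

      if (variant == "retract_replay") {
        # replay: all pipettes advance the retraction distance together
        replay_s <- (retract_um / 2) * step_measure_s
        t <- t + replay_s
        hunt_s <- hunt_s + replay_s
        for (i in contacts) {
          log_event(log, t, i, "STEP",
                    sprintf("replay %g um", retract_um))
          if (stats::runif(1) >= tissue$replay_recontact_prob) {
            dislodged[i] <- TRUE
            rig$contact[i] <- "dislodged"
          }
          wait_min[i] <- wait_min[i] + replay_s / 60
        }
      } else if (length(contacts) > 1) {
        # held contacts are exposed to the other pipettes' movement for the
        # whole waiting episode; the last pipette to stop never waits
        for (i in contacts) {
          if (wait_min[i] > 0 &&
              stats::runif(1) < tissue$dislodge_prob_per_foreign_move) {
            dislodged[i] <- TRUE
            rig$contact[i] <- "dislodged"
          }
        }
      }

      if (length(contacts)) {
        # shared valve bank: one synchronized schedule for all pipettes
        for (i in contacts) {
          tr$to(i, "GIGASEALING")
          log_event(log, t, i, "SEAL_START",
                    sprintf("waiting_min=%.2f", wait_min[i]))
        }
        results <- lapply(contacts, function(i) {
          run_gigaseal_schedule(rig, i, waiting_min = wait_min[i])
        })
        t <- t + schedule_duration()
        rig$clock_s <- t
        for (k in seq_along(contacts)) {
          finish_seal(contacts[k], results[[k]], wait_min[contacts[k]])
        }
        seal_s_total <- seal_s_total - length(contacts) * schedule_duration() +
          schedule_duration()  # synchronized: wall time is one schedule
      }
    }

    # --- break-in, simultaneous on all held gigaseals ----------------------
    t <- t + breakin_delay_s
    to_breakin <- which(sealed & !lost_waiting)
    if (length(to_breakin)) {
      pulse_counts <- integer(0)
      for (i in to_breakin) {
        tr$to(i, "BREAKING_IN")
        log_event(log, t, i, "BREAKIN_START", "suction pulses")
      }
      clock_before <- rig$clock_s
      for (i in to_breakin) {
        res <- attempt_breakin(rig, i)
        rig$clock_s <- clock_before  # pulses run in parallel across pipettes
        pulse_counts <- c(pulse_counts, res$pulses)
        if (res$success) {
          whole_cell[i] <- TRUE
          tr$to(i, "WHOLE_CELL")
          log_event(log, t, i, "BREAKIN_OK", sprintf("pulses=%d", res$pulses))
        } else {
          tr$to(i, "GIGASEALED_HELD")
          log_event(log, t, i, "BREAKIN_FAIL",
                    sprintf("pulses=%d", res$pulses))
        }
      }
      t <- t + max(pulse_counts) * tissue$breakin_pulse_s
      rig$clock_s <- t
    }

    clogged <- rig$clogged
    hunted <- qc & !clogged
    events <- events_df(log)
    events <- events[order(events$t), , drop = FALSE]  # stable: ties keep order
    rownames(events) <- NULL
    structure(
      list(
        trial_id = NA_integer_,
        variant = variant,
        pipettes = data.frame(
          pipette = seq_len(n),
          qc = qc,
          clogged = clogged,
          hunted = hunted,
          detected = detected,
          sealed = sealed,
          whole_cell = whole_cell,
          dislodged = dislodged,
          exhausted = exhausted,
          lost_while_waiting = lost_waiting,
          seal_wait_min = seal_wait_min,
          final_phase = tr$phase,
          stringsAsFactors = FALSE
        ),
        timings = list(descent_s = descent_s, hunt_s = hunt_s,
                       seal_s_total = seal_s_total, total_s = t),
        events = events,
        transitions = tr$log
      ),
      class = "trial_record"
    )
  })
}

#' @export
print.trial_record <- function(x, ...) {
  p <- x$pipettes
  cat(sprintf(
    "<trial_record> variant=%s: %d pipettes, %d clogged, %d sealed, %d whole-cell; %.1f min\n",
    x$variant, nrow(p), sum(p$clogged), sum(p$sealed), sum(p$whole_cell),
    x$timings$total_s / 60
  ))
  invisible(x)
}
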