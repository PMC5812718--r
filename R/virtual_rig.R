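#' Pipette specification
#'
#' Fabrication-level properties of a patch pipette entering a trial. Bare
#' resistances are drawn in the 5-9 MOhm fabrication range by default; the
#' controller's quality-control acceptance range is the wider 3-9 MOhm.
#'
#' @param bare_resistance_mohm Bare tip resistance in MOhm, or `NULL` to draw
#'   uniformly from `resistance_range_mohm` when the rig is created.
#' @param clog_on_descent_prob Probability that the tip clogs or fouls during
#'   the initial descent to depth. Default 31/164, the observed blockage rate.
#' @param clog_increment_range_mohm Range (MOhm) of the resistance increase a
#'   clog produces; both ends must exceed the 0.35 MOhm clog-detection
#'   threshold so that a clogged tip is always detectable.
#' @param resistance_range_mohm Range to draw bare resistances from.
#' @return An object of class `pipette_spec`.
#' @export
pipette_spec <- function(bare_resistance_mohm = NULL,
                         clog_on_descent_prob = 31 / 164,
                         clog_increment_range_mohm = c(0.5, 3),
                         resistance_range_mohm = c(5, 9)) {
  if (!is.null(bare_resistance_mohm)) {
    stopifnot_scalar(bare_resistance_mohm, "bare_resistance_mohm",
                     positive = TRUE)
  }
  stopifnot(clog_on_descent_prob >= 0, clog_on_descent_prob <= 1,
            all(clog_increment_range_mohm > 0.35))
  structure(
    list(
      bare_resistance_mohm = bare_resistance_mohm,
      clog_on_descent_prob = clog_on_descent_prob,
      clog_increment_range_mohm = clog_increment_range_mohm,
      resistance_range_mohm = resistance_range_mohm
    ),
    class = "pipette_spec"
  )
}

#' Tissue interaction model
#'
#' The stochastic structure of pipette-tissue interaction that the controller
#' is tested against. Stage probabilities default to maximum-likelihood
#' proportions of published stage counts; see the methods vignette for the
#' provenance of every default.
#'
#' @param encounter_hazard_per_step Per-2-um-step probability of encountering
#'   a neuron while hunting. The default 0.005 puts the median hunt near 140
#'   steps (~280 um of travel).
#' @param contact_ramp_mohm_per_step Resistance increase per step while
#'   approaching a neuron (MOhm); the ramp lasts `contact_ramp_steps` steps
#'   and then plateaus. Defaults guarantee the 0.25 MOhm / 3-step detector
#'   fires on a true contact.
#' @param contact_ramp_steps Number of ramp steps before the plateau.
#' @param dislodge_prob_per_foreign_move Probability that a held (not yet
#'   sealed) contact is lost per waiting episode during which other pipettes
#'   move. Default 10/49, the observed fraction of waiting pipettes whose
#'   resistance fell back to its pre-contact baseline.
#' @param seal_success_base Probability that an immediately attempted
#'   gigaseal succeeds. Default 77/133.
#' @param seal_success_decay_per_min Multiplicative decay of seal success per
#'   minute of waiting between contact and the gigaseal attempt (models the
#'   deleterious exposure to intracellular solution). Must be in (0, 1].
#' @param breakin_success_prob_per_pulse Per-suction-pulse break-in
#'   probability. Default calibrated so that a 10-pulse attempt on a retained
#'   gigaseal succeeds with probability 52/72 (which, combined with the 5/77
#'   held-seal loss rate, reproduces the 67.5% attempt-level break-in rate).
#' @param breakin_max_pulses Maximum suction pulses per break-in attempt.
#' @param breakin_pulse_s Duration of one suction pulse, seconds.
#' @param seal_loss_while_held_prob Probability that a formed gigaseal is
#'   lost while held waiting for break-in. Default 5/77.
#' @param seal_growth_timescale_s Time constant of saturating seal-resistance
#'   growth, seconds.
#' @param seal_growth_boost Growth-rate multiplier applied while suction or a
#'   hyperpolarizing holding potential (<= -35 mV) is active.
#' @param seal_max_mohm Asymptote of a success-fated seal, MOhm (>= 1000).
#' @param seal_fail_delta_mohm Asymptotic resistance increase of a
#'   failure-fated attempt, MOhm (< 100 so that a failing attempt shows less
#'   than a 100 MOhm rise at the 35 s abort checkpoint).
#' @param replay_recontact_prob Probability that a contact is re-established
#'   when a retracted pipette is advanced back onto its neuron
#'   (retract-and-replay strategy). Default 27/59.
#' @param measurement_noise_sd_mohm SD of resistance measurement noise, MOhm.
#' @param deterministic_encounter_steps Optional integer vector: forces the
#'   neuron encounter of pipette i to fire exactly at its i-th entry
#'   (own hunting steps). Used for timeline tests; `NULL` for stochastic
#'   encounters.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(encounter_hazard_per_step = 0.005,
                         contact_ramp_mohm_per_step = 0.15,
                         contact_ramp_steps = 4,
                         dislodge_prob_per_foreign_move = 10 / 49,
                         seal_success_base = 77 / 133,
                         seal_success_decay_per_min = 0.70,
                         breakin_success_prob_per_pulse =
                           1 - (1 - 52 / 72)^(1 / 10),
                         breakin_max_pulses = 10,
                         breakin_pulse_s = 0.1,
                         seal_loss_while_held_prob = 5 / 77,
                         seal_growth_timescale_s = 15,
                         seal_growth_boost = 1.5,
                         seal_max_mohm = 1500,
                         seal_fail_delta_mohm = 60,
                         replay_recontact_prob = 27 / 59,
                         measurement_noise_sd_mohm = 0.005,
                         deterministic_encounter_steps = NULL) {
  probs <- c(encounter_hazard_per_step, dislodge_prob_per_foreign_move,
             seal_success_base, breakin_success_prob_per_pulse,
             seal_loss_while_held_prob, replay_recontact_prob)
  stopifnot(all(probs >= 0), all(probs <= 1),
            seal_success_decay_per_min > 0, seal_success_decay_per_min <= 1,
            seal_max_mohm >= 1000, seal_fail_delta_mohm < 100,
            seal_growth_timescale_s > 0, breakin_max_pulses >= 1)
  if (contact_ramp_mohm_per_step * min(3, contact_ramp_steps) < 0.25) {
    stop("contact ramp must produce >= 0.25 MOhm over 3 steps for a true contact")
  }
  structure(
    list(
      encounter_hazard_per_step = encounter_hazard_per_step,
      contact_ramp_mohm_per_step = contact_ramp_mohm_per_step,
      contact_ramp_steps = contact_ramp_steps,
      dislodge_prob_per_foreign_move = dislodge_prob_per_foreign_move,
      seal_success_base = seal_success_base,
      seal_success_decay_per_min = seal_success_decay_per_min,
      breakin_success_prob_per_pulse = breakin_success_prob_per_pulse,
      breakin_max_pulses = breakin_max_pulses,
      breakin_pulse_s = breakin_pulse_s,
      seal_loss_while_held_prob = seal_loss_while_held_prob,
      seal_growth_timescale_s = seal_growth_timescale_s,
      seal_growth_boost = seal_growth_boost,
      seal_max_mohm = seal_max_mohm,
      seal_fail_delta_mohm = seal_fail_delta_mohm,
      replay_recontact_prob = replay_recontact_prob,
      measurement_noise_sd_mohm = measurement_noise_sd_mohm,
      deterministic_encounter_steps = deterministic_encounter_steps
    ),
    class = "tissue_model"
  )
}

#' Create a virtual rig
#'
#' Ground truth for one trial: per-pipette depth, pressure, contact status,
#' seal resistance and clog status, hidden from the controller except through
#' resistance measurements. The rig is a mutable environment; all rig
#' operations update it in place and consume the ambient RNG stream in a
#' fixed, documented order (seed the stream before creating the rig for
#' reproducibility).
#'
#' @param n_pipettes Number of installed pipettes.
#' @param tissue A [tissue_model()].
#' @param pipettes A single [pipette_spec()] applied to all pipettes, or a
#'   list of one spec per pipette.
#' @return An environment of class `rig_state`.
#' @export
new_rig <- function(n_pipettes = 4, tissue = tissue_model(),
                    pipettes = pipette_spec()) {
  stopifnot(n_pipettes >= 1, inherits(tissue, "tissue_model"))
  if (inherits(pipettes, "pipette_spec")) {
    pipettes <- rep(list(pipettes), n_pipettes)
  }
  stopifnot(length(pipettes) == n_pipettes)
  rig <- new.env(parent = emptyenv())
  rig$n <- as.integer(n_pipettes)
  rig$tissue <- tissue
  rig$specs <- pipettes
  rig$bare_r <- vapply(pipettes, function(s) {
    if (is.null(s$bare_resistance_mohm)) {
      stats::runif(1, s$resistance_range_mohm[1], s$resistance_range_mohm[2])
    } else {
      s$bare_resistance_mohm
    }
  }, numeric(1))
  rig$depth_um <- numeric(n_pipettes)
  rig$pressure <- rep("ATMOSPHERIC", n_pipettes)
  rig$contact <- rep("none", n_pipettes)      # none/approaching/contacting/dislodged
  rig$ramp_steps_done <- integer(n_pipettes)
  rig$clogged <- logical(n_pipettes)
  rig$clog_dr <- numeric(n_pipettes)
  rig$seal_r <- rep(NA_real_, n_pipettes)     # NA until a seal attempt starts
  rig$seal_fate <- rep(NA, n_pipettes)
  rig$seal_r0 <- numeric(n_pipettes)
  rig$seal_teff <- numeric(n_pipettes)        # boost-weighted seal growth time
  rig$sealing <- logical(n_pipettes)
  rig$broken_in <- logical(n_pipettes)
  rig$motion_locked <- logical(n_pipettes)
  rig$clock_s <- 0
  class(rig) <- c("rig_state", "environment")
  rig
}

#' @export
print.rig_state <- function(x, ...) {
  cat(sprintf(
    "<rig_state> %d pipettes, t = %.1f s; clogged: %d, contacting: %d, sealing: %d, broken in: %d\n",
    x$n, x$clock_s, sum(x$clogged), sum(x$contact == "contacting"),
    sum(x$sealing), sum(x$broken_in)
  ))
  invisible(x)
}

check_pipette_index <- function(rig, i) {
  if (!is_scalar_number(i) || i < 1 || i > rig$n) {
    stop("invalid pipette index")
  }
  as.integer(i)
}

#' Set the pneumatic state of one pipette
#'
#' @param rig A [new_rig()] environment.
#' @param i Pipette index.
#' @param label One of the discrete pressure states (see
#'   [pressure_set_points()]).
#' @return The rig, invisibly.
#' @export
set_pressure <- function(rig, i, label) {
  i <- check_pipette_index(rig, i)
  stopifnot(label %in% names(pressure_set_points()))
  rig$pressure[i] <- label
  invisible(rig)
}

#' Measure the resistance a pipette currently presents
#'
#' The seal-test resistance the controller would read: bare resistance plus
#' clog increment, plus the contact ramp while approaching a neuron, replaced
#' by the growing seal resistance during/after gigasealing; Gaussian
#' measurement noise is added (one RNG draw).
#'
#' @param rig A rig environment.
#' @param i Pipette index.
#' @param noise Add measurement noise? Disable for exact ground-truth reads.
#' @return Resistance in MOhm.
#' @export
rig_measure <- function(rig, i, noise = TRUE) {
  i <- check_pipette_index(rig, i)
  if (!is.na(rig$seal_r[i])) {
    r <- rig$seal_r[i]
  } else {
    r <- rig$bare_r[i] + rig$clog_dr[i]
    if (rig$contact[i] %in% c("approaching", "contacting")) {
      ts <- rig$tissue
      r <- r + min(rig$ramp_steps_done[i], ts$contact_ramp_steps) *
        ts$contact_ramp_mohm_per_step
    }
  }
  if (noise) r <- r + stats::rnorm(1, 0, rig$tissue$measurement_noise_sd_mohm)
  r
}

#' Lower a pipette to its target depth
#'
#' Descent at ~200 um/s under high positive pressure; the rig clock advances
#' by `target_depth_um / 200` seconds. With probability
#' `clog_on_descent_prob` the tip clogs, raising its measured resistance by a
#' draw from the clog increment range (two RNG draws when clogged, one
#' otherwise).
#'
#' @param rig A rig environment.
#' @param i Pipette index.
#' @param target_depth_um Target depth in um (> 0).
#' @param speed_um_per_s Descent speed, um/s.
#' @return The rig, invisibly.
#' @export
descend_to_depth <- function(rig, i, target_depth_um, speed_um_per_s = 200) {
  i <- check_pipette_index(rig, i)
  if (rig$pressure[i] != "HIGH_POSITIVE") {
    abort_protocol("descent requires HIGH_POSITIVE pressure")
  }
  if (target_depth_um <= 0) stop("`target_depth_um` must be > 0")
  rig$depth_um[i] <- target_depth_um
  rig$clock_s <- rig$clock_s + target_depth_um / speed_um_per_s
  spec <- rig$specs[[i]]
  if (stats::runif(1) < spec$clog_on_descent_prob) {
    rig$clogged[i] <- TRUE
    rig$clog_dr[i] <- stats::runif(1, spec$clog_increment_range_mohm[1],
                                   spec$clog_increment_range_mohm[2])
  }
  invisible(rig)
}

#' Advance a hunting pipette by one step
#'
#' Moves the tip forward by `step_um` (default 2 um). A neuron encounter
#' fires with probability `encounter_hazard_per_step` (or deterministically,
#' if the tissue model prescribes encounter steps); once fired, subsequent
#' measurements follow the monotone contact ramp.
#'
#' @param rig A rig environment.
#' @param i Pipette index.
#' @param step_um Step size in um.
#' @return The measured resistance (with noise) after the step, MOhm.
#' @export
hunt_step <- function(rig, i, step_um = 2) {
  i <- check_pipette_index(rig, i)
  if (rig$clogged[i]) abort_protocol("cannot hunt with a clogged pipette")
  if (rig$sealing[i] || rig$motion_locked[i]) {
    abort_protocol("pipette phase forbids motion")
  }
  rig$depth_um[i] <- rig$depth_um[i] + step_um
  ts <- rig$tissue
  if (rig$contact[i] == "none") {
    det <- ts$deterministic_encounter_steps
    fired <- if (!is.null(det)) {
      rig$hunt_steps_taken <- rig$hunt_steps_taken %||% integer(rig$n)
      rig$hunt_steps_taken[i] <- rig$hunt_steps_taken[i] + 1L
      rig$hunt_steps_taken[i] >= det[i]
    } else {
      stats::runif(1) < ts$encounter_hazard_per_step
    }
    if (fired) {
      rig$contact[i] <- "approaching"
      rig$ramp_steps_done[i] <- 0L
    }
  } else if (rig$contact[i] == "approaching") {
    rig$ramp_steps_done[i] <- rig$ramp_steps_done[i] + 1L
    if (rig$ramp_steps_done[i] >= ts$contact_ramp_steps) {
      rig$contact[i] <- "contacting"
    }
  }
  rig_measure(rig, i)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Perturb held contacts when another pipette moves
#'
#' Tissue displacement from one pipette's movement episode can dislodge the
#' neurons held (but not yet gigasealed) by the others: each held contact is
#' lost with probability `dislodge_prob_per_foreign_move`, upon which its
#' measured resistance returns to the pre-contact baseline. Gigasealed
#' pipettes are immune.
#'
#' @param rig A rig environment.
#' @param moving Index of the pipette whose movement episode causes the
#'   perturbation.
#' @return Integer indices of the pipettes dislodged by this episode.
#' @export
foreign_movement_perturbation <- function(rig, moving) {
  moving <- check_pipette_index(rig, moving)
  held <- which(rig$contact %in% c("approaching", "contacting") &
                  !rig$sealing & is.na(rig$seal_r) &
                  seq_len(rig$n) != moving)
  dislodged <- integer(0)
  for (i in held) {
    if (stats::runif(1) < rig$tissue$dislodge_prob_per_foreign_move) {
      rig$contact[i] <- "dislodged"
      rig$ramp_steps_done[i] <- 0L
      dislodged <- c(dislodged, i)
    }
  }
  dislodged
}

#' Begin a gigasealing attempt
#'
#' Draws the attempt's fate once, at attempt start: success with probability
#' `seal_success_base * seal_success_decay_per_min ^ waiting_min` for a held
#' contact, and zero for a dislodged or absent contact. A success-fated
#' attempt's seal resistance grows saturating towards `seal_max_mohm`; a
#' failure-fated attempt's total rise stays below 100 MOhm.
#'
#' @param rig A rig environment.
#' @param i Pipette index; must be in contact (or dislodged) and unclogged.
#' @param waiting_min Minutes the contact was held before this attempt.
#' @return `TRUE` if the attempt is success-fated (one RNG draw for held
#'   contacts; none for dislodged contacts, which are always failure-fated).
#' @export
start_gigaseal_attempt <- function(rig, i, waiting_min = 0) {
  i <- check_pipette_index(rig, i)
  if (rig$clogged[i]) abort_protocol("cannot gigaseal a clogged pipette")
  if (!rig$contact[i] %in% c("contacting", "approaching", "dislodged")) {
    abort_protocol("gigasealing requires a pipette in contact with a neuron")
  }
  ts <- rig$tissue
  fate <- if (rig$contact[i] == "dislodged") {
    FALSE
  } else {
    p <- ts$seal_success_base * ts$seal_success_decay_per_min^waiting_min
    stats::runif(1) < p
  }
  rig$sealing[i] <- TRUE
  rig$seal_fate[i] <- fate
  rig$seal_r0[i] <- rig$bare_r[i] + rig$clog_dr[i] +
    if (rig$contact[i] == "contacting") {
      ts$contact_ramp_steps * ts$contact_ramp_mohm_per_step
    } else 0
  rig$seal_r[i] <- rig$seal_r0[i]
  rig$seal_teff[i] <- 0
  rig$motion_locked[i] <- TRUE
  fate
}

seal_growth_rate_boost <- function(tissue, pressure, holding_mv) {
  if (identical(pressure, "LOW_SUCTION") || holding_mv <= -35) {
    tissue$seal_growth_boost
  } else {
    1
  }
}

#' Advance seal-resistance growth by one interval
#'
#' Saturating first-order growth of the seal resistance towards its fated
#' asymptote, accelerated by `seal_growth_boost` while suction or a
#' hyperpolarizing holding potential (<= -35 mV) is applied. Deterministic
#' given the fate drawn by [start_gigaseal_attempt()].
#'
#' @param rig A rig environment.
#' @param i Pipette index with an active or held seal attempt.
#' @param dt_s Interval to advance, seconds.
#' @param pressure Pneumatic state label during the interval.
#' @param holding_mv Holding potential during the interval, mV.
#' @return The seal resistance at the end of the interval, MOhm.
#' @export
gigaseal_step <- function(rig, i, dt_s, pressure = "ATMOSPHERIC",
                          holding_mv = 0) {
  i <- check_pipette_index(rig, i)
  if (rig$clogged[i]) abort_protocol("cannot gigaseal a clogged pipette")
  if (is.na(rig$seal_fate[i])) {
    abort_protocol("no gigaseal attempt active; call start_gigaseal_attempt()")
  }
  ts <- rig$tissue
  boost <- seal_growth_rate_boost(ts, pressure, holding_mv)
  rig$seal_teff[i] <- rig$seal_teff[i] + boost * dt_s
  asymptote <- if (rig$seal_fate[i]) {
    ts$seal_max_mohm
  } else {
    rig$seal_r0[i] + ts$seal_fail_delta_mohm
  }
  rig$seal_r[i] <- asymptote - (asymptote - rig$seal_r0[i]) *
    exp(-rig$seal_teff[i] / ts$seal_growth_timescale_s)
  rig$clock_s <- rig$clock_s + dt_s
  rig$seal_r[i]
}

#' Attempt break-in on a gigasealed pipette
#'
#' Applies suction pulses until the membrane patch ruptures or the pulse
#' budget is exhausted. Each pulse succeeds independently with probability
#' `breakin_success_prob_per_pulse` (one RNG draw per pulse).
#'
#' @param rig A rig environment.
#' @param i Pipette index; its seal resistance must be >= 1000 MOhm.
#' @param max_pulses Pulse budget; defaults to the tissue model's.
#' @return A list with `success` (logical) and `pulses` (pulses applied).
#' @export
attempt_breakin <- function(rig, i, max_pulses = NULL) {
  i <- check_pipette_index(rig, i)
  if (is.na(rig$seal_r[i]) || rig$seal_r[i] < 1000) {
    abort_protocol("break-in requires a gigaseal (>= 1000 MOhm)")
  }
  ts <- rig$tissue
  max_pulses <- max_pulses %||% ts$breakin_max_pulses
  for (pulse in seq_len(max_pulses)) {
    if (stats::runif(1) < ts$breakin_success_prob_per_pulse) {
      rig$broken_in[i] <- TRUE
      rig$clock_s <- rig$clock_s + pulse * ts$breakin_pulse_s
      return(list(success = TRUE, pulses = pulse))
    }
  }
  rig$clock_s <- rig$clock_s + max_pulses * ts$breakin_pulse_s
  list(success = FALSE, pulses = max_pulses)
}

#' Calibrate a tissue model from stage counts
#'
#' Stage probabilities are maximum-likelihood binomial proportions of the
#' supplied counts, with exact (Clopper-Pearson) 95% confidence intervals
#' attached. Recognized stages, each `c(successes, attempts)`:
#' `clog` (clogged / installed), `seal` (gigasealed / pipettes that attempted
#' gigasealing), `breakin` (whole-cell / gigasealed, attempt level),
#' `dislodge` (dislodged / waiting episodes).
#'
#' @param stage_counts Named list of `c(successes, attempts)` pairs.
#' @param base A [tissue_model()] supplying every uncalibrated parameter.
#' @return A `tissue_model` with calibrated probabilities and a
#'   `"calibration"` attribute (data frame of estimates and 95% CIs).
#' @export
#' @examples
#' tm <- calibrate_from_counts(list(seal = c(77, 133)))
#' tm$seal_success_base
calibrate_from_counts <- function(stage_counts, base = tissue_model()) {
  stopifnot(is.list(stage_counts), length(stage_counts) >= 1,
            !is.null(names(stage_counts)))
  rows <- lapply(names(stage_counts), function(stage) {
    x <- stage_counts[[stage]]
    if (length(x) != 2 || x[2] <= 0) {
      abort_typed("calibration_error",
                  sprintf("stage '%s' needs c(successes, attempts) with attempts > 0",
                          stage))
    }
    if (x[1] > x[2] || x[1] < 0) {
      abort_typed("calibration_error",
                  sprintf("stage '%s': successes must be in [0, attempts]", stage))
    }
    ci <- stats::binom.test(x[1], x[2])$conf.int
    data.frame(stage = stage, successes = x[1], attempts = x[2],
               estimate = x[1] / x[2], lower = ci[1], upper = ci[2])
  })
  calib <- do.call(rbind, rows)
  tm <- base
  get_est <- function(stage) calib$estimate[calib$stage == stage]
  # the clog rate lives on pipette_spec, not the tissue model; its estimate
  # stays available in the calibration table
  if ("seal" %in% calib$stage) tm$seal_success_base <- get_est("seal")
  if ("dislodge" %in% calib$stage) {
    tm$dislodge_prob_per_foreign_move <- get_est("dislodge")
  }
  if ("breakin" %in% calib$stage) {
    # attempt-level rate -> per-pulse rate over the pulse budget, after
    # removing the held-seal loss channel
    p_attempt <- get_est("breakin")
    p_retained <- min(1, p_attempt / (1 - tm$seal_loss_while_held_prob))
    tm$breakin_success_prob_per_pulse <-
      1 - (1 - p_retained)^(1 / tm$breakin_max_pulses)
  }
  attr(tm, "calibration") <- calib
  tm
}
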