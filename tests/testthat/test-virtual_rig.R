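test_that("descent obeys the 200 um/s speed and the pressure precondition", {
  set.seed(1)
  rig <- new_rig(1, pipettes = pipette_spec(6, clog_on_descent_prob = 0))
  expect_error(descend_to_depth(rig, 1, 400), class = "protocol_violation")
  set_pressure(rig, 1, "HIGH_POSITIVE")
  t0 <- rig$clock_s
  descend_to_depth(rig, 1, 400)
  expect_equal(rig$clock_s - t0, 2.0)  # 400 um at 200 um/s
  expect_false(rig$clogged[1])
})

test_that("descent clogging matches its binomial rate", {
  set.seed(7)
  # zero probability never clogs
  rig0 <- new_rig(1000, pipettes = pipette_spec(6, clog_on_descent_prob = 0))
  for (i in 1:1000) {
    set_pressure(rig0, i, "HIGH_POSITIVE")
    descend_to_depth(rig0, i, 400)
  }
  expect_false(any(rig0$clogged))

  p <- 31 / 164
  n <- 10000
  rig <- new_rig(n, pipettes = pipette_spec(6, clog_on_descent_prob = p))
  for (i in seq_len(n)) {
    set_pressure(rig, i, "HIGH_POSITIVE")
    descend_to_depth(rig, i, 400)
  }
  sd3 <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(rig$clogged) - p), sd3)
  # a clog always exceeds the 0.35 MOhm localization threshold
  expect_true(all(rig$clog_dr[rig$clogged] > 0.35))
})

test_that("hunting encounters are geometric and the contact ramp is monotone", {
  # no hazard: resistance stays at baseline over 500 steps
  set.seed(3)
  quiet <- tissue_model(encounter_hazard_per_step = 0)
  rig <- new_rig(1, tissue = quiet, pipettes = pipette_spec(6))
  r <- vapply(1:500, function(k) hunt_step(rig, 1), numeric(1))
  expect_true(all(abs(r - 6) < 0.05))
  expect_identical(rig$contact[1], "none")
  expect_equal(rig$depth_um[1], 1000)  # 500 steps of 2 um

  # geometric steps-to-encounter with mean 1/h
  h <- 0.05
  ts <- tissue_model(encounter_hazard_per_step = h)
  set.seed(4)
  n <- 5000
  steps <- vapply(seq_len(n), function(k) {
    rig <- new_rig(1, tissue = ts, pipettes = pipette_spec(6))
    s <- 0
    while (rig$contact[1] == "none") {
      hunt_step(rig, 1)
      s <- s + 1
    }
    s
  }, numeric(1))
  se <- sqrt((1 - h) / h^2 / n)
  expect_lt(abs(mean(steps) - 1 / h), 3 * se)

  # after the encounter, three consecutive steps rise monotonically by
  # >= 0.25 MOhm in total (noise-free ground truth)
  det <- tissue_model(deterministic_encounter_steps = 5)
  rig <- new_rig(1, tissue = det, pipettes = pipette_spec(6))
  for (k in 1:5) hunt_step(rig, 1)
  r3 <- vapply(1:3, function(k) {
    hunt_step(rig, 1)
    rig_measure(rig, 1, noise = FALSE)
  }, numeric(1))
  expect_true(all(diff(r3) > 0))
  expect_gte(r3[3] - 6, 0.25)
})

test_that("hunting respects phase preconditions", {
  set.seed(5)
  rig <- new_rig(2, pipettes = pipette_spec(6, clog_on_descent_prob = 1))
  set_pressure(rig, 1, "HIGH_POSITIVE")
  descend_to_depth(rig, 1, 400)
  expect_error(hunt_step(rig, 1), class = "protocol_violation")  # clogged
  rig$motion_locked[2] <- TRUE
  expect_error(hunt_step(rig, 2), class = "protocol_violation")  # halted
})

test_that("foreign movement dislodges held contacts at the calibrated rate", {
  ts <- tissue_model(dislodge_prob_per_foreign_move = 0,
                     deterministic_encounter_steps = rep(1, 3))
  set.seed(6)
  rig <- new_rig(3, tissue = ts, pipettes = pipette_spec(6))
  for (i in 2:3) for (k in 1:5) hunt_step(rig, i)
  expect_identical(foreign_movement_perturbation(rig, 1), integer(0))
  expect_true(all(rig$contact[2:3] == "contacting"))

  # calibrated probability: dislodged fraction over 10,000 waiting episodes
  p <- 10 / 49
  n <- 10001
  ts2 <- tissue_model(dislodge_prob_per_foreign_move = p,
                      deterministic_encounter_steps = rep(1, n))
  set.seed(8)
  rig2 <- new_rig(n, tissue = ts2, pipettes = pipette_spec(6))
  for (i in 2:n) for (k in 1:5) hunt_step(rig2, i)
  lost <- foreign_movement_perturbation(rig2, 1)
  sd3 <- 3 * sqrt(p * (1 - p) / (n - 1))
  expect_lt(abs(length(lost) / (n - 1) - p), sd3)
  # dislodgement resets the measured resistance to baseline exactly
  expect_equal(rig_measure(rig2, lost[1], noise = FALSE),
               rig2$bare_r[lost[1]])
})

test_that("gigaseal growth separates success- and failure-fated attempts", {
  mk_contact <- function(ts) {
    rig <- new_rig(1, tissue = ts, pipettes = pipette_spec(6))
    for (k in 1:10) hunt_step(rig, 1)
    rig
  }
  # success-fated: >= 1 GOhm within the 60 s schedule
  set.seed(9)
  rig <- mk_contact(tissue_model(seal_success_base = 1,
                                 deterministic_encounter_steps = 1))
  res <- run_gigaseal_schedule(rig, 1)
  expect_identical(res$outcome, "SEAL_OK")
  expect_gte(res$final_r_mohm, 1000)
  expect_equal(res$elapsed_s, 60)

  # failure-fated: total rise below 100 MOhm at the 35 s checkpoint
  rig2 <- mk_contact(tissue_model(seal_success_base = 0,
                                  deterministic_encounter_steps = 1))
  start_gigaseal_attempt(rig2, 1)
  r35 <- gigaseal_step(rig2, 1, 35, pressure = "LOW_SUCTION")
  expect_lt(r35 - rig2$seal_r0[1], 100)

  # clogged pipette: protocol violation
  rig3 <- new_rig(1, pipettes = pipette_spec(6, clog_on_descent_prob = 1))
  set_pressure(rig3, 1, "HIGH_POSITIVE")
  descend_to_depth(rig3, 1, 400)
  rig3$contact[1] <- "contacting"
  expect_error(start_gigaseal_attempt(rig3, 1), class = "protocol_violation")
})

test_that("immediate seal success matches its base probability; waiting never helps", {
  base <- 77 / 133
  ts <- tissue_model(seal_success_base = base,
                     deterministic_encounter_steps = 1)
  draw_fates <- function(waiting_min, n) {
    vapply(seq_len(n), function(k) {
      rig <- new_rig(1, tissue = ts, pipettes = pipette_spec(6))
      for (s in 1:5) hunt_step(rig, 1)
      start_gigaseal_attempt(rig, 1, waiting_min = waiting_min)
    }, logical(1))
  }
  set.seed(10)
  n <- 10000
  f0 <- draw_fates(0, n)
  sd3 <- 3 * sqrt(base * (1 - base) / n)
  expect_lt(abs(mean(f0) - base), sd3)

  # monotone harm: multi-minute waiting lowers the success rate
  f4 <- draw_fates(4, 3000)
  expect_lt(mean(f4), mean(f0))
  p4 <- base * tissue_model()$seal_success_decay_per_min^4
  expect_lt(abs(mean(f4) - p4), 3 * sqrt(p4 * (1 - p4) / 3000))
})

test_that("break-in follows the per-pulse closed form", {
  mk_sealed <- function(p_pulse) {
    ts <- tissue_model(seal_success_base = 1,
                       breakin_success_prob_per_pulse = p_pulse,
                       deterministic_encounter_steps = 1)
    rig <- new_rig(1, tissue = ts, pipettes = pipette_spec(6))
    for (k in 1:10) hunt_step(rig, 1)
    start_gigaseal_attempt(rig, 1)
    gigaseal_step(rig, 1, 60, pressure = "LOW_SUCTION", holding_mv = -70)
    rig
  }
  set.seed(11)
  rig <- mk_sealed(1)
  expect_identical(attempt_breakin(rig, 1), list(success = TRUE, pulses = 1L))

  # eventual success probability with per-pulse p over N pulses
  p <- 0.15; N <- 5
  n <- 10000
  wins <- vapply(seq_len(n), function(k) {
    attempt_breakin(mk_sealed(p), 1, max_pulses = N)$success
  }, logical(1))
  p_eventual <- 1 - (1 - p)^N
  expect_lt(abs(mean(wins) - p_eventual),
            3 * sqrt(p_eventual * (1 - p_eventual) / n))

  # break-in on a non-gigasealed pipette is a protocol violation
  rig2 <- new_rig(1, pipettes = pipette_spec(6))
  expect_error(attempt_breakin(rig2, 1), class = "protocol_violation")
})

test_that("calibration from stage counts gives ML proportions with 95% CIs", {
  tm <- calibrate_from_counts(list(seal = c(77, 133)))
  expect_equal(tm$seal_success_base, 77 / 133)
  calib <- attr(tm, "calibration")
  expect_true(calib$lower <= 77 / 133 && 77 / 133 <= calib$upper)

  tm2 <- calibrate_from_counts(list(seal = c(50, 50)))
  expect_equal(tm2$seal_success_base, 1)

  # attempt-level break-in rate maps back through the pulse budget
  tm3 <- calibrate_from_counts(list(breakin = c(52, 77)))
  p_attempt_retained <- 1 - (1 - tm3$breakin_success_prob_per_pulse)^10
  expect_equal(p_attempt_retained * (1 - tm3$seal_loss_while_held_prob),
               52 / 77, tolerance = 1e-10)

  expect_error(calibrate_from_counts(list(seal = c(0, 0))),
               class = "calibration_error")
  expect_error(calibrate_from_counts(list(seal = c(5, 3))),
               class = "calibration_error")
})
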