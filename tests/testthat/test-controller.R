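test_that("quality control accepts the inclusive 3-9 MOhm range", {
  expect_true(qc_check(4.0))
  expect_false(qc_check(2.0))
  expect_true(qc_check(3.0))
  expect_true(qc_check(9.0))
  expect_false(qc_check(9.01))
  expect_false(qc_check(2.99))
})

test_that("regional localization deactivates on a strict 0.35 MOhm rise", {
  expect_false(regional_localization(5.00, 5.50))  # dR 0.5 -> deactivate
  expect_true(regional_localization(5.00, 5.20))
  expect_true(regional_localization(5.00, 5.35))   # boundary: strict >
})

test_that("neuron detection agrees with a brute-force evaluation of the rule", {
  expect_true(detect_neuron(c(5.00, 5.10, 5.20, 5.30)))
  expect_false(detect_neuron(c(5.00, 5.00, 5.00, 5.00)))
  expect_false(detect_neuron(c(5.00, 5.30, 5.20, 5.60)))
  expect_false(detect_neuron(c(5.00, 5.10, 5.20)))  # insufficient history

  # exhaustive check over every 4-point grid on {5.0, 5.1, ..., 5.6}
  grid <- expand.grid(a = seq(5.0, 5.6, by = 0.1), b = seq(5.0, 5.6, by = 0.1),
                      c = seq(5.0, 5.6, by = 0.1), d = seq(5.0, 5.6, by = 0.1))
  for (k in seq_len(nrow(grid))) {
    h <- as.numeric(grid[k, ])
    expect_identical(detect_neuron(h), oracle_detect(h))
  }
})

test_that("the gigasealing schedule is the published 60 s program", {
  sched <- gigaseal_schedule()
  expect_equal(schedule_duration(sched), 60)
  expect_identical(sched$pressure[1:3],
                   c("LOW_POSITIVE", "ATMOSPHERIC", "LOW_SUCTION"))
  # voltage switches instantly to -35 mV at 25 s, then ramps to -70 over 30 s
  expect_equal(schedule_voltage_at(sched, 24), 0)
  expect_equal(schedule_voltage_at(sched, 25.0001), -35, tolerance = 1e-3)
  expect_equal(schedule_voltage_at(sched, 35), -35 + (10 / 30) * (-35))
  expect_equal(schedule_voltage_at(sched, 55), -70)
  expect_equal(schedule_voltage_at(sched, 60), -70)
  # voltage is non-increasing from the switch onward
  v <- schedule_voltage_at(sched, seq(25, 60, by = 0.5))
  expect_true(all(diff(v) <= 1e-12))
  expect_identical(schedule_pressure_at(sched, 20), "LOW_SUCTION")
  # pneumatic set points
  expect_identical(pressure_set_points(),
                   c(HIGH_POSITIVE = 800, LOW_POSITIVE = 25, ATMOSPHERIC = 0,
                     LOW_SUCTION = -15, HIGH_SUCTION = -300))
})

test_that("running the schedule yields SEAL_OK, SEAL_FAIL or a 35 s abort", {
  mk_contact <- function(base) {
    ts <- tissue_model(seal_success_base = base,
                       deterministic_encounter_steps = 1)
    rig <- new_rig(1, tissue = ts, pipettes = pipette_spec(6))
    for (k in 1:10) hunt_step(rig, 1)
    rig
  }
  set.seed(20)
  ok <- run_gigaseal_schedule(mk_contact(1), 1)
  expect_identical(ok$outcome, "SEAL_OK")
  expect_equal(ok$elapsed_s, 60)
  expect_gte(ok$final_r_mohm, 1000)

  fail <- run_gigaseal_schedule(mk_contact(0), 1)
  expect_identical(fail$outcome, "SEAL_FAIL")
  expect_equal(fail$elapsed_s, 60)
  expect_lt(fail$final_r_mohm, 1000)

  aborted <- run_gigaseal_schedule(mk_contact(0), 1, abort_policy = TRUE)
  expect_identical(aborted$outcome, "SEAL_ABORTED")
  expect_equal(aborted$elapsed_s, 35)
  expect_lt(aborted$delta_at_check_mohm, 100)

  # a success-fated attempt is never auto-aborted
  ok2 <- run_gigaseal_schedule(mk_contact(1), 1, abort_policy = TRUE)
  expect_identical(ok2$outcome, "SEAL_OK")

  # schedule on a pipette that has no contact is a protocol violation
  rig <- new_rig(1, pipettes = pipette_spec(6))
  expect_error(run_gigaseal_schedule(rig, 1), class = "protocol_violation")
})

test_that("a deterministic interleaved trial matches the hand-computed timeline", {
  ts <- tissue_model(
    deterministic_encounter_steps = c(20, 40, 60, 80),
    seal_success_base = 1,
    breakin_success_prob_per_pulse = 1,
    seal_loss_while_held_prob = 0,
    measurement_noise_sd_mohm = 1e-6
  )
  rec <- run_trial("interleaved", tissue = ts,
                   pipettes = pipette_spec(6, clog_on_descent_prob = 0),
                   depths_um = 400, seed = 1)
  # timeline oracle, composed independently of the controller:
  #   descent 400/200 = 2 s; one localization measurement 0.5 s;
  #   detections at encounter + 3 steps of 0.5 s, interleaved with 60 s
  #   seals; one synchronized break-in pulse of 0.1 s
  detect_steps <- c(20, 40, 60, 80) + 3
  t <- 2 + 0.5
  for (k in 1:4) {
    bout <- detect_steps[k] - if (k == 1) 0 else detect_steps[k - 1]
    t <- t + bout * 0.5 + 60
  }
  t <- t + 0.1
  expect_equal(rec$timings$total_s, t)
  expect_equal(rec$timings$descent_s, 2)
  expect_true(all(rec$pipettes$whole_cell))
  # event times never decrease
  expect_true(all(diff(rec$events$t) >= 0))
  # each pipette's DETECT precedes its SEAL_START at the same time stamp
  det <- rec$events[rec$events$event == "DETECT", ]
  expect_equal(det$t, 2.5 + detect_steps * 0.5 + (0:3) * 60)
})

test_that("interleaved gigasealing is mutually exclusive and motion-free", {
  set.seed(21)
  for (k in 1:50) {
    rec <- run_trial("interleaved")
    iv <- seal_intervals(rec$events)
    if (nrow(iv) > 1) {
      iv <- iv[order(iv$from), ]
      expect_true(all(iv$from[-1] >= iv$to[-nrow(iv)]))
    }
    steps <- rec$events$t[rec$events$event == "STEP"]
    for (j in seq_len(nrow(iv))) {
      expect_false(any(steps > iv$from[j] & steps < iv$to[j]))
    }
  }
})

test_that("synchronized variants share seal timestamps and count clogs correctly", {
  # forced clog on exactly one pipette: three reach hunting
  specs <- c(list(pipette_spec(6, clog_on_descent_prob = 1)),
             rep(list(pipette_spec(6, clog_on_descent_prob = 0)), 3))
  set.seed(22)
  rec <- run_trial("sync_all", pipettes = specs,
                   tissue = tissue_model(deterministic_encounter_steps =
                                           c(10, 20, 30, 40)))
  expect_equal(sum(rec$pipettes$hunted), 3)
  expect_true(rec$pipettes$clogged[1])
  # the shared valve bank: all SEAL_START events carry one timestamp
  starts <- rec$events[rec$events$event == "SEAL_START", ]
  expect_equal(length(unique(starts$t)), 1)

  rec2 <- run_trial("retract_replay", pipettes = specs,
                    tissue = tissue_model(deterministic_encounter_steps =
                                            c(10, 20, 30, 40)), seed = 3)
  starts2 <- rec2$events[rec2$events$event == "SEAL_START", ]
  expect_equal(length(unique(starts2$t)), 1)
  expect_error(run_trial("no_such_variant"), "arg")
})

test_that("trials only ever use legal phase transitions", {
  legal <- unlist(lapply(names(phase_transitions()), function(from) {
    paste0(from, "->", phase_transitions()[[from]])
  }))
  set.seed(23)
  for (variant in c("interleaved", "sync_all", "retract_replay")) {
    for (k in 1:20) {
      rec <- run_trial(variant)
      expect_true(all(rec$transitions %in% legal))
    }
  }
})
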