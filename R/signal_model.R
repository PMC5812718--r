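#' Square-wave seal-test stimulus
#'
#' The command signal used to measure pipette resistance: a small square wave
#' in voltage clamp, by default 10 mV peak-to-peak at 10 Hz, optionally with
#' a DC holding offset (0 down to -70 mV during gigasealing).
#'
#' @param peak_to_peak_mv Peak-to-peak amplitude in mV. The resistance
#'   estimator divides this applied voltage by the peak-to-peak current, so
#'   the amplitude convention here is peak-to-peak throughout.
#' @param frequency_hz Square-wave frequency in Hz.
#' @param dc_offset_mv DC holding offset in mV (<= 0 during gigasealing).
#' @param sample_rate_hz Acquisition sampling rate in Hz.
#' @param duration_s Trace duration in seconds; must cover > 1 cycle.
#' @return An object of class `square_wave_stimulus`.
#' @export
#' @examples
#' stim <- square_wave_stimulus()
#' stim$peak_to_peak_mv
square_wave_stimulus <- function(peak_to_peak_mv = 10,
                                 frequency_hz = 10,
                                 dc_offset_mv = 0,
                                 sample_rate_hz = 15000,
                                 duration_s = 0.3) {
  stopifnot_scalar(peak_to_peak_mv, "peak_to_peak_mv", positive = TRUE)
  stopifnot_scalar(frequency_hz, "frequency_hz", positive = TRUE)
  stopifnot_scalar(dc_offset_mv, "dc_offset_mv")
  stopifnot_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  if (sample_rate_hz < 2 * frequency_hz) {
    stop("`sample_rate_hz` must be at least twice `frequency_hz`")
  }
  if (duration_s <= 1 / frequency_hz) {
    stop("`duration_s` must exceed one stimulus period")
  }
  structure(
    list(
      peak_to_peak_mv = peak_to_peak_mv,
      frequency_hz = frequency_hz,
      dc_offset_mv = dc_offset_mv,
      sample_rate_hz = sample_rate_hz,
      duration_s = duration_s
    ),
    class = "square_wave_stimulus"
  )
}

#' Stimulus voltage at given times
#'
#' @param stim A [square_wave_stimulus()].
#' @param t Numeric vector of times in seconds.
#' @return Voltage in mV at each time; the first half of every cycle is the
#'   high plateau.
#' @export
stimulus_voltage <- function(stim, t) {
  phase <- (t * stim$frequency_hz) %% 1
  stim$dc_offset_mv + (stim$peak_to_peak_mv / 2) * ifelse(phase < 0.5, 1, -1)
}

#' Lumped electrode circuit model
#'
#' A minimal electrical model of a patch pipette used to synthesize seal-test
#' currents: a resistive pathway plus a stray capacitance charged through it.
#' The resistive pathway is the pipette resistance in the bath, the seal
#' resistance once a cell-attached seal forms, and pipette (access) plus
#' membrane resistance after break-in.
#'
#' @param pipette_resistance_mohm Pipette resistance in MOhm (> 0).
#' @param stray_capacitance_pf Stray capacitance in pF (>= 0).
#' @param seal_resistance_mohm Seal resistance in MOhm; `Inf` when no seal
#'   pathway exists. Must be >= pipette resistance outside `bath` mode.
#' @param membrane_resistance_mohm Membrane resistance in MOhm, used in
#'   `whole_cell` mode only.
#' @param mode One of `"bath"`, `"cell_attached"`, `"whole_cell"`.
#' @return An object of class `electrode_circuit`.
#' @export
electrode_circuit <- function(pipette_resistance_mohm,
                              stray_capacitance_pf = 0,
                              seal_resistance_mohm = Inf,
                              membrane_resistance_mohm = 100,
                              mode = c("bath", "cell_attached", "whole_cell")) {
  mode <- match.arg(mode)
  if (!is.numeric(pipette_resistance_mohm) ||
      length(pipette_resistance_mohm) != 1L ||
      !is.finite(pipette_resistance_mohm) ||
      pipette_resistance_mohm <= 0) {
    abort_typed("invalid_circuit", "`pipette_resistance_mohm` must be > 0")
  }
  if (stray_capacitance_pf < 0) {
    abort_typed("invalid_circuit", "`stray_capacitance_pf` must be >= 0")
  }
  if (mode != "bath" && seal_resistance_mohm < pipette_resistance_mohm) {
    abort_typed(
      "invalid_circuit",
      "`seal_resistance_mohm` must be >= pipette resistance when sealed"
    )
  }
  structure(
    list(
      pipette_resistance_mohm = pipette_resistance_mohm,
      stray_capacitance_pf = stray_capacitance_pf,
      seal_resistance_mohm = seal_resistance_mohm,
      membrane_resistance_mohm = membrane_resistance_mohm,
      mode = mode
    ),
    class = "electrode_circuit"
  )
}

#' Effective resistive pathway of a circuit, MOhm
#'
#' @param circuit An [electrode_circuit()].
#' @return Resistance in MOhm seen by the seal test: the pipette resistance
#'   in the bath, the seal resistance when cell-attached, and access plus
#'   membrane resistance in whole-cell mode.
#' @export
effective_resistance <- function(circuit) {
  switch(circuit$mode,
    bath = circuit$pipette_resistance_mohm,
    cell_attached = circuit$seal_resistance_mohm,
    whole_cell = circuit$pipette_resistance_mohm +
      circuit$membrane_resistance_mohm
  )
}

#' Uniformly sampled current trace
#'
#' @param samples_pa Numeric vector of current samples in pA; all finite.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(samples_pa, sample_rate_hz, t0 = 0) {
  if (!is.numeric(samples_pa) || !all(is.finite(samples_pa))) {
    stop("`samples_pa` must be numeric and finite")
  }
  stopifnot_scalar(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  structure(
    list(samples_pa = as.numeric(samples_pa),
         sample_rate_hz = sample_rate_hz, t0 = t0),
    class = "current_trace"
  )
}

#' @export
length.current_trace <- function(x) length(x$samples_pa)

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "<current_trace> %d samples @ %g Hz (%.4g s), range [%.4g, %.4g] pA\n",
    length(x$samples_pa), x$sample_rate_hz,
    length(x$samples_pa) / x$sample_rate_hz,
    min(x$samples_pa), max(x$samples_pa)
  ))
  invisible(x)
}

#' Synthesize the seal-test current response of an electrode circuit
#'
#' Forward model of the measurement chain: the square-wave command applied to
#' the lumped circuit yields a resistive plateau `V/R` plus, at every voltage
#' edge, a first-order capacitive transient of amplitude `dV/R` decaying with
#' time constant `R * C` (so the charge delivered per edge is `dV * C`).
#' Gaussian noise of the requested RMS is added on top.
#'
#' @param stim A [square_wave_stimulus()].
#' @param circuit An [electrode_circuit()].
#' @param noise_rms_pa RMS of additive Gaussian current noise, pA.
#' @param seed Optional integer seed; the trace is deterministic given it.
#' @return A [current_trace()] in pA at the stimulus sampling rate.
#' @export
#' @examples
#' stim <- square_wave_stimulus()
#' tr <- synthesize_current(stim, electrode_circuit(5), noise_rms_pa = 0)
#' max(tr$samples_pa) - min(tr$samples_pa)  # 2000 pA for 10 mV / 5 MOhm
synthesize_current <- function(stim, circuit, noise_rms_pa = 0, seed = NULL) {
  stopifnot(inherits(stim, "square_wave_stimulus"),
            inherits(circuit, "electrode_circuit"))
  r_mohm <- effective_resistance(circuit)
  if (!is.finite(r_mohm) || r_mohm <= 0) {
    abort_typed("invalid_circuit", "circuit has non-positive resistance")
  }
  n <- round(stim$duration_s * stim$sample_rate_hz)
  t <- (seq_len(n) - 1) / stim$sample_rate_hz
  # mV / MOhm = nA; traces are in pA
  i_pa <- stimulus_voltage(stim, t) / r_mohm * 1000

  c_pf <- circuit$stray_capacitance_pf
  if (c_pf > 0) {
    tau_s <- r_mohm * c_pf * 1e-6  # MOhm * pF = microseconds
    half_period <- 1 / (2 * stim$frequency_hz)
    edges <- seq(0, stim$duration_s, by = half_period)
    edges <- edges[edges < stim$duration_s]
    for (k in seq_along(edges)) {
      # edge k = 1 (t = 0) swings low -> high: dV = +pp; then alternating
      dv <- stim$peak_to_peak_mv * if (k %% 2 == 1) 1 else -1
      idx <- which(t >= edges[k])
      i_pa[idx] <- i_pa[idx] +
        (dv / r_mohm) * 1000 * exp(-(t[idx] - edges[k]) / tau_s)
    }
  }

  if (noise_rms_pa > 0) {
    i_pa <- i_pa + with_seed(seed, stats::rnorm(n, 0, noise_rms_pa))
  }
  current_trace(i_pa, stim$sample_rate_hz)
}

#' Triangular moving-average filter
#'
#' Smooths a current trace by convolution with a symmetric triangular kernel
#' of half-width `half_width` samples (`2 * half_width + 1` taps, linear
#' weights peaking at the centre, normalized to sum to one). With the default
#' half-width of six samples the kernel has 13 taps. Edges are handled by
#' reflect padding so the output has the same length as the input.
#'
#' @param trace A [current_trace()].
#' @param half_width Kernel half-width in samples (>= 1).
#' @return Filtered [current_trace()].
#' @export
triangular_moving_average <- function(trace, half_width = 6) {
  stopifnot(inherits(trace, "current_trace"))
  if (!is_scalar_number(half_width) || half_width < 1) {
    stop("`half_width` must be >= 1")
  }
  half_width <- as.integer(half_width)
  x <- trace$samples_pa
  n <- length(x)
  n_taps <- 2L * half_width + 1L
  if (n < n_taps) {
    stop("trace is shorter than the filter kernel")
  }
  w <- c(seq_len(half_width + 1L), rev(seq_len(half_width)))
  w <- w / sum(w)
  # reflect padding (no sample repetition at the boundary)
  pad_l <- x[(half_width + 1L):2L]
  pad_r <- x[(n - 1L):(n - half_width)]
  xp <- c(pad_l, x, pad_r)
  y <- stats::filter(xp, w, method = "convolution", sides = 2L)
  y <- as.numeric(y)[(half_width + 1L):(half_width + n)]
  current_trace(y, trace$sample_rate_hz, trace$t0)
}

#' Exponential settling filter
#'
#' First-order exponential smoother (unity DC gain) with time constant `tau_s`,
#' applied to suppress the capacitive transients left by uncompensated stray
#' capacitance so that the peak-to-peak of the filtered trace reflects the
#' resistive plateau. The default time constant is 1 ms.
#'
#' @param trace A [current_trace()].
#' @param tau_s Time constant in seconds (> 0).
#' @return Filtered [current_trace()].
#' @export
exponential_settle_filter <- function(trace, tau_s = 0.001) {
  stopifnot(inherits(trace, "current_trace"))
  stopifnot_scalar(tau_s, "tau_s", positive = TRUE)
  x <- trace$samples_pa
  dt <- 1 / trace$sample_rate_hz
  alpha <- 1 - exp(-dt / tau_s)
  y <- stats::filter(alpha * x, 1 - alpha, method = "recursive",
                     init = x[1])
  current_trace(as.numeric(y), trace$sample_rate_hz, trace$t0)
}

#' Estimate pipette resistance from a seal-test trace
#'
#' Resistance is the applied peak-to-peak voltage divided by the peak-to-peak
#' amplitude of the measured current (mV / nA = MOhm). The peak-to-peak
#' current of each stimulus cycle is measured as the difference between the
#' plateau means over the last 25% of each half-cycle (after the capacitive
#' transients have settled); the median across cycles is used.
#'
#' @param stim The [square_wave_stimulus()] that produced the trace.
#' @param trace A [current_trace()] spanning at least one full cycle.
#' @return An object of class `resistance_estimate` with fields
#'   `value_mohm`, `timestamp_s` and `n_cycles_used`.
#' @export
#' @examples
#' stim <- square_wave_stimulus()
#' tr <- synthesize_current(stim, electrode_circuit(5))
#' estimate_resistance(stim, tr)$value_mohm  # 5
estimate_resistance <- function(stim, trace) {
  stopifnot(inherits(stim, "square_wave_stimulus"),
            inherits(trace, "current_trace"))
  spc <- round(trace$sample_rate_hz / stim$frequency_hz)  # samples per cycle
  n_cycles <- length(trace$samples_pa) %/% spc
  if (n_cycles < 1L) {
    stop("trace must span at least one full stimulus cycle")
  }
  half <- spc %/% 2L
  plateau_idx <- function(start, len) {
    # last 25% of a half-cycle beginning at `start` (1-based, length `len`)
    from <- start + ceiling(0.75 * len)
    seq(from, start + len - 1L)
  }
  pp <- vapply(seq_len(n_cycles) - 1L, function(k) {
    base <- k * spc + 1L
    hi <- mean(trace$samples_pa[plateau_idx(base, half)])
    lo <- mean(trace$samples_pa[plateau_idx(base + half, spc - half)])
    hi - lo
  }, numeric(1))
  pp_pa <- stats::median(pp)
  if (!is.finite(pp_pa) || pp_pa <= 0) {
    abort_typed(
      "measurement_failure",
      "zero peak-to-peak current: amplifier or valve fault, not a resistance"
    )
  }
  structure(
    list(
      value_mohm = stim$peak_to_peak_mv / (pp_pa / 1000),
      timestamp_s = trace$t0 + length(trace$samples_pa) / trace$sample_rate_hz,
      n_cycles_used = n_cycles
    ),
    class = "resistance_estimate"
  )
}

#' Five-measurement averaged resistance
#'
#' Every resistance value consumed by the control algorithm is the arithmetic
#' mean of five consecutive resistance measurements.
#'
#' @param history Exactly five resistance values in MOhm, or a list of five
#'   `resistance_estimate` objects.
#' @return Mean resistance in MOhm.
#' @export
averaged_resistance <- function(history) {
  if (is.list(history)) {
    history <- vapply(history, function(e) {
      if (inherits(e, "resistance_estimate")) e$value_mohm else as.numeric(e)
    }, numeric(1))
  }
  if (length(history) != 5L || !is.numeric(history)) {
    abort_typed("insufficient_history",
                "exactly 5 consecutive resistance measurements are required")
  }
  mean(history)
}

#' Export a current trace as CSV
#'
#' Writes `time_s,current_pA` with deterministic 6-significant-digit
#' formatting.
#'
#' @param trace A [current_trace()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  t <- trace$t0 + (seq_along(trace$samples_pa) - 1) / trace$sample_rate_hz
  lines <- c(
    "time_s,current_pA",
    sprintf("%.6g,%.6g", t, trace$samples_pa)
  )
  writeLines(lines, path)
  invisible(path)
}
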