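#' Synthetic I-V point set for reversal-potential estimation
#'
#' Currents follow `I = g * (V - E_true) + noise` over the given voltage
#' steps, the structure of a GABA-A I-V protocol (-80 to -40 mV in 5- or
#' 10-mV increments).
#'
#' @param e_true_mV True reversal potential.
#' @param g_nS Slope conductance (> 0).
#' @param v_steps_mV Command voltages (default `seq(-80, -40, 10)`).
#' @param noise_sd_pA Gaussian noise SD on the currents (default 0).
#' @return Data.frame with columns `v_mV`, `i_pA`.
#' @export
generate_iv_curve <- function(e_true_mV, g_nS, v_steps_mV = seq(-80, -40, 10),
                              noise_sd_pA = 0) {
  if (g_nS <= 0) stop("conductance must be positive")
  i <- g_nS * (v_steps_mV - e_true_mV) +
    stats::rnorm(length(v_steps_mV), sd = noise_sd_pA)
  data.frame(v_mV = v_steps_mV, i_pA = i)
}

#' Ideal capacitive transient of a voltage step
#'
#' RC response to a rectangular step dV across the series resistance:
#' `I(t) = (dV/Rs) * exp(-t / (Rs*C))`, sampled from the peak at t = 0.
#' With Rs = 10 MOhm, C = 150 pF and dV = -10 mV the peak current is -1 nA
#' and the total charge -1.5 pC.
#'
#' @param rs_MOhm Series resistance (> 0).
#' @param c_pF Cell capacitance (> 0).
#' @param dV_mV Step amplitude (default -10).
#' @param fs_hz Sampling rate (default 10000).
#' @param duration_s Trace length (default 0.05, i.e. many time constants).
#' @return Numeric current trace in pA.
#' @export
generate_rc_transient <- function(rs_MOhm, c_pF, dV_mV = -10, fs_hz = 10000,
                                  duration_s = 0.05) {
  if (rs_MOhm <= 0 || c_pF <= 0)
    stop("configuration error: Rs and C must be positive")
  tau_s <- rs_MOhm * c_pF * 1e-6          # MOhm * pF = us
  t <- seq(0, duration_s, by = 1 / fs_hz)
  1000 * (dV_mV / rs_MOhm) * exp(-t / tau_s)   # mV/MOhm = nA -> pA
}

#' Pair of holding-current traces with a planted tonic shift
#'
#' Gaussian holding-current noise around `i_hold_pA` (before) and
#' `i_hold_pA + tonic_shift_pA` (during blocker). Optionally superimposes
#' inward synaptic-event deflections (exponential decays at a Poisson rate)
#' on either trace, emulating the phasic-event tail that makes the histogram
#' mode, not the mean, the right holding-current estimator.
#'
#' @param i_hold_pA Holding current of the "before" trace.
#' @param tonic_shift_pA Planted outward shift (positive = less negative
#'   holding current during the blocker).
#' @param noise_sd_pA Gaussian noise SD (default 5).
#' @param duration_s Per-trace length (default 20 s).
#' @param fs_hz Sampling rate (default 10000).
#' @param event_rate_hz_before,event_rate_hz_during Poisson rates of
#'   synaptic deflections (default 0).
#' @param event_amp_pA Event peak amplitude, inward (default -40).
#' @param event_tau_s Event decay time constant (default 0.02).
#' @return List with `before` and `during` traces (pA).
#' @export
generate_holding_traces <- function(i_hold_pA, tonic_shift_pA,
                                    noise_sd_pA = 5, duration_s = 20,
                                    fs_hz = 10000,
                                    event_rate_hz_before = 0,
                                    event_rate_hz_during = 0,
                                    event_amp_pA = -40, event_tau_s = 0.02) {
  n <- round(duration_s * fs_hz)
  ev_wave <- event_amp_pA *
    exp(-seq(0, 8 * event_tau_s, by = 1 / fs_hz) / event_tau_s)
  mk <- function(level, rate) {
    tr <- stats::rnorm(n, mean = level, sd = noise_sd_pA)
    if (rate > 0) {
      times <- dead_time_train(0, duration_s - 10 * event_tau_s, rate,
                               2 * event_tau_s)
      tr <- add_at(tr, times, fs_hz, ev_wave)
    }
    tr
  }
  list(before = mk(i_hold_pA, event_rate_hz_before),
       during = mk(i_hold_pA + tonic_shift_pA, event_rate_hz_during))
}

#' Generate the full set of patch-clamp fixtures
#'
#' Convenience wrapper bundling [generate_iv_curve()] (somatic and dendritic
#' point sets), [generate_rc_transient()] and [generate_holding_traces()]
#' under a single seed.
#'
#' @param e_soma_mV,e_dendrite_mV True reversal potentials (default -55.5
#'   and -61, a somatodendritic gradient of 5.5 mV).
#' @param g_nS Slope conductance (default 1).
#' @param noise_sd_pA I-V current noise (default 0).
#' @param rs_MOhm,c_pF,dV_mV Passive-properties fixture (defaults 10, 150,
#'   -10).
#' @param i_hold_pA,tonic_shift_pA Holding-trace fixture (defaults -200, 30).
#' @param seed Integer seed.
#' @return List with `iv_soma`, `iv_dendrite`, `transient`, `holding`.
#' @export
generate_patch_fixtures <- function(e_soma_mV = -55.5, e_dendrite_mV = -61,
                                    g_nS = 1, noise_sd_pA = 0,
                                    rs_MOhm = 10, c_pF = 150, dV_mV = -10,
                                    i_hold_pA = -200, tonic_shift_pA = 30,
                                    seed = 1L) {
  set.seed(seed)
  list(iv_soma = generate_iv_curve(e_soma_mV, g_nS,
                                   noise_sd_pA = noise_sd_pA),
       iv_dendrite = generate_iv_curve(e_dendrite_mV, g_nS,
                                       noise_sd_pA = noise_sd_pA),
       transient = generate_rc_transient(rs_MOhm, c_pF, dV_mV),
       holding = generate_holding_traces(i_hold_pA, tonic_shift_pA))
}

#' Generate a hierarchical paired outcome table with known truth
#'
#' Simulates the study's data structure: patients contribute several units
#' (slices or cells), each measured at baseline and under treatment, with
#' `y = alpha + beta * post + b_patient + eps`, `b ~ N(0, between_sd^2)`,
#' `eps ~ N(0, within_sd^2)`. The baseline covariate recorded per unit is
#' its baseline-period outcome. The true intraclass correlation
#' `between^2 / (between^2 + within^2)` is attached as an attribute.
#'
#' @param n_patients Number of patients (>= 2).
#' @param units_per_patient Units (slices/cells) per patient.
#' @param true_effect Treatment effect beta.
#' @param between_sd,within_sd Patient-level and residual SDs (>= 0).
#' @param alpha Grand mean of the baseline period (default 0).
#' @param seed Integer seed.
#' @return Data.frame (class `hierarchical_dataset`) in long format with
#'   columns `patient_id`, `unit_id`, `period`, `outcome`,
#'   `baseline_covariate`; attributes `true_effect`, `true_icc`.
#' @export
generate_hierarchical_dataset <- function(n_patients, units_per_patient,
                                          true_effect, between_sd, within_sd,
                                          alpha = 0, seed = 1L) {
  if (n_patients < 2) stop("need n_patients >= 2")
  if (between_sd < 0 || within_sd < 0) stop("SDs must be >= 0")
  set.seed(seed)
  b <- stats::rnorm(n_patients, sd = between_sd)
  rows <- expand.grid(unit = seq_len(units_per_patient),
                      patient = seq_len(n_patients))
  base <- alpha + b[rows$patient] +
    stats::rnorm(nrow(rows), sd = within_sd)
  treat <- alpha + true_effect + b[rows$patient] +
    stats::rnorm(nrow(rows), sd = within_sd)
  unit_id <- sprintf("p%02d_u%02d", rows$patient, rows$unit)
  out <- data.frame(
    patient_id = rep(sprintf("p%02d", rows$patient), 2),
    unit_id = rep(unit_id, 2),
    period = rep(c("baseline", "treatment"), each = nrow(rows)),
    outcome = c(base, treat),
    baseline_covariate = rep(base, 2))
  attr(out, "true_effect") <- true_effect
  attr(out, "true_icc") <- if (between_sd + within_sd == 0) NA_real_ else
    between_sd^2 / (between_sd^2 + within_sd^2)
  class(out) <- c("hierarchical_dataset", "data.frame")
  out
}
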