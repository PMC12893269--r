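#' Ionic conditions for GABA-A reversal calculations
#'
#' Bundles the chloride and bicarbonate concentrations, the relative
#' HCO3-/Cl- permeability of the GABA-A channel, and the bath temperature.
#' Defaults correspond to whole-cell recording at 32 C with an intracellular
#' bicarbonate set by the Henderson-Hasselbalch equation (pHi 7.2, pHo 7.4,
#' 26 mM extracellular HCO3-) and a permeability ratio of 0.3.
#'
#' @param cl_i_mM Intracellular (pipette) Cl- in mM.
#' @param cl_o_mM Extracellular Cl- in mM.
#' @param hco3_i_mM Intracellular HCO3- in mM; default from
#'   [hh_bicarbonate()] at the stated pH values.
#' @param hco3_o_mM Extracellular HCO3- in mM (default 26).
#' @param perm_ratio P_HCO3 / P_Cl (default 0.3).
#' @param temperature_K Absolute temperature (default 305.15 K = 32 C).
#' @param ph_i,ph_o Intra-/extracellular pH (recorded for provenance).
#' @return List of class `ion_conditions`.
#' @export
ion_conditions <- function(cl_i_mM, cl_o_mM, hco3_i_mM = NULL,
                           hco3_o_mM = 26, perm_ratio = 0.3,
                           temperature_K = 305.15, ph_i = 7.2, ph_o = 7.4) {
  if (is.null(hco3_i_mM)) hco3_i_mM <- hh_bicarbonate(ph_i, ph_o, hco3_o_mM)
  x <- list(cl_i_mM = cl_i_mM, cl_o_mM = cl_o_mM, hco3_i_mM = hco3_i_mM,
            hco3_o_mM = hco3_o_mM, perm_ratio = perm_ratio,
            temperature_K = temperature_K, ph_i = ph_i, ph_o = ph_o)
  conc <- c(x$cl_i_mM, x$cl_o_mM, x$hco3_i_mM, x$hco3_o_mM)
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (x$perm_ratio < 0) stop("perm_ratio must be >= 0")
  if (x$temperature_K <= 0) stop("temperature must be positive")
  class(x) <- "ion_conditions"
  x
}

# RT/F in mV at temperature T (Kelvin); gas constant and Faraday from CODATA
rt_over_f_mV <- function(temperature_K) {
  1000 * 8.31446261815324 * temperature_K / 96485.33212331
}

#' Intracellular bicarbonate from the Henderson-Hasselbalch equation
#'
#' Under the constant-pCO2 assumption the intracellular bicarbonate follows
#' from the extracellular one and the pH gradient:
#' `hco3_i = hco3_o * 10^(ph_i - ph_o)`.
#' At pHi 7.2 / pHo 7.4 / 26 mM this evaluates to 16.41 mM. (A value of
#' 16.38 mM is sometimes quoted for the same inputs; it corresponds to a
#' rounded power-of-ten factor. This function always returns the exact
#' evaluation.)
#'
#' @param ph_i,ph_o Intra- and extracellular pH, in (0, 14).
#' @param hco3_o_mM Extracellular bicarbonate in mM.
#' @return Intracellular bicarbonate in mM.
#' @export
hh_bicarbonate <- function(ph_i, ph_o, hco3_o_mM) {
  if (ph_i <= 0 || ph_i >= 14 || ph_o <= 0 || ph_o >= 14)
    stop("pH values must lie in (0, 14)")
  if (hco3_o_mM <= 0) stop("hco3_o_mM must be positive")
  hco3_o_mM * 10^(ph_i - ph_o)
}

#' GHK reversal potential of a Cl-/HCO3--permeable channel
#'
#' Goldman-Hodgkin-Katz voltage equation for the GABA-A channel, permeable
#' to the anions Cl- and HCO3- with relative permeability `perm_ratio`
#' (P_HCO3/P_Cl). In the anion convention used here
#' `E = (RT/F) * ln((cl_i + r*hco3_i) / (cl_o + r*hco3_o))` (millivolts).
#' With `perm_ratio = 0` this reduces to the Cl- Nernst potential.
#'
#' @param cond An [ion_conditions()] object.
#' @return Reversal potential in mV.
#' @export
ghk_reversal <- function(cond) {
  stopifnot(inherits(cond, "ion_conditions"))
  r <- cond$perm_ratio
  rt_over_f_mV(cond$temperature_K) *
    log((cond$cl_i_mM + r * cond$hco3_i_mM) /
        (cond$cl_o_mM + r * cond$hco3_o_mM))
}

#' Invert the GHK equation for intracellular chloride
#'
#' Given a reversal potential and all conditions except `cl_i_mM`, solve the
#' GHK equation algebraically for the intracellular chloride concentration.
#' This is the operation used to express a somatodendritic E_GABA(A) gradient
#' as a chloride concentration difference.
#'
#' @param e_mV Reversal potential in mV.
#' @param cond An [ion_conditions()] object; its `cl_i_mM` is ignored.
#' @return Intracellular chloride in mM.
#' @export
invert_ghk_cl <- function(e_mV, cond) {
  stopifnot(inherits(cond, "ion_conditions"))
  r <- cond$perm_ratio
  cl_i <- (cond$cl_o_mM + r * cond$hco3_o_mM) *
    exp(e_mV / rt_over_f_mV(cond$temperature_K)) - r * cond$hco3_i_mM
  if (cl_i <= 0)
    stop(sprintf(paste0("e_mV = %.3f implies [Cl-]i = %.4f mM <= 0; the most ",
                        "negative admissible reversal for these conditions ",
                        "is %.3f mV"),
                 e_mV, cl_i,
                 rt_over_f_mV(cond$temperature_K) *
                   log(r * cond$hco3_i_mM /
                       (cond$cl_o_mM + r * cond$hco3_o_mM))))
  cl_i
}

#' Reversal potential from an I-V point set
#'
#' Fits an ordinary least-squares line through (Vp, I) pairs from voltage-step
#' experiments and reports the zero-current crossing `E = -intercept/slope`,
#' the slope conductance (nS when I is in pA and V in mV), the driving force
#' relative to a resting potential, and the residual standard deviation.
#' A non-positive slope is non-physiological for a GABA-A conductance: a zero
#' slope is an error, a negative slope returns a result flagged
#' `negative_slope`.
#'
#' @param v_mV,i_pA Numeric vectors of equal length (>= 2 distinct voltages);
#'   voltages are assumed already corrected for the liquid junction potential.
#' @param v_rest_mV Resting/holding potential used for the driving force
#'   (default NA: no driving force reported).
#' @param site Label, "soma" or "dendrite".
#' @return List of class `reversal_estimate` with fields `e_gaba_mV`,
#'   `df_mV`, `conductance_nS`, `residual_sd_pA`, `site`, `flag`.
#' @export
estimate_reversal_from_iv <- function(v_mV, i_pA, v_rest_mV = NA_real_,
                                      site = c("soma", "dendrite")) {
  site <- match.arg(site)
  if (length(v_mV) != length(i_pA)) stop("v_mV and i_pA lengths differ")
  if (length(unique(v_mV)) < 2) stop("need >= 2 distinct voltages")
  fit <- stats::lm(i_pA ~ v_mV)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) ||
      abs(slope) * diff(range(v_mV)) < 1e-9 * (1 + max(abs(i_pA))))
    stop("zero slope: currents do not depend on voltage")
  flag <- if (slope < 0) "negative_slope" else "ok"
  e <- -intercept / slope
  structure(list(e_gaba_mV = e, df_mV = e - v_rest_mV,
                 conductance_nS = slope,
                 residual_sd_pA = sqrt(mean(stats::residuals(fit)^2)),
                 site = site, flag = flag),
            class = "reversal_estimate")
}

#' @export
print.reversal_estimate <- function(x, ...) {
  cat(sprintf("E_GABA(A) at %s: %.2f mV (g = %.3f nS%s)\n", x$site,
              x$e_gaba_mV, x$conductance_nS,
              if (x$flag != "ok") paste0(", FLAG: ", x$flag) else ""))
  if (is.finite(x$df_mV)) cat(sprintf("  driving force: %.2f mV\n", x$df_mV))
  invisible(x)
}

#' Passive properties from a capacitive transient
#'
#' From the slow capacitive transient evoked by a rectangular voltage step:
#' series resistance from the peak current, `Rs = dV / I_peak`, and cell
#' capacitance from the integral of the transient, `C = Q / dV` with
#' `Q = trapezoidal integral of I dt`. Signs are handled so that both
#' estimates are positive for a passive cell.
#'
#' @param trace_pA Baseline-subtracted current trace (pA), starting at the
#'   transient peak.
#' @param fs_hz Sampling rate.
#' @param dV_mV Step amplitude in mV (nonzero; e.g. -10).
#' @return List with `capacity_pF` and `rs_MOhm`.
#' @export
rc_from_transient <- function(trace_pA, fs_hz, dV_mV) {
  if (dV_mV == 0) stop("dV_mV must be nonzero")
  if (!length(trace_pA) || all(trace_pA == 0))
    stop("transient trace is empty or all-zero")
  i_peak <- trace_pA[which.max(abs(trace_pA))]
  # pA * s = pC; trapezoid
  q_pC <- (sum(trace_pA) - (trace_pA[1] + trace_pA[length(trace_pA)]) / 2) /
    fs_hz
  rs <- 1000 * dV_mV / i_peak          # mV / nA = MOhm
  cap <- 1000 * q_pC / dV_mV           # pC / mV = nF -> pF
  if (rs <= 0 || cap <= 0)
    warning("non-positive Rs or C estimate; check trace polarity vs dV")
  list(capacity_pF = cap, rs_MOhm = rs)
}

#' Series-resistance stability check
#'
#' A recording passes quality control iff the series resistance never changed
#' by more than 20% relative to its first value ("exceeded" is strict, so a
#' change of exactly 20% still passes).
#'
#' @param rs_series Numeric vector of Rs values over the recording (>= 2).
#' @param max_change Allowed relative change (default 0.20).
#' @return Logical: TRUE if the recording passes.
#' @export
qc_series_resistance <- function(rs_series, max_change = 0.20) {
  if (length(rs_series) < 2) stop("need at least 2 Rs values")
  if (rs_series[1] <= 0) stop("initial Rs must be positive")
  max(abs(rs_series - rs_series[1])) / rs_series[1] <= max_change
}

# Mode of an all-point histogram with parabolic interpolation around the
# modal bin; bin grid anchored at the data minimum so the estimate is exactly
# equivariant under adding a constant to the trace.
histogram_mode <- function(x, bin) {
  lo <- min(x) - bin / 2
  k <- ceiling((max(x) - lo) / bin)
  counts <- tabulate(pmin(floor((x - lo) / bin) + 1L, k), nbins = k)
  centers <- lo + (seq_len(k) - 0.5) * bin
  i <- which.max(counts)
  mode <- centers[i]
  if (i > 1 && i < k) {
    cm <- counts[i - 1]; c0 <- counts[i]; cp <- counts[i + 1]
    den <- cm - 2 * c0 + cp
    if (den < 0) mode <- centers[i] + 0.5 * bin * (cm - cp) / den
  }
  # ambiguity: another local maximum within 5% of the modal count
  is_peak <- counts >= c(-Inf, counts[-k]) & counts >= c(counts[-1], -Inf)
  peaks <- which(is_peak & abs(centers - centers[i]) > 2 * bin)
  ambiguous <- any(counts[peaks] >= 0.95 * counts[i])
  list(mode = mode, ambiguous = ambiguous)
}

#' Tonic current from all-point current histograms
#'
#' The holding current of each trace is estimated as the mode of its
#' all-point histogram (default 1-pA bins, parabolic interpolation around
#' the modal bin); the tonic current is the difference of the two modes
#' (positive for an outward shift upon GABA-A blockade). The histogram mode,
#' unlike the mean, is robust to the skewed tail contributed by phasic
#' synaptic events. If a capacitance is supplied the current density
#' (pA/pF) is reported; if series resistances are supplied they are checked
#' with [qc_series_resistance()].
#'
#' @param trace_before_pA,trace_during_pA Holding-current traces (pA) before
#'   and during blocker application; at least 10 s each.
#' @param fs_hz Sampling rate.
#' @param bin_pA Histogram bin width (default 1).
#' @param capacity_pF Optional cell capacitance.
#' @param rs_before_MOhm,rs_during_MOhm Optional series resistances.
#' @return List of class `tonic_result` with holding currents, `tonic_pA`,
#'   `density_pA_per_pF`, Rs values, `qc_pass`, and an `ambiguous` flag (with
#'   a warning) when a histogram has two comparable peaks.
#' @export
tonic_from_histogram <- function(trace_before_pA, trace_during_pA, fs_hz,
                                 bin_pA = 1, capacity_pF = NA_real_,
                                 rs_before_MOhm = NA_real_,
                                 rs_during_MOhm = NA_real_) {
  if (bin_pA <= 0) stop("bin_pA must be positive")
  if (length(trace_before_pA) < 10 * fs_hz ||
      length(trace_during_pA) < 10 * fs_hz)
    stop("holding-current traces must be at least 10 s long")
  mb <- histogram_mode(trace_before_pA, bin_pA)
  md <- histogram_mode(trace_during_pA, bin_pA)
  if (mb$ambiguous || md$ambiguous)
    warning("all-point histogram has two modes of comparable height; ",
            "holding-current estimate is ambiguous")
  tonic <- md$mode - mb$mode
  qc <- if (is.finite(rs_before_MOhm) && is.finite(rs_during_MOhm))
    qc_series_resistance(c(rs_before_MOhm, rs_during_MOhm)) else NA
  structure(list(i_hold_before_pA = mb$mode, i_hold_during_pA = md$mode,
                 tonic_pA = tonic,
                 density_pA_per_pF = tonic / capacity_pF,
                 capacity_pF = capacity_pF,
                 rs_before_MOhm = rs_before_MOhm,
                 rs_during_MOhm = rs_during_MOhm,
                 qc_pass = qc,
                 ambiguous = mb$ambiguous || md$ambiguous),
            class = "tonic_result")
}

#' @export
print.tonic_result <- function(x, ...) {
  cat(sprintf("Tonic current: %.2f pA (holding %.2f -> %.2f pA)\n",
              x$tonic_pA, x$i_hold_before_pA, x$i_hold_during_pA))
  if (is.finite(x$density_pA_per_pF))
    cat(sprintf("  density: %.3f pA/pF (C = %.1f pF)\n",
                x$density_pA_per_pF, x$capacity_pF))
  if (!is.na(x$qc_pass))
    cat("  Rs QC:", if (x$qc_pass) "pass" else "FAIL", "\n")
  invisible(x)
}
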