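#' Maxed-interval grouping parameters
#'
#' Parameters of the maxed-interval burst-detection scheme adapted to ILE
#' detection on IC traces. All values are in seconds except
#' `min_discharges`. `ile_min_duration_s` separates ILEs from shorter
#' synchronous events and must be at least `min_event_duration_s`.
#' `max_end_isi_s >= max_begin_isi_s` is deliberately not required.
#'
#' Defaults (2 s begin/end ISI, 5 s merge gap, 5 s / 5 discharges minimum,
#' 10 s ILE threshold) place ILEs with ~20 s duration and ~3 Hz internal
#' discharge rates well inside the detectable region.
#'
#' @param max_begin_isi_s Largest inter-discharge interval that can open an
#'   event.
#' @param max_end_isi_s Largest interval that extends an open event.
#' @param min_ibi_s Events separated by less than this gap are merged.
#' @param min_event_duration_s Shorter events are discarded.
#' @param min_discharges Events with fewer discharges are discarded.
#' @param ile_min_duration_s Events at least this long are ILEs.
#' @return List of class `max_interval_params`.
#' @export
max_interval_params <- function(max_begin_isi_s = 2, max_end_isi_s = 2,
                                min_ibi_s = 5, min_event_duration_s = 5,
                                min_discharges = 5, ile_min_duration_s = 10) {
  p <- as.list(environment())
  if (any(unlist(p) <= 0)) stop("all parameters must be positive")
  if (ile_min_duration_s < min_event_duration_s)
    stop("ile_min_duration_s must be >= min_event_duration_s")
  class(p) <- "max_interval_params"
  p
}

#' Detect discharges on an IC trace
#'
#' Threshold crossings of the absolute trace at `k_mad` robust standard
#' deviations (1.4826 x median absolute deviation); each contiguous
#' suprathreshold run contributes its absolute peak, and peaks closer than
#' the refractory window to the previous accepted one are collapsed.
#'
#' @param trace Numeric IC trace (finite).
#' @param fs_hz Sampling rate.
#' @param k_mad Threshold in robust SDs (default 6, placing the false-crossing
#'   rate over a whole multi-IC recording well below one).
#' @param refractory_s Collapse window (default 0.05 s).
#' @return Sorted numeric vector of discharge times in seconds (empty for an
#'   empty or featureless trace).
#' @export
detect_discharges <- function(trace, fs_hz, k_mad = 6, refractory_s = 0.05) {
  if (k_mad <= 0) stop("k_mad must be positive")
  if (!length(trace)) return(numeric(0))
  if (!all(is.finite(trace))) stop("trace must be finite")
  thr <- k_mad * stats::mad(trace)
  if (thr <= 0) thr <- .Machine$double.xmin  # noiseless trace: any deflection
  above <- abs(trace) >= thr
  if (!any(above)) return(numeric(0))
  idx <- which(above)
  run_start <- c(TRUE, diff(idx) > 1)
  run_id <- cumsum(run_start)
  peaks <- vapply(split(idx, run_id), function(ii)
    ii[which.max(abs(trace[ii]))], numeric(1))
  times <- (sort(peaks) - 1) / fs_hz
  # collapse within refractory window
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_s) { keep[i] <- TRUE; last <- times[i] }
  }
  unname(times[keep])
}

#' Group discharges into events with the maxed-interval method
#'
#' Classic maxed-interval semantics: an event opens at the first
#' inter-spike interval (ISI) not exceeding `max_begin_isi_s`, extends while
#' ISIs do not exceed `max_end_isi_s`, events separated by a gap smaller
#' than `min_ibi_s` are merged, and events shorter than
#' `min_event_duration_s` or with fewer than `min_discharges` members are
#' then discarded. Events are disjoint and sorted.
#'
#' @param discharges Sorted ascending numeric vector of discharge times.
#' @param p A [max_interval_params()].
#' @return Data.frame with columns `start_s`, `end_s`, `n_discharges` and a
#'   list-column `discharge_times`.
#' @export
group_maxed_interval <- function(discharges, p = max_interval_params()) {
  if (is.unsorted(discharges)) stop("discharges must be sorted ascending")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_discharges = integer(0),
                      discharge_times = I(list()))
  n <- length(discharges)
  if (n < 2) return(empty)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i < n) {
    isi <- discharges[i + 1L] - discharges[i]
    if (isi <= p$max_begin_isi_s) {
      s <- i
      i <- i + 1L
      while (i < n && discharges[i + 1L] - discharges[i] <= p$max_end_isi_s)
        i <- i + 1L
      starts <- c(starts, s); ends <- c(ends, i)
      i <- i + 1L
    } else i <- i + 1L
  }
  if (!length(starts)) return(empty)
  # merge events whose gap is smaller than min_ibi
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(starts) > 1) for (j in 2:length(starts)) {
    gap <- discharges[starts[j]] - discharges[me]
    if (gap < p$min_ibi_s) me <- ends[j]
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- starts[j]; me <- ends[j] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  dur <- discharges[out_e] - discharges[out_s]
  cnt <- out_e - out_s + 1L
  ok <- dur >= p$min_event_duration_s & cnt >= p$min_discharges
  out_s <- out_s[ok]; out_e <- out_e[ok]
  data.frame(start_s = discharges[out_s], end_s = discharges[out_e],
             n_discharges = out_e - out_s + 1L,
             discharge_times = I(mapply(function(a, b) discharges[a:b],
                                        out_s, out_e, SIMPLIFY = FALSE)))
}

#' Classify grouped activity into ILEs and IILDs
#'
#' Events from [group_maxed_interval()] whose duration reaches
#' `ile_min_duration_s` become ILEs. All remaining discharges — members of
#' shorter synchronous events and isolated discharges — are clustered
#' (gap <= `max_begin_isi_s`) into IILDs, each holding one synchronous
#' discharge cluster. An IILD is flagged excluded (kept in the table but
#' ignored by the IILD outcome metrics) if it falls within
#' `postictal_exclusion_s` after any ILE of the same source, or — when
#' `iild_requires_ile_free_source` (the default, matching the rule that
#' analysed IILDs occur independently of ILEs) — whenever the source shows
#' any ILE at all.
#'
#' @param discharges Sorted discharge times of one source (IC).
#' @param p A [max_interval_params()].
#' @param postictal_exclusion_s Post-ILE exclusion window (default 60 s).
#' @param iild_requires_ile_free_source See above (default TRUE).
#' @param source Integer source label attached to the output (default 1).
#' @return Data.frame with columns `source`, `kind` ("ILE"/"IILD"),
#'   `start_s`, `end_s`, `n_discharges`, `onset_class` (filled by
#'   [classify_onset()], "unclassified" here), `excluded`, and list-column
#'   `discharge_times`.
#' @export
classify_events <- function(discharges, p = max_interval_params(),
                            postictal_exclusion_s = 60,
                            iild_requires_ile_free_source = TRUE,
                            source = 1L) {
  ev <- group_maxed_interval(discharges, p)
  is_ile <- (ev$end_s - ev$start_s) >= p$ile_min_duration_s
  iles <- ev[is_ile, , drop = FALSE]
  in_ile <- rep(FALSE, length(discharges))
  for (j in seq_len(nrow(iles)))
    in_ile <- in_ile | (discharges >= iles$start_s[j] &
                          discharges <= iles$end_s[j])
  rest <- discharges[!in_ile]
  cl_start <- numeric(0); cl_end <- numeric(0); cl_n <- integer(0)
  cl_times <- list()
  if (length(rest)) {
    grp <- cumsum(c(1, as.integer(diff(rest) > p$max_begin_isi_s)))
    for (g in split(rest, grp)) {
      cl_start <- c(cl_start, g[1]); cl_end <- c(cl_end, g[length(g)])
      cl_n <- c(cl_n, length(g)); cl_times <- c(cl_times, list(g))
    }
  }
  excl <- rep(FALSE, length(cl_start))
  if (nrow(iles)) {
    if (iild_requires_ile_free_source) excl[] <- TRUE
    else for (j in seq_len(nrow(iles)))
      excl <- excl | (cl_start > iles$end_s[j] &
                        cl_start <= iles$end_s[j] + postictal_exclusion_s)
  }
  rbind(
    if (nrow(iles)) data.frame(source = source, kind = "ILE",
                               start_s = iles$start_s, end_s = iles$end_s,
                               n_discharges = iles$n_discharges,
                               onset_class = "unclassified",
                               excluded = FALSE,
                               discharge_times = I(iles$discharge_times))
    else NULL,
    if (length(cl_start)) data.frame(source = source, kind = "IILD",
                                     start_s = cl_start, end_s = cl_end,
                                     n_discharges = cl_n,
                                     onset_class = "unclassified",
                                     excluded = excl,
                                     discharge_times = I(cl_times))
    else NULL,
    data.frame(source = integer(0), kind = character(0),
               start_s = numeric(0), end_s = numeric(0),
               n_discharges = integer(0), onset_class = character(0),
               excluded = logical(0), discharge_times = I(list())))
}

#' Classify the onset pattern of an ILE
#'
#' Inspects the first `window_s` seconds after onset: a low-amplitude
#' (< half the within-event RMS) segment with dominant frequency of at
#' least 10 Hz is a low-voltage-fast (LVF) onset; initial discharges whose
#' median amplitude exceeds 1.5x the within-event median discharge
#' amplitude mark a hypersynchronous onset; anything else (including a
#' window extending past the trace end) is unclassified.
#'
#' @param trace IC trace the event was detected on.
#' @param fs_hz Sampling rate.
#' @param start_s,end_s Event boundaries.
#' @param discharge_times Discharge times of the event.
#' @param window_s Onset window (default 2 s; events must have at least this
#'   much trace after onset).
#' @return One of "LVF", "hypersynchronous", "unclassified".
#' @export
classify_onset <- function(trace, fs_hz, start_s, end_s, discharge_times,
                           window_s = 2) {
  n <- length(trace)
  i0 <- max(1L, floor(start_s * fs_hz) + 1L)
  i_win <- floor((start_s + window_s) * fs_hz)
  i1 <- min(n, floor(end_s * fs_hz) + 1L)
  if (i_win > n) return("unclassified")
  win <- trace[i0:i_win]
  ev <- trace[i0:i1]
  rms_win <- sqrt(mean(win^2)); rms_ev <- sqrt(mean(ev^2))
  # dominant frequency of the onset window (excluding near-DC); the peak
  # must be prominent (>= 20x median spectral power) so that a flat or
  # noise-only window, whose maximum bin lands anywhere, is not called an
  # oscillation
  sp <- Mod(stats::fft(win - mean(win)))^2
  nf <- length(win)
  freqs <- (seq_len(floor(nf / 2)) ) * fs_hz / nf
  pw <- sp[2:(floor(nf / 2) + 1)]
  dom <- freqs[which.max(pw)]
  prominent <- max(pw) > 20 * stats::median(pw)
  if (rms_ev > 0 && rms_win < 0.5 * rms_ev && dom >= 10 && prominent)
    return("LVF")
  amp_at <- function(tt) abs(trace[pmin(n, floor(tt * fs_hz) + 1L)])
  init <- discharge_times[discharge_times <= start_s + window_s]
  if (length(init) && length(discharge_times) >= 2) {
    med_all <- stats::median(amp_at(discharge_times))
    if (med_all > 0 && stats::median(amp_at(init)) > 1.5 * med_all)
      return("hypersynchronous")
  }
  "unclassified"
}

#' Per-source outcome metrics for one analysis epoch
#'
#' Computes, for every source of the model, the four headline ILE outcome
#' measures within the epoch — number of ILEs normalised to a 20-min window,
#' mean ILE duration, mean within-ILE discharge frequency (per-ILE
#' n/duration averaged over ILEs), and the spatial extent (electrode count)
#' of the source — plus the frequency and spatial extent of retained
#' (non-excluded) IILDs. Epochs with no ILEs report 0 for count, duration
#' and frequency, with `had_activity` distinguishing sources that showed
#' any retained activity.
#'
#' @param events Event table (rbind of [classify_events()] over sources).
#' @param model The `source_model` the events were detected on.
#' @param epoch List or one-row data.frame with `label`, `start_s`, `end_s`.
#' @param theta Spatial-map threshold (default 0.2).
#' @return Data.frame, one row per source.
#' @export
summarize_epoch <- function(events, model, epoch, theta = 0.2) {
  len <- epoch$end_s - epoch$start_s
  if (!is.finite(len) || len <= 0) stop("epoch has non-positive length")
  out <- lapply(seq_len(model$n_ics), function(s) {
    in_ep <- events$source == s & events$start_s >= epoch$start_s &
      events$start_s < epoch$end_s
    ile <- events[in_ep & events$kind == "ILE", , drop = FALSE]
    iild <- events[in_ep & events$kind == "IILD" & !events$excluded, ,
                   drop = FALSE]
    ext <- length(spatial_map(model, s, theta))
    n_ile <- nrow(ile)
    dur <- if (n_ile) ile$end_s - ile$start_s else numeric(0)
    data.frame(
      source = s, epoch = epoch$label,
      n_ile_per_20min = n_ile * 1200 / len,
      mean_ile_duration_s = if (n_ile) mean(dur) else 0,
      within_ile_discharge_freq_hz =
        if (n_ile) mean(ile$n_discharges / dur) else 0,
      ile_spatial_extent_electrodes = if (n_ile) ext else 0L,
      iild_freq_hz = nrow(iild) / len,
      iild_spatial_extent_electrodes = if (nrow(iild)) ext else 0L,
      had_activity = n_ile > 0 || nrow(iild) > 0)
  })
  do.call(rbind, out)
}
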