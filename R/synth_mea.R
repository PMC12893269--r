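#' Configuration for the synthetic MEA recording generator
#'
#' Defaults reproduce the statistical structure of induced ictal-like
#' activity in neocortical slices on a 59-electrode grid: when present, ILEs
#' occur about 8.9 times per 20 min, last about 22.6 s, carry discharge
#' trains at about 3.1 per second, and span about 21 electrodes; 56% of ILEs
#' have a low-voltage-fast (LVF) onset and 44% a hypersynchronous onset, and
#' each ILE is preceded by sparse large-amplitude preictal discharges.
#' Isolated interictal-like discharges (IILDs) occur at about 0.08 per
#' second on a separate, ILE-free source. Background noise is 1/f (pink)
#' plus white at 10 uV SD per channel.
#'
#' @param fs_hz Sampling rate of the generated recording (default 10000).
#' @param epochs Data.frame (label, start_s, end_s); default one 20-min
#'   baseline epoch.
#' @param n_sources Number of ILE sources (default 1).
#' @param ile_per_20min,ile_duration_s,discharge_rate_hz Planted ILE rate,
#'   duration and within-ILE discharge rate.
#' @param n_active_electrodes Electrodes spanned by each ILE source.
#' @param lvf_fraction Fraction of ILEs with LVF onset (default 0.56).
#' @param onset_s Duration of the onset segment (default 2 s).
#' @param lvf_freq_hz,lvf_amp_uV LVF onset oscillation (15 Hz, 10 uV).
#' @param discharge_amp_uV Discharge amplitude on the source's peak
#'   electrode (default 100, i.e. 10x the noise SD).
#' @param preictal_factor Preictal discharges scale (default 2).
#' @param min_isi_s Dead time between discharges in a train (default 0.08 s,
#'   reflecting the ~20 ms discharge waveform plus network refractoriness).
#' @param iild_rate_hz Rate of isolated IILDs (default 0.08).
#' @param iild_extent_electrodes Electrodes spanned by the IILD source
#'   (default 8).
#' @param iild_on_separate_source Plant IILDs on their own ILE-free source
#'   (default TRUE).
#' @param noise_sd_uV,pink_fraction Per-channel noise SD and the fraction of
#'   noise variance that is 1/f.
#' @param effect Named list mapping epoch labels to multiplier vectors with
#'   any of `n_ile`, `duration`, `discharge_rate`, `extent`, `iild_rate`
#'   (default: all 1).
#' @param seed Integer seed; identical configs and seeds generate
#'   bit-identical recordings.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(fs_hz = 10000,
                         epochs = data.frame(label = "baseline",
                                             start_s = 0, end_s = 1200),
                         n_sources = 1,
                         ile_per_20min = 8.9, ile_duration_s = 22.6,
                         discharge_rate_hz = 3.1,
                         n_active_electrodes = 21,
                         lvf_fraction = 0.56, onset_s = 2,
                         lvf_freq_hz = 15, lvf_amp_uV = 10,
                         discharge_amp_uV = 100, preictal_factor = 2,
                         min_isi_s = 0.08,
                         iild_rate_hz = 0.08, iild_extent_electrodes = 8,
                         iild_on_separate_source = TRUE,
                         noise_sd_uV = 10, pink_fraction = 0.5,
                         effect = list(), seed = 1L) {
  cfg <- as.list(environment())
  if (ile_per_20min < 0 || discharge_rate_hz < 0 || iild_rate_hz < 0)
    stop("rates must be >= 0")
  if (any(epochs$end_s <= epochs$start_s)) stop("epoch durations must be > 0")
  class(cfg) <- "synth_config"
  cfg
}

# contiguous patch on the recording-electrode grid (breadth-first growth),
# weights falling off smoothly from 1 at the seed to ~0.3 at the rim
grow_source_map <- function(layout, n_active, seed_electrode) {
  rec <- recording_electrodes(layout)
  pos <- layout[rec, c("row", "col")]
  n_active <- min(n_active, length(rec))
  d2 <- (pos$row - pos$row[seed_electrode])^2 +
    (pos$col - pos$col[seed_electrode])^2
  sel <- order(d2, seq_along(d2))[seq_len(n_active)]  # ties broken by index
  d <- sqrt(d2[sel])
  w <- numeric(length(rec))
  dmax <- max(d)
  w[sel] <- if (dmax > 0) 0.3^(d / dmax) else 1
  w
}

# Poisson-like train with dead time delta: ISIs = delta + Exp(rate'),
# with rate' chosen so the mean ISI equals 1/rate
dead_time_train <- function(t0, t1, rate, delta) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  mean_isi <- 1 / rate
  if (mean_isi <= delta) delta <- 0.5 * mean_isi
  exp_rate <- 1 / (mean_isi - delta)
  out <- numeric(ceiling((t1 - t0) * rate * 2 + 20))
  t <- t0; k <- 0L
  repeat {
    if (t > t1) break
    k <- k + 1L; out[k] <- t
    t <- t + delta + stats::rexp(1, exp_rate)
  }
  out[seq_len(k)]
}

# biphasic discharge waveform (negative lobe first), duration_s long
discharge_waveform <- function(fs, amp, duration_s = 0.02) {
  n <- max(4L, round(duration_s * fs))
  -amp * sin(2 * pi * seq(0, n - 1) / n)
}

add_at <- function(trace, times, fs, wave) {
  n <- length(trace); m <- length(wave)
  for (t in times) {
    i0 <- floor(t * fs) + 1L
    i1 <- min(i0 + m - 1L, n)
    if (i0 <= n) trace[i0:i1] <- trace[i0:i1] + wave[seq_len(i1 - i0 + 1L)]
  }
  trace
}

pink_noise <- function(n) {
  # FFT-shaped 1/f amplitude spectrum (symmetric in +/- frequency), zero DC,
  # unit variance
  white <- stats::rnorm(n)
  f <- stats::fft(white)
  j <- 0:(n - 1)
  fidx <- pmin(j, n - j)
  shape <- ifelse(fidx == 0, 0, 1 / sqrt(fidx))
  x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

effect_mult <- function(cfg, label, what) {
  e <- cfg$effect[[label]]
  if (is.null(e) || is.null(e[[what]]) || is.na(e[[what]])) 1 else e[[what]]
}

#' Generate a synthetic MEA recording with known ground truth
#'
#' Builds, from a [synth_config()], a multichannel recording equal to the sum
#' over planted sources of (spatial map x source trace) plus pink+white
#' noise. Each ILE consists of preictal large-amplitude discharges, an onset
#' segment matching its onset class (LVF: low-amplitude 10-20 Hz oscillation;
#' hypersynchronous: repetitive discharges at about twice the train
#' amplitude), and a discharge train at the planted rate. Onset classes are
#' assigned in the planted proportion (rounded), so the class mix is exact.
#' IILDs are isolated single discharges on an ILE-free source.
#'
#' @param config A [synth_config()].
#' @return List with elements `recording` (an [mea_recording()]) and `truth`
#'   (class `mea_ground_truth`: `source_maps` (source x electrode weights),
#'   `events` data.frame with per-event discharge times, `planted_rates`,
#'   `effect`, `seed`).
#' @export
generate_recording <- function(config = synth_config()) {
  cfg <- config
  set.seed(cfg$seed)
  layout <- electrode_layout()
  n_ch <- 59L
  fs <- cfg$fs_hz
  total_s <- max(cfg$epochs$end_s)
  n <- round(total_s * fs)

  n_src <- cfg$n_sources + as.integer(cfg$iild_rate_hz > 0 &&
                                        cfg$iild_on_separate_source)
  # seeds spread over the grid: first random, later ones far from earlier
  rec_idx <- recording_electrodes(layout)
  pos <- layout[rec_idx, c("row", "col")]
  seeds <- integer(n_src)
  interior <- which(pos$row >= 1 & pos$row <= 6 & pos$col >= 1 & pos$col <= 6)
  seeds[1] <- sample(interior, 1)
  if (n_src > 1) for (s in 2:n_src) {
    dmin <- vapply(seq_len(nrow(pos)), function(i)
      min((pos$row[i] - pos$row[seeds[seq_len(s - 1)]])^2 +
            (pos$col[i] - pos$col[seeds[seq_len(s - 1)]])^2), numeric(1))
    seeds[s] <- which.max(dmin)
  }

  maps <- matrix(0, n_src, n_ch)
  events <- list()
  data <- matrix(0, n_ch, n)
  wave <- discharge_waveform(fs, cfg$discharge_amp_uV)
  ev_id <- 0L

  for (s in seq_len(cfg$n_sources)) {
    maps[s, ] <- grow_source_map(layout, cfg$n_active_electrodes, seeds[s])
    trace <- numeric(n)
    for (ei in seq_len(nrow(cfg$epochs))) {
      lab <- cfg$epochs$label[ei]
      e0 <- cfg$epochs$start_s[ei]; e1 <- cfg$epochs$end_s[ei]
      len <- e1 - e0
      n_ile <- round(cfg$ile_per_20min * len / 1200 *
                       effect_mult(cfg, lab, "n_ile"))
      dur <- cfg$ile_duration_s * effect_mult(cfg, lab, "duration")
      rate <- cfg$discharge_rate_hz * effect_mult(cfg, lab, "discharge_rate")
      if (n_ile == 0) next
      margin <- 12 + cfg$onset_s
      if (n_ile * (dur + margin) > len)
        stop("configuration error: ", n_ile, " ILEs of ", dur,
             " s (+ margins) exceed the ", len, " s epoch")
      slot <- len / n_ile
      starts <- e0 + (seq_len(n_ile) - 1) * slot + 10 +
        stats::runif(n_ile, 0, pmax(slot - dur - margin, 0))
      n_lvf <- round(n_ile * cfg$lvf_fraction)
      classes <- sample(c(rep("LVF", n_lvf), rep("hypersynchronous",
                                                 n_ile - n_lvf)))
      for (k in seq_len(n_ile)) {
        st <- starts[k]; en <- st + dur; cls <- classes[k]
        # preictal large-amplitude discharges, well separated (> 2 s ISI)
        pre_t <- st - c(9, 6, 3)
        pre_t <- pre_t[pre_t >= e0]
        trace <- add_at(trace, pre_t, fs, wave * cfg$preictal_factor)
        if (cls == "LVF") {
          i0 <- floor(st * fs) + 1L
          i1 <- min(floor((st + cfg$onset_s) * fs), n)
          tt <- (seq(i0, i1) - i0) / fs
          trace[i0:i1] <- trace[i0:i1] +
            cfg$lvf_amp_uV * sin(2 * pi * cfg$lvf_freq_hz * tt)
          disch <- dead_time_train(st + cfg$onset_s, en, rate, cfg$min_isi_s)
          trace <- add_at(trace, disch, fs, wave)
        } else {
          onset_t <- dead_time_train(st, st + cfg$onset_s, rate,
                                     cfg$min_isi_s)
          disch <- dead_time_train(st + cfg$onset_s, en, rate, cfg$min_isi_s)
          trace <- add_at(trace, onset_t, fs, wave * 1.8)
          trace <- add_at(trace, disch, fs, wave)
          disch <- c(onset_t, disch)
        }
        ev_id <- ev_id + 1L
        events[[ev_id]] <- data.frame(
          source = s, kind = "ILE", start_s = st, end_s = en,
          onset_class = cls, epoch = lab,
          n_discharges = length(disch),
          discharge_times = I(list(disch)))
      }
    }
    active <- which(maps[s, ] > 0)
    for (ch in active) data[ch, ] <- data[ch, ] + maps[s, ch] * trace
  }

  if (cfg$iild_rate_hz > 0) {
    s_iild <- if (cfg$iild_on_separate_source) n_src else 1L
    if (cfg$iild_on_separate_source)
      maps[s_iild, ] <- grow_source_map(layout, cfg$iild_extent_electrodes,
                                        seeds[s_iild])
    trace <- numeric(n)
    for (ei in seq_len(nrow(cfg$epochs))) {
      lab <- cfg$epochs$label[ei]
      rate <- cfg$iild_rate_hz * effect_mult(cfg, lab, "iild_rate")
      tt <- dead_time_train(cfg$epochs$start_s[ei] + 2,
                            cfg$epochs$end_s[ei] - 2, rate, 5)
      trace <- add_at(trace, tt, fs, wave)
      for (t in tt) {
        ev_id <- ev_id + 1L
        events[[ev_id]] <- data.frame(
          source = s_iild, kind = "IILD", start_s = t, end_s = t + 0.02,
          onset_class = "unclassified", epoch = lab, n_discharges = 1L,
          discharge_times = I(list(t)))
      }
    }
    active <- which(maps[s_iild, ] > 0)
    for (ch in active) data[ch, ] <- data[ch, ] + maps[s_iild, ch] * trace
  }

  if (cfg$noise_sd_uV > 0) {
    sd_pink <- cfg$noise_sd_uV * sqrt(cfg$pink_fraction)
    sd_white <- cfg$noise_sd_uV * sqrt(1 - cfg$pink_fraction)
    for (ch in seq_len(n_ch))
      data[ch, ] <- data[ch, ] + sd_pink * pink_noise(n) +
        stats::rnorm(n, sd = sd_white)
  }

  rec <- mea_recording(data, fs_hz = fs, layout = layout,
                       epochs = cfg$epochs)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(source = integer(), kind = character(), start_s = numeric(),
               end_s = numeric(), onset_class = character(),
               epoch = character(), n_discharges = integer(),
               discharge_times = I(list()))
  truth <- structure(
    list(source_maps = maps, events = ev,
         planted_rates = list(ile_per_20min = cfg$ile_per_20min,
                              ile_duration_s = cfg$ile_duration_s,
                              discharge_rate_hz = cfg$discharge_rate_hz,
                              iild_rate_hz = cfg$iild_rate_hz,
                              n_active_electrodes = cfg$n_active_electrodes),
         effect = cfg$effect, seed = cfg$seed),
    class = "mea_ground_truth")
  list(recording = rec, truth = truth)
}
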