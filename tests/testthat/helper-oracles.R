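# Independent reference implementations and small fixture builders used
# across the test files.

# Reference maxed-interval grouping, written as a literal transcription of
# the textbook procedure (explicit index bookkeeping, fixpoint merging)
# rather than the package's single-pass scan.
ref_maxed_interval <- function(t, p) {
  n <- length(t)
  evs <- list()
  i <- 1L
  while (i < n) {
    if (t[i + 1L] - t[i] <= p$max_begin_isi_s) {
      j <- i + 1L
      while (j < n && t[j + 1L] - t[j] <= p$max_end_isi_s) j <- j + 1L
      evs[[length(evs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  repeat {
    merged <- FALSE
    if (length(evs) > 1) for (k in seq_len(length(evs) - 1L)) {
      if (t[evs[[k + 1L]][1]] - t[evs[[k]][2]] < p$min_ibi_s) {
        evs[[k]] <- c(evs[[k]][1], evs[[k + 1L]][2])
        evs[[k + 1L]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  keep <- Filter(function(e)
    (t[e[2]] - t[e[1]]) >= p$min_event_duration_s &&
      (e[2] - e[1] + 1L) >= p$min_discharges, evs)
  lapply(keep, function(e) t[e[1]:e[2]])
}

# random discharge-time sequence mixing dense bursts with sparse background
random_discharge_seq <- function(n_max = 120) {
  n_burst <- sample(0:4, 1)
  t <- stats::runif(sample(0:20, 1), 0, 300)       # sparse background
  for (b in seq_len(n_burst)) {
    t0 <- stats::runif(1, 0, 280)
    t <- c(t, t0 + cumsum(stats::rexp(sample(3:30, 1), rate = 3)))
  }
  sort(t[seq_len(min(length(t), n_max))])
}

random_maxint_params <- function() {
  mind <- stats::runif(1, 0.2, 2)
  max_interval_params(max_begin_isi_s = stats::runif(1, 0.2, 2),
                      max_end_isi_s = stats::runif(1, 0.2, 3),
                      min_ibi_s = stats::runif(1, 0.5, 6),
                      min_event_duration_s = mind,
                      min_discharges = sample(2:6, 1),
                      ile_min_duration_s = mind + stats::runif(1, 0, 8))
}

# small recording: given channel x sample matrix at fs
quick_recording <- function(data, fs = 1000) {
  mea_recording(data, fs_hz = fs,
                epochs = data.frame(label = "baseline", start_s = 0,
                                    end_s = ncol(data) / fs))
}

# spiky (super-Gaussian) source trace for mixing tests
spiky_trace <- function(n, n_spikes, amp = 50) {
  s <- stats::rnorm(n, sd = 0.3)
  at <- sample(seq(10, n - 10), n_spikes)
  s[at] <- s[at] + amp * sample(c(-1, 1), n_spikes, replace = TRUE)
  s
}
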