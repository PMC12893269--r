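test_that("discharge detection finds planted spikes and respects refractory", {
  expect_length(detect_discharges(numeric(0), 1000), 0)
  expect_length(detect_discharges(rep(0, 5000), 1000), 0)
  tr <- rep(0, 4000)
  tr[c(1001, 2001, 3001)] <- -100      # spikes at 1, 2, 3 s (fs 1000)
  d <- detect_discharges(tr, 1000)
  expect_equal(d, c(1, 2, 3), tolerance = 1e-3)
  tr2 <- rep(0, 2000)
  tr2[c(501, 511)] <- -100             # 10 ms apart
  expect_length(detect_discharges(tr2, 1000, refractory_s = 0.05), 1)
  expect_error(detect_discharges(c(1, NA), 1000), "finite")
  expect_error(detect_discharges(tr, 1000, k_mad = 0), "k_mad")
})

test_that("maxed-interval grouping reproduces hand-traced examples", {
  expect_equal(nrow(group_maxed_interval(numeric(0))), 0)
  d <- c(0, 0.2, 0.4, 5.0, 5.2, 5.4, 5.6)
  p <- max_interval_params(max_begin_isi_s = 0.5, max_end_isi_s = 0.5,
                           min_ibi_s = 1, min_event_duration_s = 0.3,
                           min_discharges = 3, ile_min_duration_s = 0.3)
  ev <- group_maxed_interval(d, p)
  expect_equal(ev$start_s, c(0, 5.0))
  expect_equal(ev$end_s, c(0.4, 5.6))
  expect_equal(ev$n_discharges, c(3L, 4L))
  p2 <- p; p2$min_ibi_s <- 5
  ev2 <- group_maxed_interval(d, p2)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$n_discharges, 7L)
  expect_equal(ev2$discharge_times[[1]], d)
  expect_error(group_maxed_interval(c(2, 1)), "sorted")
})

test_that("grouping matches the reference implementation on random input", {
  set.seed(31)
  for (rep in 1:100) {
    t <- random_discharge_seq()
    p <- random_maxint_params()
    got <- group_maxed_interval(t, p)$discharge_times
    want <- ref_maxed_interval(t, p)
    expect_equal(length(got), length(want))
    for (k in seq_along(want)) expect_equal(got[[k]], want[[k]])
  }
})

test_that("raising min_discharges never increases the event count", {
  set.seed(17)
  for (rep in 1:20) {
    t <- random_discharge_seq()
    p <- random_maxint_params()
    counts <- vapply(1:6, function(md) {
      p$min_discharges <- md
      nrow(group_maxed_interval(t, p))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("events are disjoint and metrics shift-invariant", {
  set.seed(23)
  t <- random_discharge_seq()
  p <- max_interval_params(max_begin_isi_s = 1, max_end_isi_s = 1,
                           min_ibi_s = 2, min_event_duration_s = 1,
                           min_discharges = 3, ile_min_duration_s = 2)
  ev <- group_maxed_interval(t, p)
  if (nrow(ev) > 1)
    expect_true(all(ev$start_s[-1] > ev$end_s[-nrow(ev)]))
  shifted <- group_maxed_interval(t + 100, p)
  expect_equal(shifted$start_s, ev$start_s + 100)
  expect_equal(shifted$end_s - shifted$start_s, ev$end_s - ev$start_s)
})

test_that("ILE/IILD classification applies the independence rules", {
  p <- max_interval_params()
  # a single 20-s, 60-discharge train is one ILE
  train <- seq(0, 20, length.out = 61)
  ev <- classify_events(train, p)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "ILE")
  # isolated single discharges in an ILE-free source are retained IILDs
  singles <- c(10, 40, 90, 150)
  ev2 <- classify_events(singles, p)
  expect_equal(ev2$kind, rep("IILD", 4))
  expect_false(any(ev2$excluded))
  # an IILD 30 s after an ILE of the same source is excluded (60-s window)
  both <- c(train, 50, 200)
  ev3 <- classify_events(both, p, postictal_exclusion_s = 60,
                         iild_requires_ile_free_source = FALSE)
  expect_equal(ev3$kind, c("ILE", "IILD", "IILD"))
  expect_equal(ev3$excluded, c(FALSE, TRUE, FALSE))
  # with the source-exclusivity rule every IILD in an ILE source is excluded
  ev4 <- classify_events(both, p, iild_requires_ile_free_source = TRUE)
  expect_equal(ev4$excluded[ev4$kind == "IILD"], c(TRUE, TRUE))
})

test_that("onset classification recognises planted LVF and hypersynchronous", {
  fs <- 1000
  set.seed(41)
  noise <- rnorm(30 * fs, sd = 1)
  train <- seq(7, 25, by = 1 / 3)
  mk <- function(base, times, amp) {
    for (t in times) {
      i <- round(t * fs); base[i:(i + 10)] <- base[i:(i + 10)] - amp
    }
    base
  }
  # LVF: low-amplitude 15 Hz segment in [5, 7] s, then the train
  lvf <- noise
  seg <- seq(5 * fs, 7 * fs)
  lvf[seg] <- lvf[seg] + 8 * sin(2 * pi * 15 * (seg - 5 * fs) / fs)
  lvf <- mk(lvf, train, 100)
  expect_equal(classify_onset(lvf, fs, 5, 25, train), "LVF")
  # hypersynchronous: initial discharges 2x the train amplitude
  hyp <- mk(mk(noise, seq(5, 7, by = 0.3), 200), train, 100)
  expect_equal(classify_onset(hyp, fs, 5, 25, c(seq(5, 7, by = 0.3), train)),
               "hypersynchronous")
  # flat onset segment: unclassified
  flat <- mk(noise, train, 100)
  expect_equal(classify_onset(flat, fs, 5, 25, train), "unclassified")
  # window extending past the trace end: unclassified
  expect_equal(classify_onset(lvf[1:(6 * fs)], fs, 5, 25, train),
               "unclassified")
})

test_that("epoch summaries follow the arithmetic definitions", {
  model <- structure(list(weights = rbind(c(rep(0.6, 21), rep(0, 38))),
                          n_ics = 1), class = "source_model")
  ep <- list(label = "baseline", start_s = 0, end_s = 1200)
  none <- summarize_epoch(
    data.frame(source = integer(), kind = character(), start_s = numeric(),
               end_s = numeric(), n_discharges = integer(),
               excluded = logical()), model, ep)
  expect_equal(none$n_ile_per_20min, 0)
  expect_equal(none$mean_ile_duration_s, 0)
  expect_equal(none$within_ile_discharge_freq_hz, 0)
  expect_false(none$had_activity)

  ev <- data.frame(source = 1, kind = "ILE", start_s = c(100, 400, 800),
                   end_s = c(110, 420, 830),
                   n_discharges = c(30L, 60L, 90L), excluded = FALSE)
  m <- summarize_epoch(ev, model, ep)
  expect_equal(m$n_ile_per_20min, 3)
  expect_equal(m$mean_ile_duration_s, 20)
  expect_equal(m$within_ile_discharge_freq_hz, 3)
  expect_equal(m$ile_spatial_extent_electrodes, 21)
  expect_true(m$had_activity)
  # time-shifting events and epoch together leaves the metrics unchanged
  ev2 <- ev; ev2$start_s <- ev$start_s + 55; ev2$end_s <- ev$end_s + 55
  m2 <- summarize_epoch(ev2, model,
                        list(label = "baseline", start_s = 55,
                             end_s = 1255))
  expect_equal(m2[, 3:8], m[, 3:8])
  expect_error(summarize_epoch(ev, model,
                               list(label = "x", start_s = 5, end_s = 5)),
               "epoch")
})
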