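#' Electrode layout of a 60-electrode MEA grid
#'
#' Describes the 8 x 8 grid used for slice recordings: 60 electrodes (the four
#' grid corners are unused), of which 59 record and one is the reference.
#' Electrode diameter is 100 um and pitch 700 um by default.
#'
#' @param positions Two-column integer matrix or data.frame of 0-based
#'   (row, col) grid indices, one row per electrode. Default: the 8 x 8 grid
#'   minus its four corners, row-major.
#' @param reference_index 1-based index (into `positions`) of the reference
#'   electrode. Default 1.
#' @param electrode_diameter_um,pitch_um Geometry, in micrometres.
#' @return An object of class `mea_layout`: a data.frame with columns
#'   `row`, `col`, `is_reference`, plus geometry attributes.
#' @export
electrode_layout <- function(positions = NULL, reference_index = 1L,
                             electrode_diameter_um = 100, pitch_um = 700) {
  if (is.null(positions)) {
    g <- expand.grid(col = 0:7, row = 0:7)[, c("row", "col")]
    corner <- (g$row %in% c(0L, 7L)) & (g$col %in% c(0L, 7L))
    positions <- g[!corner, ]
  }
  positions <- as.data.frame(positions)
  names(positions)[1:2] <- c("row", "col")
  if (anyDuplicated(positions[, c("row", "col")]))
    stop("electrode positions must be unique")
  if (nrow(positions) != 60L)
    stop("layout must contain exactly 60 electrode positions, got ",
         nrow(positions))
  if (reference_index < 1L || reference_index > 60L)
    stop("reference_index out of range")
  layout <- data.frame(row = as.integer(positions$row),
                       col = as.integer(positions$col),
                       is_reference = seq_len(60L) == as.integer(reference_index))
  attr(layout, "electrode_diameter_um") <- electrode_diameter_um
  attr(layout, "pitch_um") <- pitch_um
  class(layout) <- c("mea_layout", "data.frame")
  layout
}

#' @export
print.mea_layout <- function(x, ...) {
  cat("MEA layout: 60 electrodes (59 recording + 1 reference), 8 x 8 grid\n")
  cat(sprintf("  diameter %g um, pitch %g um, reference at (row %d, col %d)\n",
              attr(x, "electrode_diameter_um"), attr(x, "pitch_um"),
              x$row[x$is_reference], x$col[x$is_reference]))
  invisible(x)
}

#' Recording electrodes of a layout
#'
#' @param layout An `mea_layout`.
#' @return Integer indices (into the layout rows) of the 59 recording
#'   electrodes, in channel order.
#' @export
recording_electrodes <- function(layout) which(!layout$is_reference)

#' Construct a multichannel MEA recording
#'
#' A recording holds the extracellular voltage matrix (one row per recording
#' electrode, in microvolts), the sampling rate, the electrode layout, the
#' ionic/pharmacological condition, and a set of labelled analysis epochs.
#'
#' @param data Numeric matrix, n_channels x n_samples, voltage in uV. The
#'   number of rows must equal the number of recording electrodes of `layout`.
#' @param fs_hz Sampling rate in Hz (default 10000).
#' @param layout An `mea_layout`; default [electrode_layout()].
#' @param condition Named list with elements `mg_mM`, `k_mM`, `drug_name`,
#'   `drug_conc_uM` describing the bath condition (0 Mg2+ / 6 mM K+ induction
#'   by default, no drug).
#' @param epochs Data.frame with columns `label` (one of "baseline",
#'   "treatment", "washout"), `start_s`, `end_s`. Must be non-overlapping,
#'   sorted, and lie within the recording.
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(data, fs_hz = 10000, layout = electrode_layout(),
                          condition = list(mg_mM = 0, k_mM = 6,
                                           drug_name = NA_character_,
                                           drug_conc_uM = NA_real_),
                          epochs = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n_rec <- sum(!layout$is_reference)
  if (nrow(data) != n_rec)
    stop("data has ", nrow(data), " channels but layout has ", n_rec,
         " recording electrodes")
  if (!all(is.finite(data))) stop("all voltage samples must be finite")
  if (fs_hz <= 0) stop("fs_hz must be positive")
  dur <- ncol(data) / fs_hz
  if (is.null(epochs))
    epochs <- data.frame(label = "baseline", start_s = 0, end_s = dur)
  epochs <- validate_epochs(epochs, dur)
  structure(list(data = data, fs_hz = fs_hz, layout = layout,
                 condition = condition, epochs = epochs,
                 preprocessing = NULL),
            class = "mea_recording")
}

validate_epochs <- function(epochs, duration_s) {
  epochs <- as.data.frame(epochs)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(epochs)))
    stop("epochs must have columns label, start_s, end_s")
  ok_lab <- epochs$label %in% c("baseline", "treatment", "washout")
  if (!all(ok_lab))
    stop("epoch labels must be baseline/treatment/washout")
  if (any(epochs$end_s <= epochs$start_s)) stop("epochs must have end > start")
  if (is.unsorted(epochs$start_s)) stop("epochs must be sorted by start")
  if (nrow(epochs) > 1 &&
      any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)] - 1e-9))
    stop("epochs must be non-overlapping")
  tol <- 1e-6
  if (any(epochs$start_s < -tol) || any(epochs$end_s > duration_s + tol))
    stop("epochs must lie within [0, ", signif(duration_s, 6), "] s")
  epochs$label <- as.character(epochs$label)
  epochs
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("MEA recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  cond <- x$condition
  cat(sprintf("  condition: %g mM Mg2+, %g mM K+%s\n", cond$mg_mM, cond$k_mM,
              if (!is.na(cond$drug_name))
                sprintf(", %s %g uM", cond$drug_name, cond$drug_conc_uM)
              else ""))
  cat(sprintf("  epochs: %s\n",
              paste(sprintf("%s [%g, %g] s", x$epochs$label, x$epochs$start_s,
                            x$epochs$end_s), collapse = "; ")))
  if (!is.null(x$preprocessing))
    cat("  preprocessed:", x$preprocessing$summary, "\n")
  invisible(x)
}
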