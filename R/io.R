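#' Write a recording to the on-disk container
#'
#' The container is a plain directory holding `meta.json` (sampling rate,
#' condition, matrix dimensions, format version), `layout.csv` (row, col,
#' is_reference per electrode), `epochs.csv`, and `data.bin` (the voltage
#' matrix in little-endian float64, channel-major: all samples of channel 1,
#' then channel 2, ...). Everything except the raw samples is text, so a
#' container can be inspected with standard tools; the samples round-trip
#' bit-identically.
#'
#' @param rec An [mea_recording()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mea_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create container directory: ", path)
  meta <- list(format = "ictalmea-recording", version = 1L,
               fs_hz = rec$fs_hz,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               voltage_unit = "uV",
               condition = rec$condition,
               electrode_diameter_um = attr(rec$layout, "electrode_diameter_um"),
               pitch_um = attr(rec$layout, "pitch_um"))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  utils::write.csv(as.data.frame(rec$layout), file.path(path, "layout.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$epochs, file.path(path, "epochs.csv"),
                   row.names = FALSE)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  # channel-major: t(data) is sample-major in memory; write row-by-row instead
  writeBin(as.vector(t(rec$data)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a recording from the on-disk container
#'
#' Inverse of [write_recording()]. Missing files or metadata fields raise a
#' format error naming the missing element; a mismatch between the layout and
#' the data matrix raises a consistency error.
#'
#' @param path Container directory.
#' @return An [mea_recording()].
#' @export
read_recording <- function(path) {
  if (!dir.exists(path)) stop("recording container not found: ", path)
  need <- c("meta.json", "layout.csv", "epochs.csv", "data.bin")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("recording container format error: missing ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  for (f in c("fs_hz", "n_channels", "n_samples", "condition"))
    if (is.null(meta[[f]]))
      stop("recording container format error: meta.json lacks '", f, "'")
  lay <- utils::read.csv(file.path(path, "layout.csv"))
  layout <- electrode_layout(lay[, c("row", "col")],
                             reference_index = which(lay$is_reference),
                             electrode_diameter_um =
                               meta$electrode_diameter_um %||% 100,
                             pitch_um = meta$pitch_um %||% 700)
  n_ch <- as.integer(meta$n_channels)
  n_s <- as.integer(meta$n_samples)
  if (n_ch != sum(!layout$is_reference))
    stop("recording container consistency error: meta says ", n_ch,
         " channels but layout has ", sum(!layout$is_reference),
         " recording electrodes")
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n_ch * n_s, size = 8, endian = "little")
  if (length(v) != n_ch * n_s)
    stop("recording container consistency error: data.bin holds ", length(v),
         " samples, expected ", n_ch * n_s)
  data <- matrix(v, nrow = n_ch, ncol = n_s, byrow = TRUE)
  epochs <- utils::read.csv(file.path(path, "epochs.csv"))
  cond <- meta$condition
  cond$drug_name <- if (is.null(cond$drug_name)) NA_character_ else
    as.character(cond$drug_name)
  cond$drug_conc_uM <- if (is.null(cond$drug_conc_uM)) NA_real_ else
    as.numeric(cond$drug_conc_uM)
  mea_recording(data, fs_hz = as.numeric(meta$fs_hz), layout = layout,
                condition = cond, epochs = epochs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write detected events and per-source metrics tables
#'
#' Writes `events.csv` (one detected event per row), `metrics.csv` (one row
#' per source x epoch) and a `run_meta.json` sidecar carrying the analysis
#' configuration and seed, so a result directory is self-describing.
#'
#' @param events Data.frame of events as returned by [classify_events()]
#'   (possibly rbind-ed over sources); may have zero rows.
#' @param metrics Data.frame of per-source, per-epoch metrics from
#'   [summarize_epoch()].
#' @param path Output directory.
#' @param config Optional list (analysis parameters) stored in the sidecar.
#' @param seed Optional integer seed stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(events, metrics, path, config = NULL, seed = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot write results to: ", path)
  utils::write.csv(as.data.frame(events), file.path(path, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(metrics), file.path(path, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(package = "ictalmea", config = config, seed = seed),
                       file.path(path, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read back an events/metrics result directory
#'
#' @param path Directory written by [write_results()].
#' @return List with elements `events`, `metrics`, `meta`.
#' @export
read_results <- function(path) {
  for (f in c("events.csv", "metrics.csv"))
    if (!file.exists(file.path(path, f)))
      stop("results format error: missing ", f)
  list(events = utils::read.csv(file.path(path, "events.csv")),
       metrics = utils::read.csv(file.path(path, "metrics.csv")),
       meta = if (file.exists(file.path(path, "run_meta.json")))
         jsonlite::read_json(file.path(path, "run_meta.json")) else NULL)
}
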