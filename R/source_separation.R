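#' Preprocess a multichannel recording
#'
#' Standard LFP conditioning ahead of source separation: per-channel mean
#' removal, optional high-pass and mains-notch filtering (zero-phase
#' Butterworth via forward-backward filtering), exclusion of channels whose
#' log-variance is a robust outlier, and anti-aliased integer-factor
#' downsampling.
#'
#' Excluded channels are zeroed and recorded in the `preprocessing` field;
#' downstream weights for them are zero.
#'
#' @param rec An [mea_recording()].
#' @param hp_hz High-pass corner (default 1; 0 disables).
#' @param notch_hz Mains notch centre (default NULL = off); a 4-Hz-wide
#'   second-order band-stop is used.
#' @param target_fs_hz Output sampling rate (default 1000). Must divide the
#'   input rate; equal input/output is a no-op. Larger than the input rate
#'   is a configuration error.
#' @param bad_channel_z Robust z threshold on per-channel log-variance
#'   (default 6; `Inf` disables).
#' @return A preprocessed [mea_recording()] with the `preprocessing` field
#'   filled in.
#' @export
preprocess <- function(rec, hp_hz = 1, notch_hz = NULL, target_fs_hz = 1000,
                       bad_channel_z = 6) {
  stopifnot(inherits(rec, "mea_recording"))
  fs <- rec$fs_hz
  if (target_fs_hz > fs)
    stop("configuration error: target_fs_hz (", target_fs_hz,
         ") exceeds the sampling rate (", fs, ")")
  x <- rec$data
  x <- x - rowMeans(x)

  bad <- integer(0)
  if (is.finite(bad_channel_z)) {
    # target broken/saturated electrodes, not physiologically active ones:
    # a channel is bad only if its log-variance is a robust outlier AND
    # deviates from the channel median by at least a factor of 20
    v <- log(apply(x, 1, stats::var) + 1e-12)
    dev <- abs(v - stats::median(v))
    bad <- which(dev > pmax(bad_channel_z * stats::mad(v), log(20)))
    if (length(bad)) x[bad, ] <- 0
  }

  if (hp_hz > 0) {
    bf <- signal::butter(2, hp_hz / (fs / 2), type = "high")
    for (ch in seq_len(nrow(x)))
      if (!(ch %in% bad)) x[ch, ] <- signal::filtfilt(bf, x[ch, ])
  }
  if (!is.null(notch_hz)) {
    bs <- signal::butter(2, c(notch_hz - 2, notch_hz + 2) / (fs / 2),
                         type = "stop")
    for (ch in seq_len(nrow(x)))
      if (!(ch %in% bad)) x[ch, ] <- signal::filtfilt(bs, x[ch, ])
  }
  if (target_fs_hz < fs) {
    k <- fs / target_fs_hz
    if (abs(k - round(k)) > 1e-9)
      stop("configuration error: target_fs_hz must divide fs (", fs, ")")
    k <- as.integer(round(k))
    aa <- signal::butter(4, 0.8 * target_fs_hz / fs)  # 0.4 * target Nyquist
    y <- matrix(0, nrow(x), ceiling(ncol(x) / k))
    keep <- seq(1, ncol(x), by = k)
    for (ch in seq_len(nrow(x)))
      y[ch, ] <- if (ch %in% bad) 0 else
        signal::filtfilt(aa, x[ch, ])[keep]
    x <- y
    fs <- target_fs_hz
  }

  out <- rec
  out$data <- x
  out$fs_hz <- fs
  out$preprocessing <- list(
    mean_removed = TRUE, hp_hz = hp_hz, notch_hz = notch_hz,
    fs_in_hz = rec$fs_hz, fs_out_hz = fs, bad_channels = bad,
    summary = sprintf("demean, hp %g Hz%s, %g -> %g Hz, %d bad channel(s)",
                      hp_hz,
                      if (!is.null(notch_hz))
                        sprintf(", notch %g Hz", notch_hz) else "",
                      rec$fs_hz, fs, length(bad)))
  out
}

# symmetric decorrelation: W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

#' PCA + ICA source decomposition of a preprocessed recording
#'
#' Reduces the channel space by PCA to the smallest number of components
#' explaining at least `variance_target` of the variance (components with
#' eigenvalues tied at the cut are all kept), then unmixes with fixed-point
#' ICA under a log-cosh contrast (symmetric decorrelation, deterministic
#' seeded initialisation). Each independent component (IC) gets a
#' per-electrode weight vector — the share of the raw signal attributed to
#' that source — scaled to max |weight| = 1, and a time course oriented so
#' its largest deflection is negative (LFP convention). Reconstruction from
#' (weights, traces) explains exactly the retained PCA variance, hence at
#' least `variance_target`.
#'
#' The ICA rotation is applied to the above-noise-floor part of the retained
#' subspace: eigencomponents whose eigenvalue exceeds
#' `signal_eig_factor` times the median eigenvalue. Retained components at
#' the noise floor form an (approximately) Gaussian subspace, which is
#' rotation-invariant under the ICA model — no rotation of it is more
#' "independent" than any other, and dragging dozens of such components
#' through the fixed-point iteration only destabilises the estimate — so
#' they are passed through as PCA components. Signal ICs come first in the
#' output.
#'
#' For efficiency the unmixing matrix is estimated on an evenly spaced
#' subsample of at most `max_fit_samples` time points and then applied to
#' the full recording.
#'
#' @param rec A preprocessed [mea_recording()].
#' @param variance_target Fraction of variance the retained PCA subspace
#'   must explain (default 0.95).
#' @param max_iter,tol Fixed-point iteration cap (default 1000) and
#'   convergence tolerance (default 1e-5).
#' @param max_fit_samples Samples used for unmixing estimation (default
#'   100000).
#' @param signal_eig_factor Eigenvalues above this multiple of the median
#'   eigenvalue are treated as signal and unmixed by ICA (default 2).
#' @param seed Seed for the unmixing initialisation (default 1).
#' @return Object of class `source_model`: `ic_traces` (n_ics x n_samples),
#'   `weights` (n_ics x n_electrodes), `pca_variance_retained`, `fs_hz`,
#'   `n_signal_ics`, `converged`, `n_iter`, `preprocessing`.
#' @export
decompose <- function(rec, variance_target = 0.95, max_iter = 1000,
                      tol = 1e-5, max_fit_samples = 100000,
                      signal_eig_factor = 2, seed = 1L) {
  stopifnot(inherits(rec, "mea_recording"))
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  X <- rec$data - rowMeans(rec$data)
  n_ch <- nrow(X); n <- ncol(X)
  if (n_ch < 2) stop("need at least 2 channels")
  C <- tcrossprod(X) / n
  e <- eigen(C, symmetric = TRUE)
  total <- sum(e$values)
  if (total <= 1e-20) stop("decomposition error: rank-deficient (all-zero) input")
  cum <- cumsum(e$values) / total
  k <- which(cum >= variance_target)[1]
  if (is.na(k)) k <- n_ch
  # keep eigenvalue ties at the cut
  while (k < n_ch && e$values[k + 1] > e$values[k] * (1 - 1e-10)) k <- k + 1
  keep <- which(e$values[seq_len(k)] > total * 1e-12)
  k <- length(keep)
  E <- e$vectors[, keep, drop = FALSE]
  D <- e$values[keep]
  Z <- (t(E) %*% X) / sqrt(D)

  # signal subspace: retained eigencomponents clearly above the noise floor
  k_sig <- sum(D > signal_eig_factor * stats::median(e$values))
  converged <- TRUE; it <- 0L
  W <- diag(1, k)
  if (k_sig >= 2) {
    idx <- unique(round(seq(1, n, length.out = min(n, max_fit_samples))))
    Zf <- Z[seq_len(k_sig), idx, drop = FALSE]
    nf <- ncol(Zf)
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    Ws <- sym_decorrelate(matrix(stats::rnorm(k_sig * k_sig), k_sig, k_sig))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      G <- tanh(Ws %*% Zf)
      W1 <- (G %*% t(Zf)) / nf - diag(rowMeans(1 - G^2), k_sig) %*% Ws
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(diag(W1 %*% t(Ws))) - 1))
      Ws <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    W[seq_len(k_sig), seq_len(k_sig)] <- Ws
  }

  S <- W %*% Z
  A <- E %*% (sqrt(D) * t(W))   # mixing: columns = per-IC electrode maps
  weights <- t(A)               # n_ics x n_electrodes
  for (i in seq_len(k)) {
    peak <- which.max(abs(S[i, ]))
    if (S[i, peak] > 0) { S[i, ] <- -S[i, ]; weights[i, ] <- -weights[i, ] }
    sc <- max(abs(weights[i, ]))
    if (sc > 0) { weights[i, ] <- weights[i, ] / sc; S[i, ] <- S[i, ] * sc }
  }

  structure(list(ic_traces = S, weights = weights,
                 pca_variance_retained = sum(D) / total,
                 fs_hz = rec$fs_hz, n_ics = k, n_signal_ics = k_sig,
                 converged = converged, n_iter = it,
                 variance_target = variance_target,
                 preprocessing = rec$preprocessing),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("Source model: %d ICs over %d electrodes, %.1f%% variance retained\n",
              x$n_ics, ncol(x$weights), 100 * x$pca_variance_retained))
  cat(sprintf("  %d samples @ %g Hz; ICA %s after %d iterations\n",
              ncol(x$ic_traces), x$fs_hz,
              if (x$converged) "converged" else "did NOT converge", x$n_iter))
  invisible(x)
}

#' Active electrodes of an independent component
#'
#' Electrodes whose absolute ICA weight reaches at least `theta` times the
#' component's maximum absolute weight; the size of this set is the
#' "number of electrodes recording ILEs" outcome.
#'
#' @param model A `source_model`.
#' @param ic IC index.
#' @param theta Relative threshold in (0, 1) (default 0.2).
#' @return Integer vector of electrode (channel) indices.
#' @export
spatial_map <- function(model, ic, theta = 0.2) {
  stopifnot(inherits(model, "source_model"))
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  if (ic < 1 || ic > nrow(model$weights)) stop("ic index out of range")
  w <- abs(model$weights[ic, ])
  which(w >= theta * max(w))
}

#' Export one IC's weights as an 8 x 8 grid
#'
#' @param model A `source_model`.
#' @param ic IC index.
#' @param layout The electrode layout the recording used.
#' @return 8 x 8 numeric matrix (NA at the unused corners and the
#'   reference electrode), suitable for a heat map or CSV export.
#' @export
weight_grid <- function(model, ic, layout = electrode_layout()) {
  if (ic < 1 || ic > nrow(model$weights)) stop("ic index out of range")
  g <- matrix(NA_real_, 8, 8)
  rec <- recording_electrodes(layout)
  for (j in seq_along(rec)) {
    g[layout$row[rec[j]] + 1L, layout$col[rec[j]] + 1L] <-
      model$weights[ic, j]
  }
  g
}
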