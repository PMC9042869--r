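# Band-limited phase-locking connectivity.
#
# Pipeline: segment the recording into fixed-length artifact-screened
# epochs -> zero-phase band-pass in a canonical EEG band -> instantaneous
# phase via the analytic signal -> phase locking value (PLV) for every
# region pair -> average the per-epoch matrices into one connectome.
#
# The band-pass is applied in the frequency domain as the squared magnitude
# response of an order-4 analog Butterworth band-pass. This matches the
# magnitude of the usual forward-backward (filtfilt) order-4 design and is
# exactly zero phase -- phase distortion would corrupt PLV -- at the cost of
# circular boundary effects, which the 1-s phase margin discards anyway.

#' Canonical EEG frequency bands
#' @return Named list of `c(lo, hi)` band edges in Hz: delta 1-4, theta 4-8,
#'   alpha 8-13, beta 13-30, gamma 30-45.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 45))
}

.resolve_band <- function(band) {
  if (is.character(band)) {
    bands <- eeg_bands()
    if (!band %in% names(bands)) {
      stop("unknown band '", band, "'; one of ",
           paste(names(bands), collapse = ", "))
    }
    return(bands[[band]])
  }
  stopifnot(is.numeric(band), length(band) == 2L)
  if (!(band[1] > 0 && band[2] > band[1])) stop("need 0 < lo < hi")
  band
}

#' Regional time-series container
#'
#' @param data Numeric matrix, regions x samples (microvolts).
#' @param fs Sampling rate in Hz (> 0).
#' @param region_labels Optional character vector of region names.
#' @return Object of class `regional_ts`.
#' @export
regional_ts <- function(data, fs, region_labels = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (!all(is.finite(data))) stop("time series contain non-finite values")
  if (!is.null(region_labels)) {
    stopifnot(length(region_labels) == nrow(data))
    rownames(data) <- region_labels
  }
  structure(list(data = data, fs = as.numeric(fs),
                 region_labels = rownames(data)),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("<regional_ts> %d regions x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Segment a recording into artifact-screened epochs
#'
#' Cuts consecutive non-overlapping epochs of `epoch_len` seconds, rejects
#' any epoch in which any sample of any region exceeds `max_abs` in absolute
#' value, and returns the earliest `n_keep` surviving epochs.
#'
#' @param ts A [regional_ts()].
#' @param epoch_len Epoch length in seconds (default 40).
#' @param max_abs Artifact threshold in microvolts (default 100).
#' @param n_keep Number of surviving epochs to keep (default 4); `NULL`
#'   keeps all survivors.
#' @return List of `regional_ts` epochs.
#' @export
segment_epochs <- function(ts, epoch_len = 40, max_abs = 100, n_keep = 4) {
  stopifnot(inherits(ts, "regional_ts"), epoch_len > 0, max_abs > 0)
  len <- round(ts$fs * epoch_len)
  n_avail <- floor(ncol(ts$data) / len)
  if (n_avail < 1L) {
    stop("recording (", sprintf("%.1f", ncol(ts$data) / ts$fs),
         " s) shorter than one ", epoch_len, "-s epoch")
  }
  epochs <- lapply(seq_len(n_avail), function(k) {
    ts$data[, ((k - 1L) * len + 1L):(k * len), drop = FALSE]
  })
  keep <- vapply(epochs, function(e) max(abs(e)) <= max_abs, logical(1))
  surv <- epochs[keep]
  if (!is.null(n_keep)) {
    if (length(surv) < n_keep) {
      stop("only ", length(surv), " artifact-free epochs available, ",
           n_keep, " required")
    }
    surv <- surv[seq_len(n_keep)]
  }
  lapply(surv, regional_ts, fs = ts$fs, region_labels = ts$region_labels)
}

# amplitude gain of the zero-phase order-`order` Butterworth band-pass at
# frequencies f (Hz): |H|^2 of the analog prototype, f0 = sqrt(lo*hi)
.butter_gain <- function(f, lo, hi, order = 4) {
  w <- 2 * pi * f
  w0sq <- (2 * pi)^2 * lo * hi
  bw <- 2 * pi * (hi - lo)
  g <- numeric(length(f))
  nz <- w != 0
  xi <- (w[nz]^2 - w0sq) / (w[nz] * bw)
  g[nz] <- 1 / (1 + xi^(2 * order))
  g
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the squared magnitude response of an order-4 analog Butterworth
#' band-pass in the frequency domain (exactly zero phase, equivalent in
#' magnitude to a forward-backward order-4 pass).
#'
#' @param ts A [regional_ts()].
#' @param band Band name (see [eeg_bands()]) or numeric `c(lo, hi)` in Hz.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered `regional_ts` of the same shape.
#' @export
bandpass <- function(ts, band, order = 4) {
  stopifnot(inherits(ts, "regional_ts"))
  band <- .resolve_band(band)
  if (band[2] >= ts$fs / 2) {
    stop("band upper edge ", band[2], " Hz violates Nyquist (fs = ",
         ts$fs, " Hz)")
  }
  n <- ncol(ts$data)
  f <- (seq_len(n) - 1L) / n * ts$fs
  f <- ifelse(f > ts$fs / 2, f - ts$fs, f)        # two-sided frequency axis
  gain <- .butter_gain(abs(f), band[1], band[2], order)
  x <- stats::mvfft(t(ts$data))
  y <- Re(stats::mvfft(x * gain, inverse = TRUE)) / n
  regional_ts(t(y), fs = ts$fs, region_labels = ts$region_labels)
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the Hilbert analytic signal of each (band-limited) regional
#' series by FFT and returns its phase. Boundary transients are flagged: a
#' `margin_samples` attribute marks how many samples to drop at each end
#' before estimating phase statistics.
#'
#' @param ts A band-limited [regional_ts()].
#' @param margin Edge margin in seconds flagged for exclusion (default 1).
#' @return Regions x samples matrix of phases in radians, with attributes
#'   `fs` and `margin_samples`.
#' @export
instantaneous_phase <- function(ts, margin = 1) {
  stopifnot(inherits(ts, "regional_ts"), margin >= 0)
  x <- ts$data
  n <- ncol(x)
  rms <- sqrt(rowMeans(x^2))
  if (any(rms < .Machine$double.eps^0.5)) {
    stop("region(s) ", paste(which(rms < .Machine$double.eps^0.5),
                             collapse = ", "),
         " are (near-)zero; phase undefined")
  }
  h <- numeric(n)                       # analytic-signal spectral weights
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  X <- stats::mvfft(t(x))
  analytic <- stats::mvfft(X * h, inverse = TRUE) / n
  ph <- t(Arg(analytic))
  attr(ph, "fs") <- ts$fs
  attr(ph, "margin_samples") <- as.integer(round(margin * ts$fs))
  ph
}

#' Phase locking value of two phase series
#'
#' PLV = |mean(exp(i (phi_x - phi_y)))|: 1 for perfectly locked phases,
#' approaching `1/sqrt(n)` in expectation for independent uniform phases.
#'
#' @param phase_x,phase_y Numeric phase vectors (radians) of equal
#'   length >= 2.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) stop("phase series length mismatch")
  if (length(phase_x) < 2L) stop("need at least 2 samples")
  min(abs(mean(exp(1i * (phase_x - phase_y)))), 1)
}

# PLV between all rows of a phase matrix, margins dropped
.plv_matrix <- function(phase) {
  m <- attr(phase, "margin_samples")
  if (!is.null(m) && m > 0L && ncol(phase) > 2L * m) {
    phase <- phase[, (m + 1L):(ncol(phase) - m), drop = FALSE]
  }
  z <- exp(1i * phase)
  p <- abs(z %*% Conj(t(z))) / ncol(phase)
  p <- pmin(p, 1)
  diag(p) <- 0
  p
}

#' Band-specific PLV connectome from epochs
#'
#' Band-passes each epoch, extracts instantaneous phases, computes the PLV
#' between every region pair (excluding the edge-transient margin), and
#' averages the per-epoch matrices into one representative connectome.
#'
#' @param epochs List of [regional_ts()] epochs (>= 1), e.g. from
#'   [segment_epochs()].
#' @param band Band name or `c(lo, hi)` in Hz (default `"alpha"`).
#' @param margin Edge margin in seconds excluded from PLV (default 1).
#' @param subject_id Optional id stored on the result.
#' @return `cpm_connectome`: symmetric zero-diagonal matrix in `[0, 1]` with
#'   attributes `band` and `subject_id`.
#' @export
connectome <- function(epochs, band = "alpha", margin = 1, subject_id = NULL) {
  if (!is.list(epochs) || length(epochs) == 0L) {
    stop("epochs must be a non-empty list")
  }
  stopifnot(all(vapply(epochs, inherits, logical(1), "regional_ts")))
  mats <- lapply(epochs, function(ep) {
    .plv_matrix(instantaneous_phase(bandpass(ep, band), margin = margin))
  })
  avg <- Reduce(`+`, mats) / length(mats)
  structure(avg,
            band = if (is.character(band)) band else paste(band, collapse = "-"),
            subject_id = subject_id,
            class = "cpm_connectome")
}

#' @export
print.cpm_connectome <- function(x, ...) {
  cat(sprintf("<cpm_connectome> %d x %d%s%s\n", nrow(x), ncol(x),
              if (!is.null(attr(x, "band"))) paste0(", band ", attr(x, "band")) else "",
              if (!is.null(attr(x, "subject_id"))) paste0(", subject ", attr(x, "subject_id")) else ""))
  invisible(x)
}
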